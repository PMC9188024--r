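#' Inverse-logit and logit links
#'
#' Thin wrappers over [stats::plogis()] / [stats::qlogis()] used throughout
#' the survival, residency and yearling models.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
inv_logit <- function(x) plogis(x)

#' @rdname inv_logit
#' @export
logit <- function(x) qlogis(x)

# Equal-tailed 89% credible interval bounds used package-wide.
CRI_PROBS <- c(0.055, 0.945)

#' Summarize a vector of posterior draws
#'
#' Median, equal-tailed 89% credible interval, and the direction probability
#' reported as P(< 0) for negative medians and P(> 0) for positive medians.
#'
#' @param x numeric vector of draws.
#' @return one-row tibble with `median`, `lower89`, `upper89`, `sign`,
#'   `prob_sign` (the posterior mass on the median's side of zero).
#' @export
summarise_draws_89 <- function(x) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 0)
  q <- unname(quantile(x, CRI_PROBS))
  m <- median(x)
  if (m < 0) {
    sign <- "<0"
    p <- mean(x < 0)
  } else {
    sign <- ">0"
    p <- mean(x > 0)
  }
  tibble::tibble(
    median = m, lower89 = q[1], upper89 = q[2],
    sign = sign, prob_sign = p
  )
}

# Stop with a formatted message; all validation errors go through this so
# messages carry a consistent "fullcycle" prefix.
fc_stop <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Derive a stream of sub-seeds (< 2^31) from one master seed so that each
# stochastic stage of a pipeline gets an independent, reproducible seed.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
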