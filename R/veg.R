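#' Climate-vegetation linear regression with Bayesian summaries
#'
#' Fits an intercept + slope normal linear model of an annual vegetation
#' response deviation (EVI greenness area or maturity date) on an annual
#' climate covariate deviation, and reports the slope as a posterior
#' median, equal-tailed 89% credible interval, and sign probability. Under
#' a flat prior the slope posterior is the least-squares estimate with a
#' scaled-t distribution on n - 2 degrees of freedom, so the interval
#' coincides with the classical one.
#'
#' @param data tibble containing the two series.
#' @param response,covariate column names (strings) of the response and
#'   covariate deviations.
#' @return one-row tibble: `response`, `covariate`, `n`, `median` (slope),
#'   `lower89`, `upper89`, `sign`, `prob_sign`.
#' @export
fit_climate_veg <- function(data, response, covariate) {
  x <- data[[covariate]]
  y <- data[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) fc_stop("need >= 4 paired years (got %d)", n)
  if (sd(x) == 0) fc_stop("covariate '%s' is constant", covariate)
  fit <- lm(y ~ x)
  b <- unname(coef(fit)[2])
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  df <- n - 2
  if (se == 0) {
    lo <- hi <- b
    p_sign <- 1
  } else {
    lo <- b + qt(CRI_PROBS[1], df) * se
    hi <- b + qt(CRI_PROBS[2], df) * se
    # posterior P(slope < 0) (or > 0) from the scaled-t tail at zero
    p_neg <- pt((0 - b) / se, df)
    p_sign <- if (b < 0) p_neg else 1 - p_neg
  }
  tibble::tibble(
    response = response, covariate = covariate, n = n,
    median = b, lower89 = lo, upper89 = hi,
    sign = if (b < 0) "<0" else ">0", prob_sign = p_sign
  )
}

#' Fit all climate-vegetation regressions of an annual table
#'
#' Applies [fit_climate_veg()] to every (response, covariate) pair,
#' optionally within units (regions/ranges), mirroring the reporting layout
#' of seasonal greenness and phenology analyses.
#'
#' @param veg_table annual table with response and covariate deviation
#'   columns, optionally a `region` column.
#' @param responses,covariates column-name vectors.
#' @param by optional grouping column (e.g. `"region"`).
#' @return tibble with one row per fit.
#' @export
veg_response_table <- function(veg_table,
                               responses = c("evi_area_deviation",
                                             "maturity_deviation"),
                               covariates = "cmd_b",
                               by = NULL) {
  groups <- if (is.null(by)) list(veg_table)
            else split(veg_table, veg_table[[by]])
  purrr::imap_dfr(groups, function(g, nm) {
    out <- purrr::map_dfr(responses, function(r) {
      purrr::map_dfr(covariates, function(cv) fit_climate_veg(g, r, cv))
    })
    if (!is.null(by)) out <- dplyr::mutate(out, !!by := nm, .before = 1)
    out
  })
}
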