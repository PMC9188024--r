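#' MCMC configuration
#'
#' Sampler settings shared by every model-fitting function. The `"paper"`
#' preset is the full protocol used for production fits (3 chains, 20,000
#' adaptation, 20,000 burn-in, 40,000 sampling iterations thinned by 5);
#' `"desk"` is a short preset for development, testing and examples.
#'
#' @param scale_preset `"desk"` or `"paper"`; individual arguments override
#'   the preset.
#' @param chains number of independent chains.
#' @param adapt,burnin,iterations,thin adaptation, burn-in and retained-phase
#'   lengths (iterations before thinning) and thinning interval.
#' @return a list of class `fc_mcmc_config`.
#' @export
mcmc_config <- function(scale_preset = c("desk", "paper"),
                        chains = NULL, adapt = NULL, burnin = NULL,
                        iterations = NULL, thin = NULL) {
  scale_preset <- match.arg(scale_preset)
  preset <- switch(scale_preset,
    desk  = list(chains = 3L, adapt = 1000L, burnin = 1000L,
                 iterations = 2000L, thin = 1L),
    paper = list(chains = 3L, adapt = 20000L, burnin = 20000L,
                 iterations = 40000L, thin = 5L)
  )
  cfg <- list(
    chains = as.integer(chains %||% preset$chains),
    adapt = as.integer(adapt %||% preset$adapt),
    burnin = as.integer(burnin %||% preset$burnin),
    iterations = as.integer(iterations %||% preset$iterations),
    thin = as.integer(thin %||% preset$thin),
    scale_preset = scale_preset
  )
  bad <- vapply(cfg[c("chains", "adapt", "burnin", "iterations", "thin")],
                function(v) !is.finite(v) || v < 1L, logical(1))
  if (any(bad)) fc_stop("all MCMC counts must be >= 1")
  structure(cfg, class = "fc_mcmc_config")
}

#' Run an MCMC simulation for a JAGS model
#'
#' Thin contract over [rjags]: compiles the model, runs adaptation and
#' burn-in, and returns retained draws as a labelled object. A fixed `seed`
#' gives bit-reproducible draws (each chain gets a Mersenne-Twister stream
#' seeded from `seed`).
#'
#' @param model JAGS model code as a single string.
#' @param data named list of data nodes.
#' @param params character vector of nodes to monitor.
#' @param config an [mcmc_config()].
#' @param inits optional named list (or function) of initial values shared by
#'   all chains; RNG settings are added per chain.
#' @param seed integer master seed.
#' @return object of class `fc_draws`: a [coda::mcmc.list] in `$samples`
#'   plus metadata (`$config`, `$seed`, `$model_sha`).
#' @export
run_mcmc <- function(model, data, params, config = mcmc_config(),
                     inits = NULL, seed = 1L) {
  stopifnot(inherits(config, "fc_mcmc_config"))
  sub <- derive_seeds(seed, config$chains)
  init_list <- lapply(seq_len(config$chains), function(ch) {
    base <- if (is.function(inits)) inits(ch) else inits %||% list()
    c(base, list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = sub[ch]))
  })
  jm <- tryCatch(
    rjags::jags.model(textConnection(model), data = data, inits = init_list,
                      n.chains = config$chains, n.adapt = config$adapt,
                      quiet = TRUE),
    error = function(e) {
      fc_stop("model initialization failed: %s\n data nodes: %s",
              conditionMessage(e), paste(names(data), collapse = ", "))
    }
  )
  update(jm, n.iter = config$burnin, progress.bar = "none")
  samples <- rjags::coda.samples(jm, variable.names = params,
                                 n.iter = config$iterations,
                                 thin = config$thin,
                                 progress.bar = "none")
  structure(
    list(samples = samples, config = config, seed = as.integer(seed),
         model_sha = sum(utf8ToInt(model)) %% 1e9),
    class = "fc_draws"
  )
}

#' @export
print.fc_draws <- function(x, ...) {
  m <- as.matrix(x$samples[[1]])
  cat(sprintf("<fc_draws> %d parameters, %d chains x %d retained iterations\n",
              ncol(m), length(x$samples), nrow(m)))
  invisible(x)
}

#' Stack retained draws into a matrix
#'
#' @param x an `fc_draws` object.
#' @param params optional regular expression selecting parameter columns.
#' @return numeric matrix, rows = draws (chains stacked), columns = parameters.
#' @export
draws_matrix <- function(x, params = NULL) {
  stopifnot(inherits(x, "fc_draws"))
  m <- do.call(rbind, lapply(x$samples, as.matrix))
  if (!is.null(params)) m <- m[, grepl(params, colnames(m)), drop = FALSE]
  m
}

# resolve a parameter column, tolerating JAGS's habit of dropping the
# index on single-element nodes ("b0[1]" monitored as "b0")
get_col <- function(m, name) {
  if (name %in% colnames(m)) return(m[, name])
  base <- sub("\\[[0-9, ]+\\]$", "", name)
  if (base %in% colnames(m)) return(m[, base])
  fc_stop("unknown parameter '%s'", name)
}

# vectorized variant: map requested names onto available columns
col_names <- function(m, names) {
  have <- colnames(m)
  vapply(names, function(nm) {
    if (nm %in% have) return(nm)
    base <- sub("\\[[0-9, ]+\\]$", "", nm)
    if (base %in% have) return(base)
    fc_stop("unknown parameter '%s'", nm)
  }, character(1), USE.NAMES = FALSE)
}

#' Extract draws of a single scalar parameter
#'
#' @param x an `fc_draws` object.
#' @param name exact parameter name (e.g. `"b0phi[1]"`); for single-element
#'   nodes the unindexed name is accepted too.
#' @return numeric vector across all chains.
#' @export
param_draws <- function(x, name) {
  get_col(draws_matrix(x), name)
}

#' Tidy posterior draws into a long tibble
#'
#' @param x an `fc_draws` object.
#' @param ... unused.
#' @return tibble with columns `parameter`, `chain`, `iteration`, `value`.
#' @export
tidy.fc_draws <- function(x, ...) {
  purrr::imap_dfr(x$samples, function(ch, i) {
    m <- as.matrix(ch)
    tibble::tibble(
      parameter = rep(colnames(m), each = nrow(m)),
      chain = as.integer(i),
      iteration = rep(seq_len(nrow(m)), times = ncol(m)),
      value = as.vector(m)
    )
  })
}

#' @export
glance.fc_draws <- function(x, ...) {
  gr <- gelman_rubin(x)
  m <- as.matrix(x$samples[[1]])
  tibble::tibble(
    chains = length(x$samples),
    iterations = nrow(m),
    parameters = ncol(m),
    max_rhat = max(gr$rhat, na.rm = TRUE)
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes, per monitored parameter, the potential scale reduction factor
#' \eqn{\sqrt{((n-1)/n\,W + B/n)/W}} from the within-chain variance `W` and
#' between-chain variance `B`. A fitted model is considered converged only
#' when every value is below 1.01.
#'
#' @param x an `fc_draws` object (or a [coda::mcmc.list]).
#' @return tibble with columns `parameter` and `rhat`, plus attribute
#'   `converged` (all rhat < 1.01).
#' @export
gelman_rubin <- function(x) {
  samples <- if (inherits(x, "fc_draws")) x$samples else x
  if (length(samples) < 2) fc_stop("gelman_rubin needs >= 2 chains")
  mats <- lapply(samples, as.matrix)
  n <- nrow(mats[[1]])
  if (n < 10) fc_stop("gelman_rubin needs >= 10 retained iterations per chain")
  pars <- colnames(mats[[1]])
  rhat <- vapply(seq_along(pars), function(jp) {
    draws <- vapply(mats, function(m) m[, jp], numeric(n))
    W <- mean(apply(draws, 2, var))
    B <- n * var(colMeans(draws))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  out <- tibble::tibble(parameter = pars, rhat = rhat)
  attr(out, "converged") <- all(rhat < 1.01)
  out
}

#' Posterior-predictive Bayesian p-value
#'
#' Generic; methods exist for stage-1 fits (chi-squared discrepancy on
#' counts / yearling flags) and IPM fits (Freeman-Tukey discrepancy on
#' first-recapture m-arrays). The p-value is the fraction of retained draws
#' whose replicated-data discrepancy is greater than or equal to the
#' observed-data discrepancy (ties count as successes).
#'
#' @param fit a fitted model object.
#' @param discrepancy discrepancy name; which names are valid depends on the
#'   fit class (`"chi_squared"` or `"freeman_tukey"`).
#' @param seed integer seed for the replicate simulations.
#' @param ... passed to methods.
#' @return one-row tibble with `discrepancy`, `p_value`, `n_draws`.
#' @export
posterior_predictive_check <- function(fit, discrepancy, seed = 1L, ...) {
  UseMethod("posterior_predictive_check")
}

# p = P(D_rep >= D_obs), the ">=" convention.
ppc_pvalue <- function(d_obs, d_rep) {
  stopifnot(length(d_obs) == length(d_rep))
  mean(d_rep >= d_obs)
}

# chi-squared discrepancy with a 0.5 floor in the denominator
chisq_disc <- function(obs, expct) {
  sum((obs - expct)^2 / (expct + 0.5))
}

# Freeman-Tukey discrepancy
ft_disc <- function(obs, expct) {
  sum((sqrt(obs) - sqrt(expct))^2)
}

#' Write/read a draw file
#'
#' Long-format comma-delimited draw files (`parameter, chain, iteration,
#' value`) with a `#`-prefixed metadata header; `read_draws` round-trips the
#' values bit-exactly (full double precision).
#'
#' @param x an `fc_draws` object.
#' @param path file path.
#' @return `write_draws` returns `path` invisibly; `read_draws` returns a
#'   tibble in the long layout above.
#' @export
write_draws <- function(x, path) {
  td <- tidy.fc_draws(x)
  header <- c(
    "# fullcycle draw file",
    sprintf("# seed: %d", x$seed),
    sprintf("# chains: %d  adapt: %d  burnin: %d  iterations: %d  thin: %d",
            x$config$chains, x$config$adapt, x$config$burnin,
            x$config$iterations, x$config$thin),
    sprintf("# model_sha: %d", x$model_sha)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("parameter,chain,iteration,value", con)
  writeLines(sprintf("%s,%d,%d,%.17g", td$parameter, td$chain,
                     td$iteration, td$value), con)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  # base read.csv parses doubles with strtod, which round-trips %.17g
  # output bit-exactly
  tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                    colClasses = c("character", "integer",
                                                   "integer", "numeric")))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
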