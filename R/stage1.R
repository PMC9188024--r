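# JAGS code for the stage-1 hierarchical models. Counts: negative-binomial
# adult captures with log-linear mean (region intercepts, effort effect,
# region-by-year and station random effects). Yearling: Bernoulli microage
# flags with a logit-linear version of the same structure. The two blocks
# are fit jointly (independent parameters) so that draws are paired per
# iteration, which the derived age indices require.
stage1_model_string <- function(counts = TRUE, ages = TRUE) {
  count_block <- "
  for (i in 1:Ncount) {
    count[i] ~ dnegbin(pnb[i], r)
    pnb[i] <- r / (r + mu[i])
    log(mu[i]) <- b0[regc[i]] + b1 * ef[i] + yr[regc[i], tc[i]] + sta[stac[i]]
  }
  b1 ~ dnorm(0, 0.01)
  r ~ dunif(0, 50)
  sig_sta ~ dnorm(0, 0.25) T(0,)
  tau_sta <- pow(sig_sta, -2)
  for (j in 1:S) { sta[j] ~ dnorm(0, tau_sta) }
  for (k in 1:K) {
    b0[k] ~ dnorm(0, 0.01)
    sig_yr[k] ~ dnorm(0, 0.25) T(0,)
    tau_yr[k] <- pow(sig_yr[k], -2)
    for (t in 1:T) { yr[k, t] ~ dnorm(0, tau_yr[k]) }
  }
"
  # microaged birds sharing a station-year share pY, so the Bernoulli flags
  # aggregate to binomial counts per station-year (identical likelihood)
  age_block <- "
  for (i in 1:Nage) {
    yng[i] ~ dbin(pY[i], aged[i])
    logit(pY[i]) <- b0y[rega[i]] + yry[rega[i], ta[i]] + stay[staa[i]]
  }
  sig_stay ~ dnorm(0, 0.25) T(0,)
  tau_stay <- pow(sig_stay, -2)
  for (j in 1:S) { stay[j] ~ dnorm(0, tau_stay) }
  for (k in 1:K) {
    b0y[k] ~ dnorm(0, 0.01)
    sig_yry[k] ~ dnorm(0, 0.25) T(0,)
    tau_yry[k] <- pow(sig_yry[k], -2)
    for (t in 1:T) { yry[k, t] ~ dnorm(0, tau_yry[k]) }
  }
"
  paste0("model {\n", if (counts) count_block,
         if (ages) age_block, "}\n")
}

# aggregate microage flags into binomial station-year groups
microage_data <- function(microage_table, fr) {
  grp <- microage_table |>
    dplyr::group_by(.data$station_id, .data$region, .data$year) |>
    dplyr::summarise(yng = sum(.data$is_yearling), aged = dplyr::n(),
                     .groups = "drop")
  list(
    Nage = nrow(grp),
    yng = as.integer(grp$yng),
    aged = as.integer(grp$aged),
    rega = match(grp$region, fr$regions),
    ta = match(grp$year, fr$years),
    staa = match(grp$station_id, fr$stations)
  )
}

check_capture_table <- function(capture_table) {
  need <- c("station_id", "region", "year", "effort_ratio", "ahy_count")
  missing <- setdiff(need, names(capture_table))
  if (length(missing) > 0)
    fc_stop("capture table lacks column(s): %s", paste(missing, collapse = ", "))
  cnt <- capture_table$ahy_count
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    fc_stop("ahy_count must be nonnegative integers")
  if (any(capture_table$effort_ratio <= 0))
    fc_stop("effort_ratio must be > 0")
  invisible(capture_table)
}

# shared index frame: region/year/station codings for a stage-1 fit
stage1_frame <- function(capture_table, microage_table) {
  regions <- sort(unique(c(capture_table$region, microage_table$region)))
  years <- sort(unique(c(capture_table$year, microage_table$year)))
  stations <- sort(unique(c(capture_table$station_id,
                            microage_table$station_id)))
  list(regions = regions, years = years, stations = stations)
}

#' Fit the stage-1 abundance and yearling models
#'
#' Joint MCMC fit of the adult-capture abundance model (negative-binomial
#' counts, log-linear mean with region intercepts, an effort-ratio effect,
#' region-by-year and station random effects) and the yearling-probability
#' model (Bernoulli microage flags, logit-linear with the analogous random
#' effects). Priors: Normal(0, 100) on intercepts and the effort
#' coefficient, half-Normal(0, 2) on random-effect SDs, Uniform(0, 50) on
#' the negative-binomial dispersion. Fitting jointly keeps the two
#' posteriors paired per iteration, as the draw-level age indices require.
#'
#' @param capture_table tibble: `station_id`, `region`, `year`,
#'   `effort_ratio`, `ahy_count` (operated station-years only).
#' @param microage_table tibble: `individual_id`, `station_id`, `region`,
#'   `year`, `is_yearling`; may have zero rows, in which case only the
#'   abundance block is fit.
#' @param config an [mcmc_config()].
#' @param seed integer seed.
#' @return object of class `fc_stage1`: draws plus data and index codings.
#' @export
fit_stage1 <- function(capture_table, microage_table = NULL,
                       config = mcmc_config(), seed = 1L) {
  check_capture_table(capture_table)
  microage_table <- microage_table %||%
    tibble::tibble(individual_id = character(), station_id = character(),
                   region = integer(), year = integer(),
                   is_yearling = integer())
  has_ages <- nrow(microage_table) > 0
  if (has_ages) {
    per_region <- table(factor(microage_table$region,
                               levels = sort(unique(capture_table$region))))
    if (any(per_region == 0))
      fc_stop("no microaged birds in region %s",
              names(per_region)[which(per_region == 0)[1]])
  }
  fr <- stage1_frame(capture_table, microage_table)
  if (length(fr$years) < 2) fc_stop("need >= 2 years")
  data <- list(
    Ncount = nrow(capture_table),
    count = as.integer(capture_table$ahy_count),
    ef = capture_table$effort_ratio,
    regc = match(capture_table$region, fr$regions),
    tc = match(capture_table$year, fr$years),
    stac = match(capture_table$station_id, fr$stations),
    K = length(fr$regions), T = length(fr$years), S = length(fr$stations)
  )
  params <- c("b0", "b1", "yr", "sta", "sig_yr", "sig_sta", "r")
  if (has_ages) {
    data <- c(data, microage_data(microage_table, fr))
    params <- c(params, "b0y", "yry", "stay", "sig_yry", "sig_stay")
  }
  draws <- run_mcmc(stage1_model_string(ages = has_ages), data, params,
                    config = config, seed = seed)
  structure(
    list(draws = draws, data = data, regions = fr$regions, years = fr$years,
         stations = fr$stations, capture_table = capture_table,
         microage_table = microage_table, has_ages = has_ages),
    class = "fc_stage1"
  )
}

#' Fit only the abundance (adult-capture) model
#'
#' @inheritParams fit_stage1
#' @return `fc_stage1` object without the yearling block.
#' @export
fit_abundance_model <- function(capture_table, config = mcmc_config(),
                                seed = 1L) {
  fit_stage1(capture_table, microage_table = NULL, config = config,
             seed = seed)
}

#' Fit only the yearling-probability model
#'
#' The Bernoulli microage model on its own; counts enter only to define the
#' station/year coding.
#'
#' @inheritParams fit_stage1
#' @return object of class `fc_stage1` (abundance block absent).
#' @export
fit_yearling_model <- function(microage_table, config = mcmc_config(),
                               seed = 1L) {
  if (nrow(microage_table) == 0) fc_stop("microage table is empty")
  fr <- list(regions = sort(unique(microage_table$region)),
             years = sort(unique(microage_table$year)),
             stations = sort(unique(microage_table$station_id)))
  data <- c(microage_data(microage_table, fr),
            list(K = length(fr$regions), T = length(fr$years),
                 S = length(fr$stations)))
  draws <- run_mcmc(stage1_model_string(counts = FALSE), data,
                    c("b0y", "yry", "stay", "sig_yry", "sig_stay"),
                    config = config, seed = seed)
  structure(
    list(draws = draws, data = data, regions = fr$regions, years = fr$years,
         stations = fr$stations, microage_table = microage_table,
         has_ages = TRUE, counts_absent = TRUE),
    class = "fc_stage1"
  )
}

# draws of b0[k] + yr[k,t] as an iterations x K x T array
logad_draw_array <- function(draws, K, T) {
  m <- draws_matrix(draws)
  n_it <- nrow(m)
  arr <- array(NA_real_, c(n_it, K, T))
  for (k in seq_len(K)) {
    b0 <- get_col(m, sprintf("b0[%d]", k))
    for (t in seq_len(T)) {
      arr[, k, t] <- b0 + get_col(m, sprintf("yr[%d,%d]", k, t))
    }
  }
  arr
}

py_draw_array <- function(draws, K, T) {
  m <- draws_matrix(draws)
  arr <- array(NA_real_, c(nrow(m), K, T))
  for (k in seq_len(K)) {
    b0 <- get_col(m, sprintf("b0y[%d]", k))
    for (t in seq_len(T)) {
      arr[, k, t] <- plogis(b0 + get_col(m, sprintf("yry[%d,%d]", k, t)))
    }
  }
  arr
}

#' Derive the adult abundance index from stage-1 draws
#'
#' The index is `ad = exp(b0_k + yr_kt)` — effort and station effects are
#' excluded, so it is a relative regional index, not a detection-corrected
#' abundance. Returns the per-draw array and the mean/SD of the log index
#' used to inform the population state.
#'
#' @param fit an `fc_stage1` object.
#' @return list: `log_ad` (iterations x region x year array) and `summary`
#'   tibble (`region`, `year`, `logad_mean`, `logad_sd`).
#' @export
derive_abundance_index <- function(fit) {
  stopifnot(inherits(fit, "fc_stage1"))
  K <- length(fit$regions); T <- length(fit$years)
  arr <- logad_draw_array(fit$draws, K, T)
  summary <- tidyr::expand_grid(region = fit$regions, year = fit$years) |>
    dplyr::mutate(
      logad_mean = purrr::map2_dbl(
        match(.data$region, fit$regions), match(.data$year, fit$years),
        ~ mean(arr[, .x, .y])),
      logad_sd = purrr::map2_dbl(
        match(.data$region, fit$regions), match(.data$year, fit$years),
        ~ sd(arr[, .x, .y]))
    )
  list(log_ad = arr, summary = summary)
}

#' Derive age-specific indices and observed recruitment
#'
#' Per MCMC draw: yearling-recruit index `ad1 = pY * ad`, older-adult index
#' `ad2+ = ad - ad1`, and observed recruitment `g_t = ad1_{t+1} / ad_t`
#' (undefined in the final year); then mean and SD per region-year across
#' draws. The additive identity `ad1 + ad2+ = ad` holds exactly per draw.
#'
#' @param fit an `fc_stage1` object with both blocks.
#' @return tibble of class `fc_index_summaries`: `region`, `year`, mean/SD
#'   pairs for `logad`, `ad1`, `ad2p`, `g` (`g_*` is `NA` for the final
#'   year).
#' @export
derive_age_indices <- function(fit) {
  stopifnot(inherits(fit, "fc_stage1"))
  if (!isTRUE(fit$has_ages)) fc_stop("fit has no yearling block")
  K <- length(fit$regions); T <- length(fit$years)
  log_ad <- logad_draw_array(fit$draws, K, T)
  pY <- py_draw_array(fit$draws, K, T)
  ad <- exp(log_ad)
  ad1 <- pY * ad
  ad2p <- ad - ad1
  res <- tidyr::expand_grid(region = fit$regions, year = fit$years)
  stat <- function(arr, f) {
    purrr::map2_dbl(match(res$region, fit$regions),
                    match(res$year, fit$years),
                    ~ f(arr[, .x, .y]))
  }
  res$logad_mean <- stat(log_ad, mean)
  res$logad_sd <- stat(log_ad, sd)
  res$ad1_mean <- stat(ad1, mean)
  res$ad1_sd <- stat(ad1, sd)
  res$ad2p_mean <- stat(ad2p, mean)
  res$ad2p_sd <- stat(ad2p, sd)
  g <- array(NA_real_, dim(ad))
  g[, , 1:(T - 1)] <- ad1[, , 2:T, drop = FALSE] / ad[, , 1:(T - 1), drop = FALSE]
  res$g_mean <- stat(g, function(v) if (all(is.na(v))) NA_real_ else mean(v))
  res$g_sd <- stat(g, function(v) if (all(is.na(v))) NA_real_ else sd(v))
  structure(res, class = c("fc_index_summaries", class(res)))
}

#' @rdname derive_age_indices
#' @export
index_summaries <- derive_age_indices

#' @export
tidy.fc_stage1 <- function(x, ...) {
  m <- draws_matrix(x$draws)
  purrr::map_dfr(colnames(m), function(p) {
    dplyr::bind_cols(tibble::tibble(parameter = p), summarise_draws_89(m[, p]))
  })
}

#' @export
glance.fc_stage1 <- function(x, ...) {
  gr <- gelman_rubin(x$draws)
  tibble::tibble(
    stations = length(x$stations), years = length(x$years),
    regions = length(x$regions),
    station_years = x$data$Ncount %||% NA_integer_,
    aged_birds = x$data$Nage %||% 0L,
    max_rhat = max(gr$rhat, na.rm = TRUE),
    converged = attr(gr, "converged")
  )
}

#' @describeIn posterior_predictive_check chi-squared posterior predictive
#'   check for the stage-1 capture models: for each retained draw the
#'   discrepancy `sum((obs - exp)^2 / (exp + 0.5))` is computed for the
#'   observed data and for data replicated from the fitted model; reported
#'   separately for the count model and (if present) the yearling model.
#' @param max_draws subsample size of retained draws used for the check.
#' @export
posterior_predictive_check.fc_stage1 <- function(fit,
                                                 discrepancy = "chi_squared",
                                                 seed = 1L,
                                                 max_draws = 500L, ...) {
  if (!identical(discrepancy, "chi_squared"))
    fc_stop("unknown discrepancy '%s' for stage-1 models", discrepancy)
  m <- draws_matrix(fit$draws)
  idx <- if (nrow(m) > max_draws)
    round(seq(1, nrow(m), length.out = max_draws)) else seq_len(nrow(m))
  d <- fit$data
  out <- list()
  with_seed(seed, {
    if (!is.null(d$Ncount)) {
      d_obs <- d_rep <- numeric(length(idx))
      for (ii in seq_along(idx)) {
        i <- idx[ii]
        row <- m[i, ]
        b0 <- row[col_names(m, sprintf("b0[%d]", d$regc))]
        yr <- row[sprintf("yr[%d,%d]", d$regc, d$tc)]
        sta <- row[col_names(m, sprintf("sta[%d]", d$stac))]
        mu <- exp(b0 + row["b1"] * d$ef + yr + sta)
        r <- m[i, "r"]
        rep_counts <- rnbinom(d$Ncount, size = r, mu = mu)
        d_obs[ii] <- chisq_disc(d$count, mu)
        d_rep[ii] <- chisq_disc(rep_counts, mu)
      }
      out$counts <- tibble::tibble(model = "counts",
                                   discrepancy = "chi_squared",
                                   p_value = ppc_pvalue(d_obs, d_rep),
                                   n_draws = length(idx))
    }
    if (!is.null(d$Nage) && d$Nage > 0) {
      d_obs <- d_rep <- numeric(length(idx))
      for (ii in seq_along(idx)) {
        i <- idx[ii]
        row <- m[i, ]
        b0 <- row[col_names(m, sprintf("b0y[%d]", d$rega))]
        yr <- row[sprintf("yry[%d,%d]", d$rega, d$ta)]
        sta <- row[col_names(m, sprintf("stay[%d]", d$staa))]
        pY <- plogis(b0 + yr + sta)
        expct <- d$aged * pY
        rep_y <- rbinom(d$Nage, d$aged, pY)
        d_obs[ii] <- chisq_disc(d$yng, expct)
        d_rep[ii] <- chisq_disc(rep_y, expct)
      }
      out$ages <- tibble::tibble(model = "yearling",
                                 discrepancy = "chi_squared",
                                 p_value = ppc_pvalue(d_obs, d_rep),
                                 n_draws = length(idx))
    }
  })
  dplyr::bind_rows(out)
}
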