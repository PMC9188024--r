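test_that("gamma process density has the stated parameterization", {
  # shape 100, scale 0.5: mean 50, variance 25, by numeric integration
  f <- function(x) exp(population_process_logdensity(x, 100, 0.5))
  total <- integrate(f, 0, Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)
  mean_val <- integrate(function(x) x * f(x), 0, Inf)$value
  expect_equal(mean_val, 50, tolerance = 1e-4)
  var_val <- integrate(function(x) (x - 50)^2 * f(x), 0, Inf)$value
  expect_equal(var_val, 25, tolerance = 1e-4)
  # matches the reference gamma pdf at the mode
  expect_equal(population_process_logdensity(49.75, 100, 0.5),
               dgamma(49.75, shape = 100, rate = 2, log = TRUE))
  # scale -> 0: survivor mass collapses toward zero
  expect_gt(integrate(function(x)
    exp(population_process_logdensity(x, 100, 1e-4)), 0, 0.1)$value, 0.999)
  expect_error(population_process_logdensity(1, -1, 0.5), "shape")
  expect_error(population_process_logdensity(1, 10, 0), "scale")
})

test_that("zero-truncated normal density is correctly normalized", {
  # far from the boundary the truncation is negligible
  expect_lt(abs(truncnorm0_logpdf(50.3, 50, 1) -
                  dnorm(50.3, 50, 1, log = TRUE)), 1e-10)
  # centered at zero the half-normal doubles the density
  expect_equal(truncnorm0_logpdf(0.5, 0, 1), log(2 * dnorm(0.5)))
  # unit mass on the positive half-line for several parameter settings
  for (mu in c(-1, 0.3, 2)) {
    total <- integrate(function(x) exp(truncnorm0_logpdf(x, mu, 0.7)),
                       0, Inf)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  expect_error(truncnorm0_logpdf(1, 0, 0), "sd")
})

test_that("index likelihood peaks where the state matches the observed index", {
  summ <- tibble::tibble(
    region = 1, year = 2000:2004,
    logad_mean = log(c(10, 11, 9, 10, 10)), logad_sd = 0.1,
    ad1_mean = 3, ad1_sd = 0.5, ad2p_mean = 7, ad2p_sd = 0.8,
    g_mean = c(rep(0.3, 4), NA), g_sd = c(rep(0.05, 4), NA)
  )
  state <- tibble::tibble(year = 2000:2004, n = exp(summ$logad_mean),
                          nsurv = 7, nrecr = 3)
  ll_at <- function(scale) {
    s <- dplyr::mutate(state, n = n * scale)
    link_index_loglik(s, rep(0.3, 4), summ)
  }
  expect_gt(ll_at(1), ll_at(1.2))
  expect_gt(ll_at(1), ll_at(0.8))
  bad <- dplyr::mutate(summ, logad_sd = 0)
  expect_error(link_index_loglik(state, rep(0.3, 4), bad), "SDs")
})

test_that("transient-CJS closed-form examples hold", {
  # T = 2, certain residency, no predetermination: P(redetected) = phi * p
  lik_11 <- exp(cjs_history_loglik(c(1, 1), 1, 0, phi = 0.6, p = 0.5,
                                   pi_res = 1, rho = 0))
  expect_equal(lik_11, 0.30)
  # T = 2, pi = 0.6: history (1,0) with d = 0 sums the three pathways
  lik_10 <- exp(cjs_history_loglik(c(1, 0), 1, 0, phi = 0.6, p = 0.5,
                                   pi_res = 0.6, rho = 0))
  expect_equal(lik_10, 0.4 + 0.24 + 0.18)
  # invalid histories are rejected
  expect_error(cjs_history_loglik(c(1, 1), 2, 0, 0.5, 0.5, 0.5, 0.1),
               "before first_year")
})

test_that("marginalized likelihood equals the latent-state enumeration oracle", {
  set.seed(21)
  for (rep in 1:20) {
    Tn <- sample(2:5, 1)
    phi <- runif(Tn - 1, 0.2, 0.9)
    p <- runif(1, 0.1, 0.9)
    pi_res <- runif(1, 0.1, 0.95)
    rho <- runif(1, 0.05, 0.8)
    first <- sample(seq_len(Tn - 1), 1)
    y <- integer(Tn); y[first] <- 1L
    if (first < Tn)
      y[(first + 1):Tn] <- rbinom(Tn - first, 1, 0.4)
    d <- if (sum(y) > 1) rbinom(1, 1, 0.5) else rbinom(1, 1, 0.2)
    if (sum(y) == 1 && d == 1) d <- 0  # keep d consistent w.p. for clarity
    ours <- exp(cjs_history_loglik(y, first, d, phi, p, pi_res, rho))
    oracle <- enumerate_cjs_lik(y, first, d, phi, p, pi_res, rho)
    expect_equal(ours, oracle, tolerance = 1e-10)
  }
})

test_that("aggregated sufficient-statistic likelihood equals the per-individual sum", {
  cfg <- small_config(seed = 23)
  ds <- simulate_dataset(cfg)
  years <- sort(unique(ds$capture_table$year))
  stations <- sort(unique(ds$cmr$station_id))
  ss <- fullcycle:::cjs_suffstats(ds$cmr, years, stations)
  K <- 2; Tn <- length(years)
  set.seed(24)
  phi <- matrix(runif(K * (Tn - 1), 0.3, 0.9), K)
  pi_mat <- matrix(runif(K * Tn, 0.2, 0.9), K)
  p_st <- runif(length(stations), 0.2, 0.8)
  rho_st <- runif(length(stations), 0.1, 0.6)
  names(p_st) <- names(rho_st) <- stations
  kstation <- ds$cmr$region[match(stations, ds$cmr$station_id)]
  agg <- fullcycle:::cjs_suffstat_loglik(ss, phi, p_st, pi_mat, rho_st,
                                         kstation)
  # per-individual sum with station-specific p and rho
  per_ind <- sum(vapply(seq_len(nrow(ds$cmr)), function(i) {
    j <- match(ds$cmr$station_id[i], stations)
    cjs_history_loglik(
      as.integer(ds$cmr[i, paste0("det_", years)]),
      match(ds$cmr$first_year[i], years),
      ds$cmr$predetermined_resident[i],
      phi[ds$cmr$region[i], ], p_st[j], pi_mat[ds$cmr$region[i], ],
      rho_st[j])
  }, numeric(1)))
  expect_equal(agg, per_ind, tolerance = 1e-10)
  # scalar-parameter wrapper agrees too
  expect_equal(
    cjs_transient_logdensity(ds$cmr, phi, 0.5, 0.6, 0.3),
    sum(vapply(seq_len(nrow(ds$cmr)), function(i) {
      cjs_history_loglik(as.integer(ds$cmr[i, paste0("det_", years)]),
                         match(ds$cmr$first_year[i], years),
                         ds$cmr$predetermined_resident[i],
                         phi[ds$cmr$region[i], ], 0.5, rep(0.6, Tn), 0.3)
    }, numeric(1))), tolerance = 1e-10)
})

test_that("a small IPM fit preserves state additivity and summarizes cleanly", {
  ds <- simulate_dataset(small_config(seed = 25))
  s1 <- fit_stage1(ds$capture_table, ds$microage_table, tiny_mcmc(),
                   seed = 26)
  summ <- derive_age_indices(s1)
  ipm <- fit_ipm(ds$cmr, summ, ds$covariates, tiny_mcmc(), seed = 27)
  m <- draws_matrix(ipm$draws)
  K <- 2; Tn <- length(ipm$years)
  # n = nsurv + nrecr at every draw, exactly
  for (k in 1:K) for (t in c(1, Tn)) {
    expect_equal(m[, sprintf("n[%d,%d]", k, t)],
                 m[, sprintf("nsurv[%d,%d]", k, t)] +
                   m[, sprintf("nrecr[%d,%d]", k, t)],
                 tolerance = 1e-12)
  }
  expect_true(all(m[, sprintf("n[1,%d]", 1:Tn)] > 0))
  # linear predictors reproduce phi exactly (covariates all affect it)
  td <- tidy(ipm)
  expect_equal(nrow(td), 4 * K * 2)
  expect_true(all(td$prob_sign >= 0.5))
  gl <- glance(ipm)
  expect_equal(gl$individuals, nrow(ds$cmr))
  dem <- demographic_table(ipm)
  expect_true(all(dem$lower89 <= dem$upper89))
})

test_that("derived quantities match brute-force recomputation over draws", {
  ds <- simulate_dataset(small_config(seed = 28))
  s1 <- fit_stage1(ds$capture_table, ds$microage_table, tiny_mcmc(),
                   seed = 29)
  ipm <- fit_ipm(ds$cmr, derive_age_indices(s1), ds$covariates,
                 tiny_mcmc(), seed = 30)
  dq <- derive_quantities(ipm)
  m <- draws_matrix(ipm$draws)
  Tn <- length(ipm$years)
  # lambda for region 1, first transition
  lam_draws <- m[, "n[1,2]"] / m[, "n[1,1]"]
  row <- dq$lambda[dq$lambda$region == 1 &
                     dq$lambda$year == ipm$years[1], ]
  expect_equal(row$median, median(lam_draws))
  expect_equal(row$lower89, unname(quantile(lam_draws, 0.055)))
  # trend: geometric mean per draw
  lam_all <- sapply(1:(Tn - 1), function(t) m[, sprintf("n[1,%d]", t + 1)] /
                      m[, sprintf("n[1,%d]", t)])
  trend_draws <- (exp(rowMeans(log(lam_all))) - 1) * 100
  expect_equal(dq$trend$median[dq$trend$region == 1], median(trend_draws))
  # correlations per draw
  ns <- sapply(1:Tn, function(t) m[, sprintf("nsurv[1,%d]", t)])
  nr <- sapply(1:Tn, function(t) m[, sprintf("nrecr[1,%d]", t)])
  r_draws <- vapply(seq_len(nrow(m)), function(i) cor(ns[i, ], nr[i, ]),
                    numeric(1))
  got <- dq$correlations[dq$correlations$region == 1 &
                           dq$correlations$pair == "nsurv_nrecr", ]
  expect_equal(got$median, median(r_draws))
  expect_true(all(dq$correlations$median >= -1 &
                    dq$correlations$median <= 1))
  # phi / lambda, overall (mean over transitions per draw)
  phi1 <- sapply(1:(Tn - 1), function(t) m[, sprintf("phi[1,%d]", t)])
  pl_draws <- rowMeans(phi1 / lam_all)
  overall <- dq$phi_lambda[dq$phi_lambda$region == 1 &
                             is.na(dq$phi_lambda$year), ]
  expect_equal(overall$median, median(pl_draws))

  # Freeman-Tukey PPC on the CJS component runs and is bounded
  ppc <- posterior_predictive_check(ipm, "freeman_tukey", seed = 31,
                                    max_draws = 60)
  expect_true(ppc$p_value >= 0 && ppc$p_value <= 1)
})

test_that("year misalignment fails fast", {
  ds <- simulate_dataset(small_config(seed = 32))
  s1 <- fit_stage1(ds$capture_table, ds$microage_table, tiny_mcmc(),
                   seed = 33)
  summ <- derive_age_indices(s1)
  cov_bad <- ds$covariates[ds$covariates$year > min(ds$covariates$year) + 3, ]
  expect_error(fit_ipm(ds$cmr, summ, cov_bad, tiny_mcmc(), seed = 34),
               "covariates")
  cmr_bad <- dplyr::rename(ds$cmr, det_1800 = paste0("det_", min(ds$covariates$year)))
  expect_error(fit_ipm(cmr_bad, summ, ds$covariates, tiny_mcmc(), seed = 35),
               "misaligned")
})
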