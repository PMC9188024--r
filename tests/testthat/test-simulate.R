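test_that("simulated covariates are standardized, deterministic, and scale-invariant", {
  cfg <- sim_config(n_years = 10, seed = 5)
  cov <- simulate_covariates(cfg)
  for (cv in c("cmd_b_std", "cmd_w_std", "cmd_m_res_std", "elr_m_std")) {
    expect_lt(abs(mean(cov[[cv]])), 1e-10)
    expect_equal(sd(cov[[cv]]), 1, tolerance = 1e-10)
  }
  expect_identical(cov, simulate_covariates(cfg))
  # standardization cancels the raw scale entirely
  cov2 <- simulate_covariates(sim_config(n_years = 10, seed = 5,
                                         covariate_sd = 2))
  expect_equal(cov2$cmd_b_std, cov$cmd_b_std)
  expect_error(sim_config(n_years = 2), "n_years")
})

test_that("simulated counts match negative-binomial moments", {
  # degenerate config: no random effects, no effort effect, mean 10,
  # near-Poisson dispersion -> sample mean within 3 SE of 10
  cfg <- sim_config(n_regions = 1, stations_per_region = 400, n_years = 25,
                    mean_count_intercepts = log(10), effort_effect = 0,
                    sigma_year = 0, sigma_station = 0, nb_dispersion = 1e6,
                    missing_prob = 0, initial_n = 10, seed = 21)
  counts <- simulate_counts(cfg)
  n <- nrow(counts)
  expect_equal(n, 10000)
  se <- sqrt((10 + 100 / 1e6) / n)
  expect_lt(abs(mean(counts$ahy_count) - 10), 3 * se)

  # r = 1, mu = 1: P(0) = (r/(r+mu))^r = 0.5
  cfg0 <- sim_config(n_regions = 1, stations_per_region = 400, n_years = 25,
                     mean_count_intercepts = 0, effort_effect = 0,
                     sigma_year = 0, sigma_station = 0, nb_dispersion = 1,
                     missing_prob = 0, initial_n = 1, seed = 22)
  c0 <- simulate_counts(cfg0)
  p0 <- mean(c0$ahy_count == 0)
  expect_lt(abs(p0 - 0.5), 3 * sqrt(0.25 / nrow(c0)))

  # a region with zero stations yields an empty region, not a failure
  cfg_empty <- sim_config(stations_per_region = c(5, 0), n_years = 5,
                          seed = 3)
  ce <- simulate_counts(cfg_empty)
  expect_equal(sum(ce$region == 2), 0)
  expect_gt(sum(ce$region == 1), 0)
})

test_that("microage simulation respects the yearling model and aging fraction", {
  cfg <- sim_config(n_regions = 1, stations_per_region = 100, n_years = 4,
                    mean_count_intercepts = log(25), effort_effect = 0,
                    sigma_year = 0, sigma_station = 0, missing_prob = 0,
                    yearling_intercepts = 0, sigma_year_age = 0,
                    sigma_station_age = 0, microage_fraction = 1,
                    initial_n = 25, seed = 31)
  counts <- simulate_counts(cfg)
  ages <- simulate_ages(cfg, counts)
  n <- nrow(ages)
  expect_gt(n, 5000)
  # inverse-logit(0) = 0.5
  expect_lt(abs(mean(ages$is_yearling) - 0.5), 3 * sqrt(0.25 / n))

  # 70% microaged leaves ~70% of captures with a flag
  ages70 <- simulate_ages(cfg, counts, microage_fraction = 0.7)
  frac <- nrow(ages70) / sum(counts$ahy_count)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / sum(counts$ahy_count)))

  # no microaging at all: empty table
  expect_equal(nrow(simulate_ages(cfg, counts, microage_fraction = 0)), 0)
})

test_that("CMR histories follow the transient residency process", {
  years <- function(cfg) cfg$first_year + seq_len(cfg$n_years) - 1
  base <- list(n_regions = 1, stations_per_region = 30, n_years = 3,
               initial_n = 20, new_fraction = 1,
               phi_covariate_effects = matrix(0, 1, 4),
               gamma_covariate_effects = matrix(0, 1, 4),
               sigma_year_phi = 0, sigma_year_gamma = 0)

  # deterministic limit: everyone resident, survives, and is captured
  cfg1 <- do.call(sim_config, c(base, list(
    residency_prob = 1, capture_prob = 1, phi_intercepts = 20, seed = 41)))
  cmr1 <- simulate_cmr(cfg1, simulate_covariates(cfg1))
  det <- as.matrix(cmr1[paste0("det_", years(cfg1))])
  first <- match(cmr1$first_year, years(cfg1))
  for (i in seq_len(nrow(det)))
    expect_true(all(det[i, first[i]:ncol(det)] == 1))

  # all transients: no one is ever seen again
  cfg0 <- do.call(sim_config, c(base, list(residency_prob = 0, seed = 42)))
  cmr0 <- simulate_cmr(cfg0, simulate_covariates(cfg0))
  det0 <- as.matrix(cmr0[paste0("det_", years(cfg0))])
  expect_true(all(rowSums(det0) == 1))
  expect_true(all(cmr0$predetermined_resident == 0))

  # closed form: P(redetected next year) = pi * phi * p = 0.216
  argsp <- utils::modifyList(base, list(
    residency_prob = 0.6, capture_prob = 0.6,
    phi_intercepts = qlogis(0.6), stations_per_region = 300,
    initial_n = 30, seed = 43))
  cfgp <- do.call(sim_config, argsp)
  cmrp <- simulate_cmr(cfgp, simulate_covariates(cfgp))
  detp <- as.matrix(cmrp[paste0("det_", years(cfgp))])
  firstp <- match(cmrp$first_year, years(cfgp))
  cohort <- firstp < cfgp$n_years
  hit <- detp[cbind(which(cohort), firstp[cohort] + 1)]
  p_hat <- mean(hit)
  expect_lt(abs(p_hat - 0.216), 3 * sqrt(0.216 * (1 - 0.216) / sum(cohort)))
})

test_that("population process satisfies additivity and the stationary case", {
  cfg <- sim_config(seed = 51,
                    phi_intercepts = qlogis(0.65),
                    gamma_intercepts = log(0.35),
                    phi_covariate_effects = matrix(0, 2, 4),
                    gamma_covariate_effects = matrix(0, 2, 4),
                    sigma_year_phi = 0, sigma_year_gamma = 0)
  pv <- simulate_population_and_veg(cfg, simulate_covariates(cfg))
  expect_equal(pv$truth$n, pv$truth$nsurv + pv$truth$nrecr)
  expect_true(all(pv$truth$n > 0))
  # lambda = phi + gamma = 1: E[n_t] = n_0; average over replicate worlds
  finals <- vapply(1:40, function(s) {
    cfg_s <- sim_config(seed = 1000 + s,
                        phi_intercepts = qlogis(0.65),
                        gamma_intercepts = log(0.35),
                        phi_covariate_effects = matrix(0, 2, 4),
                        gamma_covariate_effects = matrix(0, 2, 4),
                        sigma_year_phi = 0, sigma_year_gamma = 0,
                        n_years = 10, initial_n = c(20, 20))
    pv_s <- simulate_population_and_veg(cfg_s, simulate_covariates(cfg_s))
    mean(pv_s$truth$n[pv_s$truth$year == max(pv_s$truth$year)])
  }, numeric(1))
  # Var(n_T) grows ~ n0 * t * (phi^2+gamma^2); 3-SE Monte-Carlo band
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 20), 3 * se)
})

test_that("noiseless vegetation responses recover the generative slope exactly", {
  cfg <- sim_config(seed = 61, veg_sigma = c(evi_area = 0, maturity = 0))
  pv <- simulate_population_and_veg(cfg, simulate_covariates(cfg))
  f1 <- lm(evi_area_deviation ~ cmd_b, data = pv$veg)
  f2 <- lm(maturity_deviation ~ cmd_b, data = pv$veg)
  expect_equal(unname(coef(f1)[2]), cfg$veg_slopes[["evi_area"]])
  expect_equal(unname(coef(f2)[2]), cfg$veg_slopes[["maturity"]])
})

test_that("the full dataset is reproducible from config + seed", {
  cfg <- small_config(seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$capture_table, d2$capture_table)
  expect_identical(d1$microage_table, d2$microage_table)
  expect_identical(d1$cmr, d2$cmr)
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$truth$states, d2$truth$states)
  d3 <- simulate_dataset(small_config(seed = 100))
  expect_false(identical(d1$capture_table, d3$capture_table))
  # latent additivity and CMR first-capture invariants
  expect_equal(d1$truth$states$n,
               d1$truth$states$nsurv + d1$truth$states$nrecr)
  det <- as.matrix(d1$cmr[grep("^det_", names(d1$cmr))])
  first <- match(d1$cmr$first_year, sort(unique(d1$capture_table$year)))
  expect_true(all(det[cbind(seq_len(nrow(det)), first)] == 1))
})
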