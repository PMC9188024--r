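# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Simulation configuration
#'
#' Ground-truth parameters for the synthetic-data generator. Defaults
#' describe the study system the package models: two breeding regions (a
#' small montane network of 9 stations and a larger lowland network of 35)
#' monitored over 28 breeding seasons, with negative-binomial adult capture
#' counts, Bernoulli yearling microage flags, transient-corrected
#' capture-recapture histories, a gamma survival/recruitment population
#' process, and linear vegetation-greenness responses to climate.
#'
#' @param n_regions number of breeding regions.
#' @param stations_per_region integer vector of stations per region.
#' @param n_years number of breeding seasons.
#' @param first_year calendar year of the first season.
#' @param mean_count_intercepts per-region log-scale intercepts of the mean
#'   adult capture count per station-year.
#' @param effort_effect regression coefficient of the effort ratio in the
#'   log-mean count model.
#' @param effort_sigma lognormal SD of the station-year effort ratio
#'   (median 1).
#' @param sigma_year per-region SD of random region-by-year count effects.
#' @param sigma_station SD of random station effects in the count model.
#' @param nb_dispersion negative-binomial dispersion `r`
#'   (success probability `r / (r + mu)`).
#' @param missing_prob probability a station-year was not operated (row
#'   absent, not zero).
#' @param yearling_intercepts per-region logit-scale intercepts of yearling
#'   probability.
#' @param sigma_year_age,sigma_station_age random-effect SDs of the yearling
#'   model.
#' @param microage_fraction fraction of adult captures carrying a microage
#'   determination.
#' @param phi_intercepts per-region logit-scale adult apparent-survival
#'   intercepts.
#' @param phi_covariate_effects region x 4 matrix of survival covariate
#'   effects (logit scale), columns in covariate order
#'   `cmd_b, cmd_w, cmd_m_res, elr_m`.
#' @param sigma_year_phi per-region SD of survival year effects.
#' @param gamma_intercepts per-region log-scale recruitment intercepts.
#' @param gamma_covariate_effects region x 4 matrix of recruitment effects
#'   (log scale).
#' @param sigma_year_gamma per-region SD of recruitment year effects.
#' @param residency_prob probability a newly banded adult is a resident
#'   (not a transient).
#' @param capture_prob annual recapture probability of a live resident.
#' @param predetermine_prob probability a resident is recaptured >= 7 days
#'   apart within its first season (predetermined resident).
#' @param new_fraction expected newly banded individuals per station-year as
#'   a fraction of the regional abundance index.
#' @param initial_n per-region initial abundance index.
#' @param process_scale ratio of the true regional population size to the
#'   per-station abundance index. Demographic gamma noise operates at the
#'   population scale, so the index trajectory has variance
#'   `n * rate^2 / process_scale` per transition; the default (25, roughly
#'   stations x birds per index unit) yields realistic ~10%/yr variation in
#'   annual growth instead of the absorbing random walk that index-scale
#'   shapes would imply.
#' @param covariate_sd SD of raw simulated covariate deviations.
#' @param veg_slopes named vector: linear response of `evi_area` and
#'   `maturity` deviations to the breeding-grounds drought deviation.
#' @param veg_sigma named vector of residual SDs for the two responses.
#' @param seed integer seed; identical config + seed reproduce every table
#'   exactly.
#' @return list of class `fc_sim_config`.
#' @export
sim_config <- function(n_regions = 2,
                       stations_per_region = c(9, 35),
                       n_years = 28,
                       first_year = 1992,
                       mean_count_intercepts = log(c(1.8, 1.25)),
                       effort_effect = 0.5,
                       effort_sigma = 0.3,
                       sigma_year = c(0.35, 0.35),
                       sigma_station = 0.6,
                       nb_dispersion = 1.5,
                       missing_prob = 0.1,
                       yearling_intercepts = qlogis(c(0.32, 0.35)),
                       sigma_year_age = c(0.3, 0.3),
                       sigma_station_age = 0.4,
                       microage_fraction = 0.7,
                       phi_intercepts = qlogis(c(0.69, 0.62)),
                       phi_covariate_effects = rbind(
                         c(0.23, -0.14, 0.18, -0.19),
                         c(-0.01, -0.14, -0.11, 0.03)
                       ),
                       sigma_year_phi = c(0.3, 0.3),
                       gamma_intercepts = log(c(0.32, 0.35)),
                       gamma_covariate_effects = rbind(
                         c(-0.01, 0.01, 0.00, -0.02),
                         c(0.06, -0.13, 0.01, 0.11)
                       ),
                       sigma_year_gamma = c(0.12, 0.15),
                       residency_prob = 0.6,
                       capture_prob = 0.4,
                       predetermine_prob = 0.3,
                       new_fraction = 1.6,
                       initial_n = c(1.8, 1.25),
                       process_scale = 25,
                       covariate_sd = 1,
                       veg_slopes = c(evi_area = -10, maturity = -4.6),
                       veg_sigma = c(evi_area = 8, maturity = 4),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_regions <- as.integer(n_regions)
  cfg$n_years <- as.integer(n_years)
  cfg$stations_per_region <- as.integer(stations_per_region)
  rec <- function(x) rep_len(x, cfg$n_regions)
  for (f in c("mean_count_intercepts", "sigma_year", "yearling_intercepts",
              "sigma_year_age", "phi_intercepts", "sigma_year_phi",
              "gamma_intercepts", "sigma_year_gamma", "initial_n"))
    cfg[[f]] <- rec(cfg[[f]])
  for (f in c("phi_covariate_effects", "gamma_covariate_effects")) {
    m <- cfg[[f]]
    if (is.null(dim(m))) m <- matrix(rep(m, each = cfg$n_regions), cfg$n_regions)
    if (nrow(m) != cfg$n_regions)
      m <- m[rep_len(seq_len(nrow(m)), cfg$n_regions), , drop = FALSE]
    if (ncol(m) != 4)
      fc_stop("%s must have 4 covariate columns", f)
    cfg[[f]] <- m
  }
  if (length(cfg$stations_per_region) != cfg$n_regions)
    fc_stop("stations_per_region must have one entry per region")
  probs <- c(cfg$residency_prob, cfg$capture_prob, cfg$predetermine_prob,
             cfg$microage_fraction, cfg$missing_prob)
  if (any(probs < 0 | probs > 1)) fc_stop("probabilities must lie in [0, 1]")
  core_probs <- c(cfg$residency_prob, cfg$capture_prob)
  if (any(core_probs <= 0 | core_probs >= 1)) {
    # boundary values are allowed for the deterministic-limit tests; the
    # generator itself tolerates them
  }
  sds <- c(cfg$sigma_year, cfg$sigma_station, cfg$sigma_year_age,
           cfg$sigma_station_age, cfg$sigma_year_phi, cfg$sigma_year_gamma,
           cfg$effort_sigma, cfg$covariate_sd)
  if (any(sds < 0)) fc_stop("SD parameters must be >= 0")
  if (cfg$nb_dispersion <= 0) fc_stop("nb_dispersion must be > 0")
  if (cfg$process_scale <= 0) fc_stop("process_scale must be > 0")
  if (cfg$n_years < 3) fc_stop("n_years must be >= 3")
  if (any(cfg$initial_n <= 0)) fc_stop("initial_n must be > 0")
  structure(cfg, class = "fc_sim_config")
}

# station registry implied by a config
station_registry <- function(config) {
  tibble::tibble(
    region = rep(seq_len(config$n_regions), config$stations_per_region)
  ) |>
    dplyr::mutate(station_id = sprintf("st%03d", dplyr::row_number()))
}

sim_years <- function(config) config$first_year + seq_len(config$n_years) - 1L

#' Simulate standardized climate covariates
#'
#' One value per covariate per region-year, drawn independently from
#' `Normal(0, covariate_sd^2)` and then standardized to mean 0, SD 1 across
#' all region-years (the form in which covariates enter the demographic
#' models).
#'
#' @param config an [sim_config()].
#' @return tibble of class `fc_covariates`: `region`, `year`, raw columns
#'   (`cmd_b`, `cmd_w`, `cmd_m_res`, `elr_m`) and standardized `*_std`
#'   columns.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "fc_sim_config"))
  if (config$n_years < 3) fc_stop("n_years must be >= 3")
  covs <- c("cmd_b", "cmd_w", "cmd_m_res", "elr_m")
  with_seed(derive_seeds(config$seed, 10)[1], {
    out <- tidyr::expand_grid(region = seq_len(config$n_regions),
                              year = sim_years(config))
    scaling <- list()
    for (cv in covs) {
      raw <- rnorm(nrow(out), 0, config$covariate_sd)
      out[[cv]] <- raw
      z <- standardize(raw)
      out[[paste0(cv, "_std")]] <- as.numeric(z)
      scaling[[cv]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
    }
    structure(out, scaling = scaling,
              class = c("fc_covariates", class(out)))
  })
}

# region x year x 4 array of standardized covariates
covariate_array <- function(covariates) {
  covs <- c("cmd_b_std", "cmd_w_std", "cmd_m_res_std", "elr_m_std")
  regions <- sort(unique(covariates$region))
  years <- sort(unique(covariates$year))
  X <- array(NA_real_, c(length(regions), length(years), 4),
             dimnames = list(NULL, years, covs))
  for (i in seq_along(regions)) for (j in seq_along(years)) {
    row <- covariates[covariates$region == regions[i] &
                        covariates$year == years[j], ]
    if (nrow(row) != 1) fc_stop("covariates missing region %s year %s",
                                regions[i], years[j])
    X[i, j, ] <- as.numeric(row[1, covs])
  }
  X
}

#' Simulate station-year adult capture counts
#'
#' Negative-binomial adult captures per operated station-year under the
#' log-linear mixed model: region intercept + effort effect + random
#' region-by-year effect + random station effect, with dispersion `r`
#' (success probability `r / (r + mu)`). Station-years not operated are
#' absent from the table.
#'
#' @param config an [sim_config()].
#' @param covariates unused by the count model (counts carry no climate
#'   terms); accepted for a uniform stage signature.
#' @return tibble of class `fc_capture_table`: `station_id`, `region`,
#'   `year`, `effort_ratio`, `ahy_count`. Realized random effects are kept
#'   in the `truth` attribute.
#' @export
simulate_counts <- function(config, covariates = NULL) {
  stopifnot(inherits(config, "fc_sim_config"))
  reg <- station_registry(config)
  years <- sim_years(config)
  with_seed(derive_seeds(config$seed, 10)[2], {
    yr_eff <- matrix(rnorm(config$n_regions * config$n_years, 0,
                           rep(config$sigma_year, config$n_years)),
                     config$n_regions, config$n_years)
    sta_eff <- rnorm(nrow(reg), 0, config$sigma_station)
    grid <- tidyr::expand_grid(reg, year = years) |>
      dplyr::mutate(t = match(.data$year, years),
                    sta = sta_eff[match(.data$station_id, reg$station_id)])
    grid$effort_ratio <- rlnorm(nrow(grid), 0, config$effort_sigma)
    mu <- exp(config$mean_count_intercepts[grid$region] +
                config$effort_effect * grid$effort_ratio +
                yr_eff[cbind(grid$region, grid$t)] + grid$sta)
    grid$ahy_count <- rnbinom(nrow(grid), size = config$nb_dispersion, mu = mu)
    operated <- runif(nrow(grid)) >= config$missing_prob
    out <- grid[operated, c("station_id", "region", "year",
                            "effort_ratio", "ahy_count")]
    structure(tibble::as_tibble(out),
              truth = list(yr = yr_eff, sta = sta_eff),
              class = c("fc_capture_table", class(tibble::tibble())))
  })
}

#' Simulate microage (yearling) records
#'
#' One Bernoulli yearling flag per captured adult; a configurable fraction
#' of adults is left unmicroaged (missing completely at random) and
#' excluded from the returned table.
#'
#' When the latent population `truth` is supplied (as [simulate_dataset()]
#' does), the region-year yearling probability is the realized recruit
#' fraction `nrecr / n` on the logit scale plus station effects, keeping
#' the age-structure data coherent with the population process the IPM
#' assumes. Without `truth`, flags follow the free-standing logit-linear
#' mixed model (region intercept + region-by-year + station effects).
#'
#' @param config an [sim_config()].
#' @param capture_table output of [simulate_counts()].
#' @param microage_fraction overrides `config$microage_fraction` if given.
#' @param truth optional latent-state table from
#'   [simulate_population_and_veg()].
#' @return tibble: `individual_id`, `station_id`, `region`, `year`,
#'   `is_yearling`, for microaged adults only.
#' @export
simulate_ages <- function(config, capture_table, microage_fraction = NULL,
                          truth = NULL) {
  stopifnot(inherits(config, "fc_sim_config"))
  frac <- microage_fraction %||% config$microage_fraction
  years <- sim_years(config)
  reg <- station_registry(config)
  with_seed(derive_seeds(config$seed, 10)[3], {
    if (is.null(truth)) {
      yr_eff <- matrix(rnorm(config$n_regions * config$n_years, 0,
                             rep(config$sigma_year_age, config$n_years)),
                       config$n_regions, config$n_years)
      logit_base <- matrix(config$yearling_intercepts, config$n_regions,
                           config$n_years) + yr_eff
    } else {
      frac_recr <- matrix(NA_real_, config$n_regions, config$n_years)
      for (k in seq_len(config$n_regions)) {
        tk <- truth[truth$region == k, ]
        frac_recr[k, ] <- (tk$nrecr / tk$n)[match(years, tk$year)]
      }
      logit_base <- qlogis(frac_recr)
    }
    sta_eff <- rnorm(nrow(reg), 0, config$sigma_station_age)
    rows <- capture_table[rep(seq_len(nrow(capture_table)),
                              capture_table$ahy_count), ]
    if (nrow(rows) == 0) {
      return(tibble::tibble(individual_id = character(), station_id = character(),
                            region = integer(), year = integer(),
                            is_yearling = integer()))
    }
    t <- match(rows$year, years)
    sidx <- match(rows$station_id, reg$station_id)
    pY <- plogis(logit_base[cbind(rows$region, t)] + sta_eff[sidx])
    out <- tibble::tibble(
      individual_id = sprintf("age%06d", seq_len(nrow(rows))),
      station_id = rows$station_id,
      region = rows$region,
      year = rows$year,
      is_yearling = rbinom(nrow(rows), 1, pY)
    )
    keep <- runif(nrow(out)) < frac
    out[keep, ]
  })
}

# realized demographic rates (with year effects) for each region-transition
simulate_rates <- function(config, covariates) {
  X <- covariate_array(covariates)
  Tn <- config$n_years
  with_seed(derive_seeds(config$seed, 10)[4], {
    yr_phi <- matrix(rnorm(config$n_regions * (Tn - 1), 0,
                           rep(config$sigma_year_phi, Tn - 1)),
                     config$n_regions, Tn - 1)
    yr_gam <- matrix(rnorm(config$n_regions * (Tn - 1), 0,
                           rep(config$sigma_year_gamma, Tn - 1)),
                     config$n_regions, Tn - 1)
    purrr::map_dfr(seq_len(config$n_regions), function(k) {
      lin_phi <- config$phi_intercepts[k] +
        drop(X[k, 1:(Tn - 1), ] %*% config$phi_covariate_effects[k, ]) +
        yr_phi[k, ]
      lin_gam <- config$gamma_intercepts[k] +
        drop(X[k, 1:(Tn - 1), ] %*% config$gamma_covariate_effects[k, ]) +
        yr_gam[k, ]
      tibble::tibble(region = k, year = sim_years(config)[1:(Tn - 1)],
                     phi = plogis(lin_phi), gamma = exp(lin_gam))
    })
  })
}

#' Simulate the latent population process and vegetation responses
#'
#' Iterates the first-order Markovian gamma process forward: survivors and
#' recruits in year `t` are gamma draws with shape equal to last year's
#' total and scales equal to the realized survival and recruitment rates.
#' Also simulates annual vegetation-greenness (EVI area) and maturity-date
#' deviations as linear responses to the raw breeding-grounds drought
#' deviation plus normal noise.
#'
#' @param config an [sim_config()].
#' @param covariates output of [simulate_covariates()].
#' @param rates optional realized rate table (`region`, `year`, `phi`,
#'   `gamma`); drawn from the config if `NULL`.
#' @return list with `truth` (tibble: `region`, `year`, `n`, `nsurv`,
#'   `nrecr`, `phi`, `gamma`) and `veg` (tibble: `region`, `year`,
#'   `cmd_b`, `evi_area_deviation`, `maturity_deviation`).
#' @export
simulate_population_and_veg <- function(config, covariates, rates = NULL) {
  stopifnot(inherits(config, "fc_sim_config"))
  if (any(config$initial_n <= 0)) fc_stop("initial_n must be > 0")
  rates <- rates %||% simulate_rates(config, covariates)
  years <- sim_years(config)
  Tn <- config$n_years
  with_seed(derive_seeds(config$seed, 10)[5], {
    truth <- purrr::map_dfr(seq_len(config$n_regions), function(k) {
      rk <- rates[rates$region == k, ]
      phi <- rk$phi[match(years[1:(Tn - 1)], rk$year)]
      gam <- rk$gamma[match(years[1:(Tn - 1)], rk$year)]
      n <- nsurv <- nrecr <- numeric(Tn)
      n[1] <- config$initial_n[k]
      nsurv[1] <- n[1] * phi[1] / (phi[1] + gam[1])
      nrecr[1] <- n[1] - nsurv[1]
      cs <- config$process_scale
      for (t in 2:Tn) {
        nsurv[t] <- rgamma(1, shape = cs * n[t - 1], scale = phi[t - 1] / cs)
        nrecr[t] <- rgamma(1, shape = cs * n[t - 1], scale = gam[t - 1] / cs)
        n[t] <- nsurv[t] + nrecr[t]
      }
      tibble::tibble(region = k, year = years, n = n, nsurv = nsurv,
                     nrecr = nrecr, phi = c(phi, NA), gamma = c(gam, NA))
    })
    cb <- covariates[order(covariates$region, covariates$year), ]
    veg <- tibble::tibble(
      region = cb$region, year = cb$year, cmd_b = cb$cmd_b,
      evi_area_deviation = config$veg_slopes[["evi_area"]] * cb$cmd_b +
        rnorm(nrow(cb), 0, config$veg_sigma[["evi_area"]]),
      maturity_deviation = config$veg_slopes[["maturity"]] * cb$cmd_b +
        rnorm(nrow(cb), 0, config$veg_sigma[["maturity"]])
    )
    list(truth = truth, veg = veg)
  })
}

#' Simulate capture-mark-recapture histories with transients
#'
#' Newly banded adults per station-year are Poisson with mean proportional
#' to the (rounded) regional abundance index. Each individual is a resident
#' with probability `residency_prob`; residents may be predetermined as
#' residents within their first season with probability `predetermine_prob`,
#' survive between seasons with the realized region-year survival, and are
#' redetected while alive with probability `capture_prob`. Transients are
#' never seen after their first season.
#'
#' @param config an [sim_config()].
#' @param covariates output of [simulate_covariates()].
#' @param truth optional latent-state table from
#'   [simulate_population_and_veg()] (used for banding sample sizes and
#'   shared survival); regenerated if `NULL`.
#' @return tibble of class `fc_cmr`: `individual_id`, `station_id`,
#'   `region`, `first_year`, `predetermined_resident`, and wide detection
#'   columns `det_<year>`. The `truth` attribute records residency and
#'   alive states.
#' @export
simulate_cmr <- function(config, covariates, truth = NULL) {
  stopifnot(inherits(config, "fc_sim_config"))
  if (is.null(truth)) {
    rates <- simulate_rates(config, covariates)
    truth <- simulate_population_and_veg(config, covariates, rates)$truth
  }
  years <- sim_years(config)
  Tn <- config$n_years
  reg <- station_registry(config)
  phi <- matrix(NA_real_, config$n_regions, Tn - 1)
  for (k in seq_len(config$n_regions)) {
    tk <- truth[truth$region == k, ]
    phi[k, ] <- tk$phi[match(years[1:(Tn - 1)], tk$year)]
  }
  nidx <- matrix(NA_real_, config$n_regions, Tn)
  for (k in seq_len(config$n_regions)) {
    tk <- truth[truth$region == k, ]
    nidx[k, ] <- tk$n[match(years, tk$year)]
  }
  with_seed(derive_seeds(config$seed, 10)[6], {
    recs <- list()
    id <- 0L
    for (j in seq_len(nrow(reg))) {
      k <- reg$region[j]
      for (t in seq_len(Tn)) {
        n_new <- rpois(1, config$new_fraction * round(nidx[k, t]))
        if (n_new == 0) next
        for (b in seq_len(n_new)) {
          id <- id + 1L
          R <- rbinom(1, 1, config$residency_prob)
          d <- if (R == 1) rbinom(1, 1, config$predetermine_prob) else 0L
          det <- integer(Tn)
          det[t] <- 1L
          alive <- R == 1
          if (alive && t < Tn) {
            for (tt in (t + 1):Tn) {
              alive <- alive && (runif(1) < phi[k, tt - 1])
              if (!alive) break
              det[tt] <- rbinom(1, 1, config$capture_prob)
            }
          }
          recs[[id]] <- list(station_id = reg$station_id[j], region = k,
                             first_year = as.integer(years[t]),
                             d = as.integer(d), det = det, R = as.integer(R))
        }
      }
    }
    if (id == 0) fc_stop("no individuals simulated; increase initial_n")
    det_mat <- do.call(rbind, lapply(recs, `[[`, "det"))
    colnames(det_mat) <- paste0("det_", years)
    out <- tibble::tibble(
      individual_id = sprintf("ind%06d", seq_len(id)),
      station_id = vapply(recs, `[[`, character(1), "station_id"),
      region = vapply(recs, `[[`, integer(1), "region"),
      first_year = vapply(recs, `[[`, integer(1), "first_year"),
      predetermined_resident = vapply(recs, `[[`, integer(1), "d")
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(det_mat))
    structure(out,
              truth = list(resident = vapply(recs, `[[`, integer(1), "R")),
              class = c("fc_cmr", class(tibble::tibble())))
  })
}

#' Simulate a complete synthetic study dataset
#'
#' Runs every generator stage with sub-seeds derived from `config$seed` and
#' returns all tables plus the ground truth, so any downstream stage can be
#' tested for parameter recovery.
#'
#' @param config an [sim_config()].
#' @return list of class `fc_sim_dataset` with elements `capture_table`,
#'   `microage_table`, `cmr`, `covariates`, `veg_table`, `truth` (config,
#'   realized rates and latent states).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "fc_sim_config"))
  covariates <- simulate_covariates(config)
  rates <- simulate_rates(config, covariates)
  pv <- simulate_population_and_veg(config, covariates, rates)
  counts <- simulate_counts(config, covariates)
  ages <- simulate_ages(config, counts, truth = pv$truth)
  cmr <- simulate_cmr(config, covariates, pv$truth)
  structure(
    list(capture_table = counts, microage_table = ages, cmr = cmr,
         covariates = covariates, veg_table = pv$veg,
         truth = list(config = config, states = pv$truth, rates = rates)),
    class = "fc_sim_dataset"
  )
}

#' @export
print.fc_sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<fc_sim_dataset> %d regions, %d stations, %d years | %d station-years, %d aged birds, %d CMR individuals\n",
    x$truth$config$n_regions, sum(x$truth$config$stations_per_region),
    x$truth$config$n_years, nrow(x$capture_table), nrow(x$microage_table),
    nrow(x$cmr)))
  invisible(x)
}
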