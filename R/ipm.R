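#' Gamma population-process log-density
#'
#' Log-density of the first-order Markovian gamma transition used for both
#' survivors and recruits: the new count is gamma with shape equal to last
#' year's total `n_prev` and scale equal to the rate parameter (survival
#' `phi` or recruitment `gamma`), so the expectation is `n_prev * rate` and
#' the variance `n_prev * rate^2` — the continuous analogue of binomial
#' survival / Poisson recruitment.
#'
#' @param x realized survivors (or recruits), > 0.
#' @param n_prev previous year's total, > 0 (gamma shape).
#' @param rate scale parameter: survival probability in (0,1) or
#'   recruitment rate > 0.
#' @return log-density (vectorized).
#' @export
population_process_logdensity <- function(x, n_prev, rate) {
  if (any(n_prev <= 0)) fc_stop("gamma shape (previous total) must be > 0")
  if (any(rate <= 0)) fc_stop("gamma scale (rate parameter) must be > 0")
  dgamma(x, shape = n_prev, scale = rate, log = TRUE)
}

#' Zero-truncated normal log-density
#'
#' Normal density restricted to the positive half-line and renormalized by
#' the upper-tail mass `1 - CDF(0)`; the form in which the age-specific
#' index summaries inform survivors, recruits and the recruitment rate.
#'
#' @param x observation (> 0).
#' @param mean,sd normal location and scale (`sd > 0`).
#' @return log-density (vectorized).
#' @export
truncnorm0_logpdf <- function(x, mean, sd) {
  if (any(sd <= 0)) fc_stop("sd must be > 0")
  ifelse(x < 0, -Inf,
         dnorm(x, mean, sd, log = TRUE) -
           pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

#' Index-likelihood contribution of the population state
#'
#' Sums the four stage-linking log-likelihood terms for one region:
#' mean log abundance index ~ Normal(log n, s^2); yearling-recruit index ~
#' half-line-truncated Normal centered at recruits; older-adult index
#' centered at survivors; observed recruitment centered at the recruitment
#' rate.
#'
#' @param state tibble with columns `year`, `n`, `nsurv`, `nrecr`.
#' @param gamma_rate numeric vector of recruitment rates for transitions
#'   (length `nrow(state) - 1`).
#' @param summaries one region's rows of an index-summaries table.
#' @return total log-likelihood (scalar).
#' @export
link_index_loglik <- function(state, gamma_rate, summaries) {
  s <- summaries[match(state$year, summaries$year), ]
  if (any(c(s$logad_sd, s$ad1_sd, s$ad2p_sd) <= 0, na.rm = TRUE))
    fc_stop("index summary SDs must be > 0")
  Tn <- nrow(state)
  ll <- sum(dnorm(s$logad_mean, log(state$n), s$logad_sd, log = TRUE)) +
    sum(truncnorm0_logpdf(s$ad1_mean, state$nrecr, s$ad1_sd)) +
    sum(truncnorm0_logpdf(s$ad2p_mean, state$nsurv, s$ad2p_sd))
  g_ok <- which(!is.na(s$g_mean[-Tn]))
  if (length(g_ok) > 0)
    ll <- ll + sum(truncnorm0_logpdf(s$g_mean[g_ok], gamma_rate[g_ok],
                                     s$g_sd[g_ok]))
  ll
}

#' Marginalized transient-CJS log-likelihood of one capture history
#'
#' Likelihood of a single individual's detection history with the latent
#' residency and alive states summed out. A newly banded bird is a resident
#' with probability `pi[first]`; residents may be predetermined as
#' residents (`d = 1`) with probability `rho`, survive each interval with
#' `phi[t]`, and are redetected while alive with probability `p`;
#' transients are never seen again and can never have `d = 1`.
#'
#' @param y 0/1 detection vector over all years (`y[first] == 1`).
#' @param first index of the first capture year.
#' @param d 0/1 predetermined-resident flag.
#' @param phi survival probabilities for intervals 1..T-1.
#' @param p scalar annual recapture probability.
#' @param pi_res residency probabilities per year (scalar or length T).
#' @param rho scalar predetermination probability.
#' @return log-likelihood (scalar).
#' @export
cjs_history_loglik <- function(y, first, d, phi, p, pi_res, rho) {
  Tn <- length(y)
  if (length(phi) != Tn - 1) fc_stop("phi must have length T - 1")
  pi_res <- rep_len(pi_res, Tn)
  if (y[first] != 1) fc_stop("detections[first_year] must be 1")
  if (first > 1 && any(y[seq_len(first - 1)] == 1))
    fc_stop("detection before first_year")
  # chi[t]: P(never detected after t | resident alive at t)
  chi <- numeric(Tn)
  chi[Tn] <- 1
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      chi[t] <- (1 - phi[t]) + phi[t] * (1 - p) * chi[t + 1]
    }
  }
  last <- max(which(y == 1))
  d_lik <- rho^d * (1 - rho)^(1 - d)
  if (last > first) {
    ll <- log(pi_res[first]) + log(d_lik)
    for (t in (first + 1):last) {
      ll <- ll + log(phi[t - 1]) +
        if (y[t] == 1) log(p) else log(1 - p)
    }
    ll + log(chi[last])
  } else {
    # never redetected: transient (only possible when d = 0) or resident
    # that died / was missed ever after
    log((1 - pi_res[first]) * (d == 0) + pi_res[first] * d_lik * chi[first])
  }
}

#' Total transient-CJS log-likelihood of a history table
#'
#' Sums [cjs_history_loglik()] over the individuals of a wide CMR history
#' table, with survival and residency indexed by region-year and capture /
#' predetermination probabilities indexed by station.
#'
#' @param cmr wide history tibble (see [simulate_cmr()]).
#' @param phi region x (T-1) matrix of survival probabilities.
#' @param p named vector of station capture probabilities (or scalar).
#' @param pi_res region x T matrix of residency probabilities (or scalar).
#' @param rho named vector of station predetermination probabilities (or
#'   scalar).
#' @return total log-likelihood.
#' @export
cjs_transient_logdensity <- function(cmr, phi, p, pi_res, rho) {
  years <- cmr_years(cmr)
  Tn <- length(years)
  det <- as.matrix(cmr[paste0("det_", years)])
  if (is.null(dim(phi))) phi <- matrix(phi, max(cmr$region), Tn - 1)
  if (is.null(dim(pi_res))) pi_res <- matrix(pi_res, max(cmr$region), Tn)
  p_of <- function(j) if (length(p) == 1) p else unname(p[j])
  rho_of <- function(j) if (length(rho) == 1) rho else unname(rho[j])
  sum(vapply(seq_len(nrow(cmr)), function(i) {
    k <- cmr$region[i]
    cjs_history_loglik(det[i, ], match(cmr$first_year[i], years),
                       cmr$predetermined_resident[i], phi[k, ],
                       p_of(cmr$station_id[i]), pi_res[k, ],
                       rho_of(cmr$station_id[i]))
  }, numeric(1)))
}

# years covered by a wide CMR table
cmr_years <- function(cmr) {
  as.integer(sub("^det_", "", grep("^det_", names(cmr), value = TRUE)))
}

# Aggregate a CMR table into the sufficient statistics of the marginalized
# transient-CJS likelihood: per-(region, transition) survival counts, per-
# station detection / non-detection counts, residency and predetermination
# counts, chi-term counts, and (station, cohort, d) groups of never-
# redetected individuals.
cjs_suffstats <- function(cmr, years, stations) {
  Tn <- length(years)
  det <- as.matrix(cmr[paste0("det_", years)])
  first <- match(cmr$first_year, years)
  if (any(is.na(first))) fc_stop("CMR first_year outside the year range")
  last <- apply(det, 1, function(r) max(which(r == 1)))
  if (any(det[cbind(seq_len(nrow(det)), first)] != 1))
    fc_stop("detections[first_year] must be 1 for every individual")
  for (i in seq_len(nrow(det)))
    if (first[i] > 1 && any(det[i, seq_len(first[i] - 1)] == 1))
      fc_stop("detection before first_year (individual %s)",
              cmr$individual_id[i])
  K <- max(cmr$region)
  S <- length(stations)
  j_idx <- match(cmr$station_id, stations)
  d <- cmr$predetermined_resident
  redet <- last > first
  A <- matrix(0, K, max(Tn - 1, 1))   # survival intervals
  B <- C <- E <- F_ <- numeric(S)     # det / nondet / d=1 / d=0 counts
  D <- matrix(0, K, Tn)               # residency (first-year) counts
  G <- matrix(0, S, Tn)               # chi terms at last detection
  for (i in which(redet)) {
    k <- cmr$region[i]; j <- j_idx[i]
    A[k, first[i]:(last[i] - 1)] <- A[k, first[i]:(last[i] - 1)] + 1
    seg <- (first[i] + 1):last[i]
    B[j] <- B[j] + sum(det[i, seg])
    C[j] <- C[j] + sum(1 - det[i, seg])
    D[k, first[i]] <- D[k, first[i]] + 1
    E[j] <- E[j] + d[i]
    F_[j] <- F_[j] + (1 - d[i])
    G[j, last[i]] <- G[j, last[i]] + 1
  }
  nr <- which(!redet)
  groups <- tibble::tibble(j = j_idx[nr], k = cmr$region[nr],
                           f = first[nr], d = d[nr]) |>
    dplyr::count(.data$j, .data$k, .data$f, .data$d, name = "n")
  list(A = A, B = B, C = C, D = D, E = E, F = F_, G = G,
       groups = groups, K = K, S = S, Tn = Tn,
       n_individuals = nrow(cmr), n_redetected = sum(redet))
}

# R mirror of the aggregated (sufficient-statistic) CJS log-likelihood the
# JAGS model evaluates; must agree exactly with the per-individual sum.
cjs_suffstat_loglik <- function(ss, phi, p_st, pi_mat, rho_st, kstation) {
  Tn <- ss$Tn; S <- ss$S
  chi <- matrix(1, S, Tn)
  for (j in seq_len(S)) {
    if (Tn > 1) for (t in (Tn - 1):1) {
      k <- kstation[j]
      chi[j, t] <- (1 - phi[k, t]) + phi[k, t] * (1 - p_st[j]) * chi[j, t + 1]
    }
  }
  ll <- sum(ss$A * log(phi)) +
    sum(ss$B * log(p_st)) + sum(ss$C * log(1 - p_st)) +
    sum(ss$D * log(pi_mat)) +
    sum(ss$E * log(rho_st)) + sum(ss$F * log(1 - rho_st)) +
    sum(ss$G * log(chi))
  g <- ss$groups
  if (nrow(g) > 0) {
    lik0 <- (1 - pi_mat[cbind(g$k, g$f)]) * (1 - g$d) +
      pi_mat[cbind(g$k, g$f)] * rho_st[g$j]^g$d *
        (1 - rho_st[g$j])^(1 - g$d) * chi[cbind(g$j, g$f)]
    ll <- ll + sum(g$n * log(lik0))
  }
  ll
}

# JAGS code for the integrated population model (stage 2).
ipm_model_string <- function() {
"model {
  # --- covariate models for survival and recruitment ---
  for (k in 1:K) {
    mu_phi[k] ~ dunif(0, 1)
    b0phi[k] <- logit(mu_phi[k])
    b0gam[k] ~ dnorm(0, 0.01)
    for (c in 1:4) {
      bphi[k, c] ~ dnorm(0, 0.01)
      bgam[k, c] ~ dnorm(0, 0.01)
    }
    sig_phi[k] ~ dnorm(0, 0.25) T(0,)
    tau_phi[k] <- pow(sig_phi[k], -2)
    sig_gam[k] ~ dnorm(0, 0.25) T(0,)
    tau_gam[k] <- pow(sig_gam[k], -2)
    for (t in 1:(T - 1)) {
      yrphi[k, t] ~ dnorm(0, tau_phi[k])
      logit(phi[k, t]) <- b0phi[k] + inprod(bphi[k, 1:4], X[k, t, 1:4]) + yrphi[k, t]
      log_phi[k, t] <- log(phi[k, t])
      yrgam[k, t] ~ dnorm(0, tau_gam[k])
      log(gamma[k, t]) <- b0gam[k] + inprod(bgam[k, 1:4], X[k, t, 1:4]) + yrgam[k, t]
    }
  }

  # --- residency, capture, predetermination ---
  mu_pi ~ dunif(0, 1)
  b0pi <- logit(mu_pi)
  sig_pi ~ dnorm(0, 0.25) T(0,)
  tau_pi <- pow(sig_pi, -2)
  for (k in 1:K) {
    for (t in 1:T) {
      yrpi[k, t] ~ dnorm(0, tau_pi)
      logit(pi[k, t]) <- b0pi + yrpi[k, t]
    }
  }
  mu_p ~ dunif(0, 1)
  b0p <- logit(mu_p)
  sig_p ~ dnorm(0, 0.25) T(0,)
  tau_p <- pow(sig_p, -2)
  mu_rho ~ dunif(0, 1)
  b0rho <- logit(mu_rho)
  sig_rho ~ dnorm(0, 0.25) T(0,)
  tau_rho <- pow(sig_rho, -2)
  for (j in 1:S) {
    sta_p[j] ~ dnorm(0, tau_p)
    logit(p_st[j]) <- b0p + sta_p[j]
    sta_rho[j] ~ dnorm(0, tau_rho)
    logit(rho_st[j]) <- b0rho + sta_rho[j]
  }

  # --- chi: P(resident alive at t at station j is never seen after t) ---
  for (j in 1:S) {
    chi[j, T] <- 1
    for (t in 1:(T - 1)) {
      chi[j, T - t] <- (1 - phi[kstation[j], T - t]) +
        phi[kstation[j], T - t] * (1 - p_st[j]) * chi[j, T - t + 1]
    }
    log_p[j] <- log(p_st[j])
    log_q[j] <- log(1 - p_st[j])
    log_rho[j] <- log(rho_st[j])
    log_rhoq[j] <- log(1 - rho_st[j])
    for (t in 1:T) { log_chi[j, t] <- log(chi[j, t]) }
  }
  for (k in 1:K) {
    for (t in 1:T) { log_pi[k, t] <- log(pi[k, t]) }
  }

  # --- marginalized transient-CJS likelihood via sufficient statistics ---
  ll_surv <- sum(A[1:K, 1:(T - 1)] * log_phi[1:K, 1:(T - 1)])
  ll_det <- inprod(B[1:S], log_p[1:S]) + inprod(C[1:S], log_q[1:S])
  ll_res <- sum(D[1:K, 1:T] * log_pi[1:K, 1:T])
  ll_d <- inprod(E[1:S], log_rho[1:S]) + inprod(Fd[1:S], log_rhoq[1:S])
  ll_chi <- sum(G[1:S, 1:T] * log_chi[1:S, 1:T])
  for (g in 1:Ng) {
    lik0[g] <- (1 - pi[kg[g], fg[g]]) * (1 - dg[g]) +
      pi[kg[g], fg[g]] * pow(rho_st[jg[g]], dg[g]) *
      pow(1 - rho_st[jg[g]], 1 - dg[g]) * chi[jg[g], fg[g]]
    ll_g[g] <- ng[g] * log(lik0[g])
  }
  cjs_ll <- ll_surv + ll_det + ll_res + ll_d + ll_chi + sum(ll_g[1:Ng])
  zero ~ dpois(-cjs_ll + 0.001)

  # --- gamma population process informed by stage-1 indices ---
  for (k in 1:K) {
    nsurv[k, 1] ~ dunif(0, init_upper)
    nrecr[k, 1] ~ dunif(0, init_upper)
    n[k, 1] <- nsurv[k, 1] + nrecr[k, 1]
    for (t in 2:T) {
      nsurv[k, t] ~ dgamma(n[k, t - 1], 1 / phi[k, t - 1])
      nrecr[k, t] ~ dgamma(n[k, t - 1], 1 / gamma[k, t - 1])
      n[k, t] <- nsurv[k, t] + nrecr[k, t]
    }
    for (t in 1:T) {
      logad_mean[k, t] ~ dnorm(log(n[k, t]), pow(logad_sd[k, t], -2))
      ad1_mean[k, t] ~ dnorm(nrecr[k, t], pow(ad1_sd[k, t], -2)) T(0,)
      ad2p_mean[k, t] ~ dnorm(nsurv[k, t], pow(ad2p_sd[k, t], -2)) T(0,)
    }
    for (t in 1:(T - 1)) {
      g_mean[k, t] ~ dnorm(gamma[k, t], pow(g_sd[k, t], -2)) T(0,)
    }
  }
}
"
}

# reshape an index-summaries tibble into K x T matrices
summaries_matrices <- function(summaries, regions, years) {
  grab <- function(col) {
    m <- matrix(NA_real_, length(regions), length(years))
    idx <- cbind(match(summaries$region, regions),
                 match(summaries$year, years))
    m[idx] <- summaries[[col]]
    m
  }
  lapply(setNames(c("logad_mean", "logad_sd", "ad1_mean", "ad1_sd",
                    "ad2p_mean", "ad2p_sd", "g_mean", "g_sd"),
                  c("logad_mean", "logad_sd", "ad1_mean", "ad1_sd",
                    "ad2p_mean", "ad2p_sd", "g_mean", "g_sd")), grab)
}

#' Fit the integrated population model
#'
#' Stage 2 of the two-stage IPM: a gamma population process (survivors and
#' recruits) informed by the stage-1 index summaries, a marginalized
#' transient-corrected CJS likelihood on the raw capture histories sharing
#' the survival parameters, and logit/log-linear models of survival and
#' recruitment on four standardized climate covariates with region-by-year
#' random effects. Priors: Normal(0, 100) on coefficients and the
#' recruitment intercepts, Uniform(0, 1) on inverse-logit-transformed CJS
#' intercepts (survival, residency, capture, predetermination),
#' half-Normal(0, 2) on random-effect SDs, and Uniform(0, `init_upper`) on
#' the initial-year survivors and recruits.
#'
#' @param cmr wide CMR history table (see [simulate_cmr()]).
#' @param summaries index-summaries tibble from [derive_age_indices()].
#' @param covariates `fc_covariates` tibble with `*_std` columns; transition
#'   `t -> t+1` uses the covariate row of year `t`.
#' @param config an [mcmc_config()].
#' @param seed integer seed.
#' @param init_upper upper bound of the vague initial-state prior; default
#'   10 x the maximum observed abundance index.
#' @return object of class `fc_ipm`.
#' @export
fit_ipm <- function(cmr, summaries, covariates, config = mcmc_config(),
                    seed = 1L, init_upper = NULL) {
  regions <- sort(unique(summaries$region))
  years <- sort(unique(summaries$year))
  if (!setequal(cmr_years(cmr), years))
    fc_stop("CMR years and index-summary years are misaligned")
  cov_years <- sort(unique(covariates$year))
  if (!all(years[-length(years)] %in% cov_years))
    fc_stop("covariates do not cover all transition years")
  stations <- sort(unique(cmr$station_id))
  ss <- cjs_suffstats(cmr, years, stations)
  sm <- summaries_matrices(summaries, regions, years)
  X <- covariate_array(covariates)
  X <- X[, match(years, as.integer(dimnames(X)[[2]])), , drop = FALSE]
  kstation <- cmr$region[match(stations, cmr$station_id)]
  init_upper <- init_upper %||% (10 * max(exp(sm$logad_mean), na.rm = TRUE))
  Tn <- length(years)
  data <- list(
    K = length(regions), T = Tn, S = length(stations),
    X = X, kstation = kstation,
    A = ss$A, B = ss$B, C = ss$C, D = ss$D, E = ss$E, Fd = ss$F, G = ss$G,
    Ng = nrow(ss$groups), jg = ss$groups$j, kg = ss$groups$k,
    fg = ss$groups$f, dg = ss$groups$d, ng = ss$groups$n,
    zero = 0L, init_upper = init_upper,
    logad_mean = sm$logad_mean, logad_sd = sm$logad_sd,
    ad1_mean = sm$ad1_mean, ad1_sd = sm$ad1_sd,
    ad2p_mean = sm$ad2p_mean, ad2p_sd = sm$ad2p_sd,
    g_mean = sm$g_mean[, -Tn, drop = FALSE],
    g_sd = sm$g_sd[, -Tn, drop = FALSE]
  )
  inits <- list(
    nsurv = pmax(sm$ad2p_mean, 0.1),
    nrecr = pmax(sm$ad1_mean, 0.1),
    mu_phi = rep(0.6, data$K), b0gam = rep(log(0.3), data$K),
    mu_pi = 0.5, mu_p = 0.3, mu_rho = 0.3
  )
  # initial-year states must respect the uniform prior's support
  inits$nsurv <- pmin(inits$nsurv, init_upper * 0.9)
  inits$nrecr <- pmin(inits$nrecr, init_upper * 0.9)
  draws <- run_mcmc(
    ipm_model_string(), data,
    params = c("b0phi", "mu_phi", "bphi", "b0gam", "bgam", "phi", "gamma",
               "n", "nsurv", "nrecr", "sig_phi", "sig_gam",
               "mu_pi", "mu_p", "mu_rho", "sig_pi", "sig_p", "sig_rho",
               "b0p", "sta_p", "b0pi", "yrpi"),
    config = config, inits = inits, seed = seed
  )
  structure(
    list(draws = draws, regions = regions, years = years,
         stations = stations, data = data, summaries = summaries,
         covariate_names = c("cmd_b", "cmd_w", "cmd_m_res", "elr_m"),
         suffstats = ss, marray = cjs_marray(cmr, years, stations)),
    class = "fc_ipm"
  )
}

# First-recapture m-array of newly banded cohorts: one row per
# (station, cohort) release group, columns = first-recapture year 1..T plus
# a never-recaptured column.
cjs_marray <- function(cmr, years, stations) {
  Tn <- length(years)
  det <- as.matrix(cmr[paste0("det_", years)])
  first <- match(cmr$first_year, years)
  firstre <- vapply(seq_len(nrow(det)), function(i) {
    later <- which(det[i, ] == 1 & seq_len(Tn) > first[i])
    if (length(later) == 0) 0L else as.integer(min(later))
  }, integer(1))
  j_idx <- match(cmr$station_id, stations)
  rel <- tibble::tibble(j = j_idx, k = cmr$region, f = first) |>
    dplyr::count(.data$j, .data$k, .data$f, name = "n")
  obs <- matrix(0, nrow(rel), Tn + 1)
  for (i in seq_len(nrow(det))) {
    rr <- which(rel$j == j_idx[i] & rel$f == first[i])
    col <- if (firstre[i] == 0L) Tn + 1L else firstre[i]
    obs[rr, col] <- obs[rr, col] + 1
  }
  list(rel = rel, obs = obs)
}

# iterations x K x T array of a matrix-valued monitored node
node_array <- function(m, node, K, T) {
  arr <- array(NA_real_, c(nrow(m), K, T))
  for (k in seq_len(K)) for (t in seq_len(T))
    arr[, k, t] <- m[, sprintf("%s[%d,%d]", node, k, t)]
  arr
}

#' Derive population-dynamic quantities from an IPM fit
#'
#' Per MCMC draw: annual growth `lambda_kt = n_{k,t+1} / n_{k,t}`; trend as
#' `(geometric mean lambda - 1) * 100` %/yr; Pearson correlations across
#' years between survivors and recruits and between survival and
#' recruitment rates; and the survival contribution `phi / lambda`.
#' Summaries are medians with equal-tailed 89% credible intervals and sign
#' probabilities.
#'
#' @param fit an `fc_ipm` object.
#' @return list of tibbles: `lambda` (region-year), `trend` (per region,
#'   %/yr), `correlations` (region x pair), `phi_lambda` (region-year and
#'   per-region mean).
#' @export
derive_quantities <- function(fit) {
  stopifnot(inherits(fit, "fc_ipm"))
  K <- length(fit$regions); Tn <- length(fit$years)
  if (Tn < 3) fc_stop("need >= 3 years to derive correlations")
  m <- draws_matrix(fit$draws)
  n <- node_array(m, "n", K, Tn)
  nsurv <- node_array(m, "nsurv", K, Tn)
  nrecr <- node_array(m, "nrecr", K, Tn)
  phi <- node_array(m, "phi", K, Tn - 1)
  gam <- node_array(m, "gamma", K, Tn - 1)
  lam <- n[, , 2:Tn, drop = FALSE] / n[, , 1:(Tn - 1), drop = FALSE]
  out_lambda <- purrr::map_dfr(seq_len(K), function(k) {
    purrr::map_dfr(seq_len(Tn - 1), function(t) {
      dplyr::bind_cols(
        tibble::tibble(region = fit$regions[k], year = fit$years[t]),
        summarise_draws_89(lam[, k, t])
      )
    })
  })
  out_trend <- purrr::map_dfr(seq_len(K), function(k) {
    gm <- exp(rowMeans(log(lam[, k, , drop = FALSE][, 1, ])))
    dplyr::bind_cols(tibble::tibble(region = fit$regions[k]),
                     summarise_draws_89((gm - 1) * 100))
  })
  out_cor <- purrr::map_dfr(seq_len(K), function(k) {
    r_nn <- vapply(seq_len(nrow(m)),
                   function(i) cor(nsurv[i, k, ], nrecr[i, k, ]), numeric(1))
    r_pg <- vapply(seq_len(nrow(m)),
                   function(i) cor(phi[i, k, ], gam[i, k, ]), numeric(1))
    dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(region = fit$regions[k],
                                      pair = "nsurv_nrecr"),
                       summarise_draws_89(r_nn)),
      dplyr::bind_cols(tibble::tibble(region = fit$regions[k],
                                      pair = "phi_gamma"),
                       summarise_draws_89(r_pg))
    )
  })
  pl <- phi / lam
  out_pl <- purrr::map_dfr(seq_len(K), function(k) {
    annual <- purrr::map_dfr(seq_len(Tn - 1), function(t) {
      dplyr::bind_cols(
        tibble::tibble(region = fit$regions[k], year = fit$years[t]),
        summarise_draws_89(pl[, k, t])
      )
    })
    overall <- dplyr::bind_cols(
      tibble::tibble(region = fit$regions[k], year = NA_integer_),
      summarise_draws_89(rowMeans(pl[, k, , drop = FALSE][, 1, ]))
    )
    dplyr::bind_rows(annual, overall)
  })
  list(lambda = out_lambda, trend = out_trend, correlations = out_cor,
       phi_lambda = out_pl)
}

#' Covariate-effect table of an IPM fit
#'
#' Medians, 89% credible intervals and sign probabilities of the survival
#' and recruitment covariate effects per region, in the conventional
#' covariate x region x rate layout.
#'
#' @param x an `fc_ipm` object.
#' @param ... unused.
#' @return tibble: `covariate`, `region`, `rate` (phi/gamma), `median`,
#'   `lower89`, `upper89`, `sign`, `prob_sign`.
#' @export
tidy.fc_ipm <- function(x, ...) {
  m <- draws_matrix(x$draws)
  purrr::map_dfr(seq_along(x$covariate_names), function(c) {
    purrr::map_dfr(seq_along(x$regions), function(k) {
      dplyr::bind_rows(
        dplyr::bind_cols(
          tibble::tibble(covariate = x$covariate_names[c],
                         region = x$regions[k], rate = "phi"),
          summarise_draws_89(m[, sprintf("bphi[%d,%d]", k, c)])),
        dplyr::bind_cols(
          tibble::tibble(covariate = x$covariate_names[c],
                         region = x$regions[k], rate = "gamma"),
          summarise_draws_89(m[, sprintf("bgam[%d,%d]", k, c)]))
      )
    })
  })
}

#' @export
glance.fc_ipm <- function(x, ...) {
  gr <- gelman_rubin(x$draws)
  tibble::tibble(
    regions = length(x$regions), years = length(x$years),
    stations = length(x$stations),
    individuals = x$suffstats$n_individuals,
    redetected = x$suffstats$n_redetected,
    max_rhat = max(gr$rhat, na.rm = TRUE),
    converged = attr(gr, "converged")
  )
}

#' Annual demographic summary of an IPM fit
#'
#' Posterior medians and 89% intervals of survival, recruitment rate and
#' the abundance state per region-year.
#'
#' @param fit an `fc_ipm` object.
#' @return tibble: `region`, `year`, `quantity`, `median`, `lower89`,
#'   `upper89`.
#' @export
demographic_table <- function(fit) {
  stopifnot(inherits(fit, "fc_ipm"))
  m <- draws_matrix(fit$draws)
  K <- length(fit$regions); Tn <- length(fit$years)
  rows <- list()
  for (k in seq_len(K)) {
    for (t in seq_len(Tn)) {
      for (q in c("n", "nsurv", "nrecr")) {
        v <- m[, sprintf("%s[%d,%d]", q, k, t)]
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(region = fit$regions[k], year = fit$years[t],
                         quantity = q),
          summarise_draws_89(v)[c("median", "lower89", "upper89")])
      }
      if (t < Tn) {
        for (q in c("phi", "gamma")) {
          v <- m[, sprintf("%s[%d,%d]", q, k, t)]
          rows[[length(rows) + 1]] <- dplyr::bind_cols(
            tibble::tibble(region = fit$regions[k], year = fit$years[t],
                           quantity = q),
            summarise_draws_89(v)[c("median", "lower89", "upper89")])
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' @describeIn posterior_predictive_check Freeman-Tukey posterior predictive
#'   check for the IPM's CJS component, on first-recapture counts aggregated
#'   by banding cohort and recapture year (the standard m-array form).
#' @export
posterior_predictive_check.fc_ipm <- function(fit,
                                              discrepancy = "freeman_tukey",
                                              seed = 1L, max_draws = 200L,
                                              ...) {
  if (!identical(discrepancy, "freeman_tukey"))
    fc_stop("unknown discrepancy '%s' for the CJS component", discrepancy)
  m <- draws_matrix(fit$draws)
  idx <- if (nrow(m) > max_draws)
    round(seq(1, nrow(m), length.out = max_draws)) else seq_len(nrow(m))
  K <- length(fit$regions); Tn <- length(fit$years)
  marr <- fit$marray
  d_obs <- d_rep <- numeric(length(idx))
  with_seed(seed, {
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      phi <- node_array(m[i, , drop = FALSE], "phi", K, Tn - 1)
      exp_m <- matrix(0, nrow(marr$rel), Tn + 1)
      for (rr in seq_len(nrow(marr$rel))) {
        j <- marr$rel$j[rr]; k <- marr$rel$k[rr]; f <- marr$rel$f[rr]
        n_rel <- marr$rel$n[rr]
        pj <- plogis(m[i, "b0p"] + m[i, sprintf("sta_p[%d]", j)])
        pik <- plogis(m[i, "b0pi"] + m[i, sprintf("yrpi[%d,%d]", k, f)])
        if (f < Tn) {
          surv <- cumprod(phi[1, k, f:(Tn - 1)])
          miss <- cumprod(c(1, rep(1 - pj, Tn - f - 1)))
          exp_m[rr, (f + 1):Tn] <- n_rel * pik * surv * miss * pj
        }
        exp_m[rr, Tn + 1] <- n_rel - sum(exp_m[rr, 1:Tn])
      }
      d_obs[ii] <- ft_disc(marr$obs, exp_m)
      rep_m <- matrix(0, nrow(exp_m), ncol(exp_m))
      for (rr in seq_len(nrow(exp_m))) {
        pr <- pmax(exp_m[rr, ], 0) / marr$rel$n[rr]
        rep_m[rr, ] <- as.numeric(stats::rmultinom(1, marr$rel$n[rr],
                                                   pr / sum(pr)))
      }
      d_rep[ii] <- ft_disc(rep_m, exp_m)
    }
  })
  tibble::tibble(model = "cjs", discrepancy = "freeman_tukey",
                 p_value = ppc_pvalue(d_obs, d_rep), n_draws = length(idx))
}
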