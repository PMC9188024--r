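# Shared fixtures and independent oracles for the test suite.

# Short MCMC settings for unit tests (kept separate from the desk preset so
# unit tests stay fast; inference quality is checked elsewhere).
tiny_mcmc <- function(chains = 2L) {
  mcmc_config("desk", chains = chains, adapt = 300, burnin = 300,
              iterations = 600)
}

# A small two-region synthetic world used by integration tests.
small_config <- function(seed = 1L, ...) {
  sim_config(
    stations_per_region = c(3, 3), n_years = 8,
    mean_count_intercepts = log(c(4, 4)), initial_n = c(4, 4),
    missing_prob = 0, seed = seed, ...
  )
}

# Exhaustive-enumeration oracle for the transient CJS likelihood of one
# capture history: sums the joint probability of (history, d) over all
# latent residency (R) and alive (z) configurations. Independent of the
# package's marginalized recursion.
enumerate_cjs_lik <- function(y, first, d, phi, p, pi_res, rho) {
  Tn <- length(y)
  pi_res <- rep_len(pi_res, Tn)
  total <- 0
  for (R in 0:1) {
    pR <- if (R == 1) pi_res[first] else 1 - pi_res[first]
    pD <- if (R == 1) rho^d * (1 - rho)^(1 - d) else as.numeric(d == 0)
    if (pR * pD == 0) next
    if (R == 0) {
      # transient: dead to the study after first season
      ok <- all(y[-first][seq_len(Tn)[-first] > first] == 0)
      ok <- !any(y[seq_len(Tn) > first] == 1)
      total <- total + pR * pD * as.numeric(ok)
      next
    }
    # resident: enumerate death year (alive through year `alive_until`)
    for (alive_until in first:Tn) {
      # P(alive exactly until alive_until)
      surv <- 1
      if (alive_until > first)
        surv <- prod(phi[first:(alive_until - 1)])
      pdie <- if (alive_until < Tn) (1 - phi[alive_until]) else 1
      pz <- surv * pdie
      # detection likelihood given alive years
      pdet <- 1
      if (Tn > first) {
        for (t in (first + 1):Tn) {
          if (t <= alive_until) {
            pdet <- pdet * (if (y[t] == 1) p else 1 - p)
          } else if (y[t] == 1) pdet <- 0
        }
      }
      total <- total + pR * pD * pz * pdet
    }
  }
  total
}

# Brute-force convex hull: a point is a hull vertex iff it is not strictly
# inside the hull; build by testing all half-planes defined by point pairs.
brute_hull <- function(lon, lat) {
  n <- length(lon)
  on_hull <- rep(FALSE, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    # all points on one side of the line i->j ?
    cr <- (lon[j] - lon[i]) * (lat - lat[i]) - (lat[j] - lat[i]) * (lon - lon[i])
    if (all(cr <= 1e-12) || all(cr >= -1e-12)) {
      on_hull[i] <- TRUE
      on_hull[j] <- TRUE
    }
  }
  which(on_hull)
}

# monthly climate fixture: deterministic values keyed to (point, year, month)
climate_fixture <- function(points = c("p1", "p2"), years = 1990:2000,
                            role = "breeding_station", region = 1) {
  grid <- expand.grid(point_id = points, year = years, month = 1:12,
                      stringsAsFactors = FALSE)
  grid$point_role <- role
  grid$region <- region
  grid$cmd <- 10 * match(grid$point_id, points) + grid$month / 100 +
    (grid$year - 1990)
  grid$precip <- 50 + 5 * grid$month + (grid$year - 1990)
  tibble::as_tibble(grid)
}
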