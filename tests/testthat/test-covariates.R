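test_that("seasonal sums use exactly the stated window months", {
  clim <- climate_fixture(points = "p1", years = 1995:1997)
  # constant CMD of 1: the 7-month Oct-Apr window must sum to 7
  clim1 <- dplyr::mutate(clim, cmd = 1)
  out <- seasonal_sum(clim1, season_window("breeding_oct_apr"), 1996)
  expect_equal(out$value, 7)
  # constant CMD of 2 over the 12-month Apr(prev)-Mar window sums to 24
  clim2 <- dplyr::mutate(clim, cmd = 2)
  out <- seasonal_sum(clim2, season_window("winter_apr_mar"), 1996)
  expect_equal(out$value, 24)

  # sentinel values (month-coded) expose any wrong month/offset bookkeeping
  clim_s <- dplyr::mutate(clim,
                          cmd = .data$month + 1000 * (.data$year - 1995))
  bre <- seasonal_sum(clim_s, season_window("breeding_oct_apr"), 1996)
  expect_equal(bre$value, sum(10:12) + 0 + sum(1:4) + 1000 * 4)
  mol <- seasonal_sum(clim_s, season_window("molt_apr_sep"), 1996)
  expect_equal(mol$value, sum(4:9) + 1000 * 6)
  win <- seasonal_sum(clim_s, season_window("winter_apr_mar"), 1996)
  expect_equal(win$value, sum(4:12) + sum(1:3) + 1000 * 3)
})

test_that("seasonal sums match a brute-force cell-selection oracle", {
  set.seed(42)
  clim <- climate_fixture(points = c("a", "b", "c"), years = 1990:1999)
  clim$cmd <- runif(nrow(clim), 0, 100)
  win <- season_window("breeding_oct_apr")
  out <- seasonal_sum(clim, win, 1995:1997)
  for (i in seq_len(nrow(out))) {
    cells <- vapply(seq_len(nrow(win)), function(w) {
      clim$cmd[clim$point_id == out$point_id[i] &
                 clim$year == out$year[i] + win$year_offset[w] &
                 clim$month == win$month[w]]
    }, numeric(1))
    expect_equal(out$value[i], sum(cells))
  }
  # a missing month is a named error, not a silent NA
  clim_miss <- clim[!(clim$point_id == "b" & clim$year == 1995 &
                        clim$month == 12), ]
  expect_error(seasonal_sum(clim_miss, win, 1996), "point 'b', year 1995")
})

test_that("early:late rainfall ratio is (Jun+Jul)/(Aug+Sep)", {
  clim <- climate_fixture(points = "p", years = 2000)
  clim$precip <- ifelse(clim$month %in% 6:7, 15, 30)
  expect_equal(elr(clim, 2000)$value, 30 / 60)
  clim$precip <- 8  # early = late
  expect_equal(elr(clim, 2000)$value, 1)
  # zero late-season rain is flagged missing, not infinite
  clim$precip <- ifelse(clim$month %in% 8:9, 0, 10)
  expect_true(is.na(elr(clim, 2000)$value))
  # random table matches direct recomputation
  set.seed(7)
  clim$precip <- runif(12, 0, 50)
  expect_equal(
    elr(clim, 2000)$value,
    sum(clim$precip[clim$month %in% 6:7]) /
      sum(clim$precip[clim$month %in% 8:9])
  )
})

test_that("deviations subtract point normals and vanish over the reference period", {
  vals <- tibble::tibble(point_id = "p", year = 1991:2000,
                         value = c(120, 80, 100, 90, 110, 95, 105, 99, 101, 130))
  norms <- point_normals(vals, 1991:2000)
  dev <- deviation(vals, norms)
  expect_equal(mean(dev$deviation), 0)
  expect_equal(deviation(tibble::tibble(point_id = "p", year = 1, value = 120),
                         tibble::tibble(point_id = "p", normal = 100))$deviation,
               20)
  expect_error(deviation(vals, tibble::tibble(point_id = "q", normal = 1)),
               "no normal")
})

test_that("regional averaging and residualization behave as least squares", {
  d <- tibble::tibble(point_id = c("a", "b"), year = 2000,
                      deviation = c(1, 3))
  expect_equal(regional_average(d)$value, 2)
  expect_error(
    regional_average(tibble::tibble(point_id = "a", year = 2000,
                                    deviation = NA_real_)),
    "all points missing")

  expect_equal(residualize(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  # hand-computed OLS: y orthogonal to x pattern leaves centered x
  expect_equal(residualize(c(0, 1, 0), c(-1, 0, 1)),
               c(-1 / 3, 2 / 3, -1 / 3))
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  r <- residualize(x, y)
  expect_lt(abs(mean(r)), 1e-10)
  expect_lt(abs(sum(r * (y - mean(y)))), 1e-10)
  expect_error(residualize(x, rep(2, 30)), "constant")
})

test_that("standardization gives exact z-scores and is idempotent", {
  expect_equal(as.numeric(standardize(c(1, 2, 3))), c(-1, 0, 1))
  set.seed(2)
  v <- rnorm(50, 7, 3)
  z <- standardize(v)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(as.numeric(standardize(as.numeric(z))), as.numeric(z))
  expect_error(standardize(rep(1, 5)), "SD")
})

test_that("the full covariate build yields standardized, orthogonalized covariates", {
  set.seed(9)
  stations <- climate_fixture(points = c("s1", "s2", "s3"),
                              years = 1989:2000)
  stations$region <- ifelse(stations$point_id == "s1", 1, 2)
  molt <- climate_fixture(points = c("m1", "m2"), years = 1989:2000,
                          role = "molt_sample", region = NA)
  winter <- climate_fixture(points = c("w1", "w2"), years = 1989:2000,
                            role = "winter_sample", region = NA)
  clim <- dplyr::bind_rows(stations, molt, winter)
  clim$cmd <- runif(nrow(clim), 0, 60)
  clim$precip <- runif(nrow(clim), 1, 80)
  cov <- build_covariates(clim, years = 1992:2000, ref_years = 1990:1991)
  expect_s3_class(cov, "fc_covariates")
  for (cv in c("cmd_b_std", "cmd_w_std", "cmd_m_res_std", "elr_m_std")) {
    expect_lt(abs(mean(cov[[cv]])), 1e-8)
    expect_equal(sd(cov[[cv]]), 1, tolerance = 1e-8)
  }
  # molt drought residuals are orthogonal to winter drought by construction
  one_region <- cov[cov$region == 1, ]
  expect_lt(abs(cov(one_region$cmd_m_res, one_region$cmd_w)), 1e-8)
  # non-breeding covariates are shared across regions
  r1 <- cov[cov$region == 1, ]
  r2 <- cov[cov$region == 2, ]
  expect_equal(r1$cmd_w, r2$cmd_w)
  expect_equal(r1$elr_m, r2$elr_m)
})

test_that("deviation-then-average commutes with average-then-deviation", {
  set.seed(11)
  pts <- c("x", "y", "z")
  vals <- tidyr::expand_grid(point_id = pts, year = 1990:1999)
  vals$value <- runif(nrow(vals), 0, 10)
  norms <- point_normals(vals, 1990:1994)
  # average of per-point deviations
  a <- regional_average(deviation(vals, norms))
  # deviation of per-year averages from the averaged normal
  yearly <- vals |> dplyr::group_by(year) |>
    dplyr::summarise(value = mean(value), .groups = "drop")
  b <- yearly$value - mean(yearly$value[yearly$year %in% 1990:1994])
  expect_equal(a$value, b)
})
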