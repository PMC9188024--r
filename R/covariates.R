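#' Seasonal window definitions
#'
#' The four climate windows used to build annual covariates, expressed as
#' (month, year offset) pairs relative to the demographic year `t`:
#' * breeding-grounds drought (`cmd_b`): summed CMD over the overwintering
#'   period Oct (t-1) through Apr (t), before arrival on breeding grounds;
#' * molting-grounds drought (`cmd_m`): summed CMD Apr-Sep of year `t`;
#' * wintering-grounds drought (`cmd_w`): summed CMD Apr (t-1) through
#'   Mar (t);
#' * early:late rainfall ratio (`elr_m`): (Jun + Jul) / (Aug + Sep)
#'   precipitation of year `t`.
#'
#' @param name one of `"breeding_oct_apr"`, `"molt_apr_sep"`,
#'   `"winter_apr_mar"`.
#' @return tibble with columns `month` and `year_offset`.
#' @export
season_window <- function(name = c("breeding_oct_apr", "molt_apr_sep",
                                   "winter_apr_mar")) {
  name <- match.arg(name)
  switch(name,
    breeding_oct_apr = tibble::tibble(
      month = c(10:12, 1:4),
      year_offset = c(rep(-1L, 3), rep(0L, 4))
    ),
    molt_apr_sep = tibble::tibble(month = 4:9, year_offset = 0L),
    winter_apr_mar = tibble::tibble(
      month = c(4:12, 1:3),
      year_offset = c(rep(-1L, 9), rep(0L, 3))
    )
  )
}

# validate a monthly climate table
check_climate_table <- function(climate) {
  need <- c("point_id", "year", "month")
  missing <- setdiff(need, names(climate))
  if (length(missing) > 0)
    fc_stop("climate table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(climate$month < 1 | climate$month > 12))
    fc_stop("climate table has month outside 1..12")
  dup <- duplicated(climate[c("point_id", "year", "month")])
  if (any(dup)) fc_stop("duplicate (point_id, year, month) rows in climate table")
  invisible(climate)
}

#' Sum a climate variable over a seasonal window
#'
#' For each point, sums `var` over the window months, where each month is
#' taken from calendar year `target_year + year_offset`. Used to build the
#' seasonal drought-deficit covariates.
#'
#' @param climate monthly climate table (`point_id`, `year`, `month`, plus
#'   the variable column).
#' @param window tibble with columns `month` and `year_offset` (see
#'   [season_window()]).
#' @param target_year the demographic year the window is anchored to (may be
#'   a vector).
#' @param var name of the variable column to sum (default `"cmd"`).
#' @return tibble with columns `point_id`, `year` (= target year), `value`.
#'   A missing window month raises an error naming the point, year and month.
#' @export
seasonal_sum <- function(climate, window, target_year, var = "cmd") {
  check_climate_table(climate)
  if (!var %in% names(climate)) fc_stop("no column '%s' in climate table", var)
  grid <- tidyr::expand_grid(
    point_id = unique(climate$point_id),
    target_year = unique(as.integer(target_year)),
    window
  ) |>
    dplyr::mutate(year = .data$target_year + .data$year_offset)
  joined <- dplyr::left_join(
    grid,
    dplyr::select(climate, "point_id", "year", "month",
                  value = dplyr::all_of(var)),
    by = c("point_id", "year", "month")
  )
  miss <- joined[is.na(joined$value), , drop = FALSE]
  if (nrow(miss) > 0) {
    m <- miss[1, ]
    fc_stop("missing climate value: point '%s', year %d, month %d (and %d more)",
            as.character(m$point_id), m$year, m$month, nrow(miss) - 1L)
  }
  joined |>
    dplyr::group_by(point_id = .data$point_id, year = .data$target_year) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
}

#' Early:late monsoon rainfall ratio
#'
#' Per point and year, the ratio of early-season (Jun + Jul) to late-season
#' (Aug + Sep) precipitation — a simple index of monsoon phenology on the
#' molting grounds. A zero late-season denominator yields `NA` (flagged
#' missing and excluded from averaging) rather than infinity.
#'
#' @param climate monthly climate table with a `precip` column.
#' @param target_year year(s) to evaluate.
#' @return tibble `point_id`, `year`, `value` (the ratio, `NA` if the
#'   late-season total is zero).
#' @export
elr <- function(climate, target_year) {
  check_climate_table(climate)
  if (!"precip" %in% names(climate)) fc_stop("no 'precip' column in climate table")
  sub <- climate |>
    dplyr::filter(.data$year %in% as.integer(target_year),
                  .data$month %in% 6:9)
  counts <- sub |>
    dplyr::count(.data$point_id, .data$year) |>
    dplyr::filter(.data$n < 4L)
  if (nrow(counts) > 0)
    fc_stop("Jun-Sep precipitation incomplete for point '%s', year %d",
            as.character(counts$point_id[1]), counts$year[1])
  sub |>
    dplyr::group_by(.data$point_id, .data$year) |>
    dplyr::summarise(
      early = sum(.data$precip[.data$month %in% 6:7]),
      late = sum(.data$precip[.data$month %in% 8:9]),
      .groups = "drop"
    ) |>
    dplyr::mutate(value = ifelse(.data$late > 0, .data$early / .data$late,
                                 NA_real_)) |>
    dplyr::select("point_id", "year", "value")
}

#' Deviation of annual values from point-level normals
#'
#' Subtracts each point's reference-period normal from its annual value,
#' removing spatial gradients so that covariates measure year-to-year
#' anomalies only.
#'
#' @param values tibble `point_id`, `year`, `value`.
#' @param normals tibble `point_id`, `normal`.
#' @return `values` with an added `deviation = value - normal` column.
#' @export
deviation <- function(values, normals) {
  out <- dplyr::left_join(values, dplyr::select(normals, "point_id", "normal"),
                          by = "point_id")
  if (any(is.na(out$normal)))
    fc_stop("no normal for point '%s'",
            as.character(out$point_id[which(is.na(out$normal))[1]]))
  dplyr::mutate(out, deviation = .data$value - .data$normal)
}

#' Compute point-level normals from a reference period
#'
#' Mean of the per-point annual values over `ref_years` (e.g. the 1971-2000
#' normal period). By construction, deviations computed against these
#' normals average to zero over the reference period itself.
#'
#' @param values tibble `point_id`, `year`, `value`.
#' @param ref_years integer vector of reference years.
#' @return tibble `point_id`, `normal`.
#' @export
point_normals <- function(values, ref_years) {
  values |>
    dplyr::filter(.data$year %in% ref_years, !is.na(.data$value)) |>
    dplyr::group_by(.data$point_id) |>
    dplyr::summarise(normal = mean(.data$value), .groups = "drop")
}

#' Average point-level deviations into an annual regional series
#'
#' Arithmetic mean over the (non-missing) points of a sampling role for each
#' year. Breeding-grounds drought is station-scale and is averaged only when
#' a single regional series is required (e.g. for the recruitment model's
#' region-year covariate matrix).
#'
#' @param deviations tibble `point_id`, `year`, `deviation`.
#' @return tibble `year`, `value` (mean deviation).
#' @export
regional_average <- function(deviations) {
  out <- deviations |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_points = sum(!is.na(.data$deviation)),
      value = mean(.data$deviation, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(out$n_points == 0))
    fc_stop("all points missing for year %d", out$year[which(out$n_points == 0)[1]])
  dplyr::select(out, "year", "value")
}

#' Residualize one annual series on another
#'
#' Ordinary least-squares residuals of `x` regressed on `y`; used to strip
#' the wintering-grounds drought signal out of molting-grounds drought so
#' the two covariates enter the demographic models near-orthogonally.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return numeric vector of residuals (zero mean, zero sample covariance
#'   with `y`).
#' @export
residualize <- function(x, y) {
  if (length(x) != length(y)) fc_stop("x and y must have equal length")
  if (length(x) < 3) fc_stop("residualize needs length >= 3")
  if (sd(y) == 0) fc_stop("y is constant; regression slope undefined")
  unname(resid(lm(x ~ y)))
}

#' Standardize a vector to mean 0, SD 1
#'
#' Sample-SD z-scores; the centering and scaling constants are attached as
#' attributes so fitted effects can be mapped back to natural units.
#'
#' @param v numeric vector, length >= 2, non-constant.
#' @return numeric vector with attributes `center` and `scale`.
#' @export
standardize <- function(v) {
  if (length(v) < 2) fc_stop("standardize needs length >= 2")
  s <- sd(v)
  if (!is.finite(s) || s == 0) fc_stop("standardize: zero or undefined SD")
  m <- mean(v)
  structure((v - m) / s, center = m, scale = s)
}

#' Build the standardized annual climate covariate set
#'
#' Runs the full covariate pipeline on a monthly point-level climate table:
#' seasonal sums per window, point-level deviations from normals, regional
#' averaging by sampling role, residualization of molting-grounds drought on
#' wintering-grounds drought, and standardization. Point roles must be one
#' of `breeding_station` (with a `region` column), `molt_sample`,
#' `winter_sample`.
#'
#' @param climate monthly table: `point_id`, `point_role`, `region` (for
#'   breeding stations), `year`, `month`, `cmd`, `precip`.
#' @param years demographic years to cover.
#' @param normals optional precomputed normals (list with elements `cmd_b`,
#'   `cmd_m`, `cmd_w`, `elr_m`, each `point_id`/`normal`); if `NULL`,
#'   computed from `ref_years` within `climate`.
#' @param ref_years reference years for normals when `normals` is `NULL`.
#' @return tibble of class `fc_covariates`: one row per region-year with raw
#'   deviations (`cmd_b`, `cmd_w`, `cmd_m`, `cmd_m_res`, `elr_m`) and
#'   standardized versions (`*_std`). Standardization constants are kept in
#'   the `scaling` attribute.
#' @export
build_covariates <- function(climate, years, normals = NULL,
                             ref_years = NULL) {
  check_climate_table(climate)
  if (!"point_role" %in% names(climate)) fc_stop("climate table needs 'point_role'")
  years <- sort(as.integer(years))
  roles <- list(
    cmd_b = "breeding_station", cmd_m = "molt_sample", cmd_w = "winter_sample",
    elr_m = "molt_sample"
  )
  windows <- list(
    cmd_b = season_window("breeding_oct_apr"),
    cmd_m = season_window("molt_apr_sep"),
    cmd_w = season_window("winter_apr_mar")
  )
  annual <- function(covar) {
    sub <- dplyr::filter(climate, .data$point_role == roles[[covar]])
    if (nrow(sub) == 0) fc_stop("no points with role '%s'", roles[[covar]])
    if (covar == "elr_m") elr(sub, years)
    else seasonal_sum(sub, windows[[covar]], years, var = "cmd")
  }
  vals <- lapply(setNames(names(roles), names(roles)), annual)
  if (is.null(normals)) {
    if (is.null(ref_years)) fc_stop("supply either normals or ref_years")
    ref_vals <- lapply(setNames(names(roles), names(roles)), function(covar) {
      sub <- dplyr::filter(climate, .data$point_role == roles[[covar]])
      if (covar == "elr_m") elr(sub, ref_years)
      else seasonal_sum(sub, windows[[covar]], ref_years, var = "cmd")
    })
    normals <- lapply(ref_vals, point_normals, ref_years = ref_years)
  }
  devs <- lapply(setNames(names(roles), names(roles)), function(covar) {
    deviation(vals[[covar]], normals[[covar]])
  })

  # regional series: breeding stations carry a region; non-breeding roles are
  # shared across regions
  stations <- climate |>
    dplyr::filter(.data$point_role == "breeding_station") |>
    dplyr::distinct(.data$point_id, .data$region)
  regions <- sort(unique(stations$region))
  cmd_b_reg <- devs$cmd_b |>
    dplyr::left_join(stations, by = "point_id") |>
    dplyr::group_by(.data$region, .data$year) |>
    dplyr::summarise(cmd_b = mean(.data$deviation), .groups = "drop")
  shared <- function(d) regional_average(d) |> dplyr::rename(dev = "value")
  cmd_w_ann <- shared(devs$cmd_w)
  cmd_m_ann <- shared(devs$cmd_m)
  elr_ann <- shared(devs$elr_m)
  cmd_m_res <- residualize(cmd_m_ann$dev[match(years, cmd_m_ann$year)],
                           cmd_w_ann$dev[match(years, cmd_w_ann$year)])
  base <- tibble::tibble(
    year = years,
    cmd_w = cmd_w_ann$dev[match(years, cmd_w_ann$year)],
    cmd_m = cmd_m_ann$dev[match(years, cmd_m_ann$year)],
    cmd_m_res = cmd_m_res,
    elr_m = elr_ann$dev[match(years, elr_ann$year)]
  )
  out <- tidyr::expand_grid(region = regions, year = years) |>
    dplyr::left_join(cmd_b_reg, by = c("region", "year")) |>
    dplyr::left_join(base, by = "year")
  scaling <- list()
  for (cv in c("cmd_b", "cmd_w", "cmd_m_res", "elr_m")) {
    z <- standardize(out[[cv]])
    out[[paste0(cv, "_std")]] <- as.numeric(z)
    scaling[[cv]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
  }
  structure(out, scaling = scaling,
            class = c("fc_covariates", class(out)))
}
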