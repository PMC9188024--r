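#' Read a delimited table, auto-detecting the dialect
#'
#' Accepts comma- or tab-delimited files with a header; `#`-prefixed lines
#' are treated as comments (provenance headers written by this package).
#'
#' @param path file path.
#' @return tibble.
#' @export
read_delim_auto <- function(path) {
  if (!file.exists(path)) fc_stop("file not found: %s", path)
  lines <- readLines(path, n = 50)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) fc_stop("file has no data rows: %s", path)
  delim <- if (sum(stringr::str_count(lines[1], "\t")) >=
               sum(stringr::str_count(lines[1], ","))) "\t" else ","
  readr::read_delim(path, delim = delim, comment = "#",
                    show_col_types = FALSE, progress = FALSE)
}

#' Write an output table with a provenance header
#'
#' Comma-delimited with fixed column order; a `#`-prefixed header records
#' the seed, scale preset and a content hash of the inputs so outputs are
#' traceable.
#'
#' @param x data frame.
#' @param path output path.
#' @param seed,scale_preset,inputs provenance fields (inputs: named vector
#'   of input descriptions/hashes).
#' @return `path`, invisibly.
#' @export
write_output_table <- function(x, path, seed = NA, scale_preset = NA,
                               inputs = NULL) {
  hdr <- c(
    sprintf("# fullcycle output table: %s", basename(path)),
    sprintf("# seed: %s  scale_preset: %s", seed, scale_preset),
    if (!is.null(inputs))
      sprintf("# input %s: %s", names(inputs), unname(inputs))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

# stable content hash for provenance headers (no external digest dependency)
content_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x, vec.len = 1e6)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 997)) %%
            .Machine$integer.max)
}

#' Validate banding inputs and apply station-inclusion filters
#'
#' Applies the standard constant-effort station filters: breeding must be
#' documented at the station, the station must have operated in at least
#' `min_years` years, and must have banded on average at least
#' `min_mean_adults` adults per operated year. If a raw capture-record
#' table with dates is supplied, records outside the breeding-season window
#' (May 1 to Aug 9) are dropped first.
#'
#' @param capture_table station-year table (`station_id`, `region`, `year`,
#'   `effort_ratio`, `ahy_count`), optionally with a logical
#'   `breeding_documented` column.
#' @param records optional per-capture table with a `date` column.
#' @param min_years minimum operated years (default 4).
#' @param min_mean_adults minimum mean adults per year (default 1).
#' @return list of class `fc_validation`: `capture_table` (filtered),
#'   `stations_kept`, `exclusions` (tibble `station_id`, `reason`),
#'   `filter_counts` (tibble `reason`, `n`).
#' @export
validate_inputs <- function(capture_table, records = NULL,
                            min_years = 4, min_mean_adults = 1) {
  check_capture_table(capture_table)
  n_window_dropped <- 0L
  if (!is.null(records) && "date" %in% names(records)) {
    md <- as.integer(format(as.Date(records$date), "%m")) * 100 +
      as.integer(format(as.Date(records$date), "%d"))
    keep <- md >= 501 & md <= 809
    n_window_dropped <- sum(!keep)
    records <- records[keep, ]
  }
  per_station <- capture_table |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(
      n_years = dplyr::n_distinct(.data$year),
      mean_adults = mean(.data$ahy_count),
      breeding = if ("breeding_documented" %in% names(capture_table))
        any(.data$breeding_documented) else TRUE,
      .groups = "drop"
    )
  exclusions <- dplyr::bind_rows(
    per_station |> dplyr::filter(!.data$breeding) |>
      dplyr::transmute(.data$station_id, reason = "no_breeding_documented"),
    per_station |> dplyr::filter(.data$breeding,
                                 .data$n_years < min_years) |>
      dplyr::transmute(.data$station_id, reason = "min_years"),
    per_station |> dplyr::filter(.data$breeding,
                                 .data$n_years >= min_years,
                                 .data$mean_adults < min_mean_adults) |>
      dplyr::transmute(.data$station_id, reason = "min_captures")
  )
  kept <- setdiff(per_station$station_id, exclusions$station_id)
  counts <- exclusions |> dplyr::count(.data$reason)
  if (n_window_dropped > 0)
    counts <- dplyr::bind_rows(
      counts, tibble::tibble(reason = "outside_breeding_window",
                             n = n_window_dropped))
  structure(
    list(
      capture_table = capture_table[capture_table$station_id %in% kept, ],
      stations_kept = kept,
      exclusions = exclusions,
      filter_counts = counts,
      records = records
    ),
    class = "fc_validation"
  )
}

#' @export
print.fc_validation <- function(x, ...) {
  cat(sprintf("<fc_validation> %d stations kept, %d excluded\n",
              length(x$stations_kept), nrow(x$exclusions)))
  if (nrow(x$filter_counts) > 0) print(x$filter_counts)
  invisible(x)
}

#' Write / read a synthetic dataset as delimited text
#'
#' Persists every table of an [simulate_dataset()] result plus a
#' human-readable key-value sidecar with the ground-truth scalar
#' parameters.
#'
#' @param dataset an `fc_sim_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir` invisibly; `read_dataset` returns the list of tables.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "fc_sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- dataset$truth$config$seed
  w <- function(x, name) write_output_table(x, file.path(dir, name),
                                            seed = seed)
  w(dataset$capture_table, "capture_table.csv")
  w(dataset$microage_table, "microage_table.csv")
  w(dataset$cmr, "cmr_histories.csv")
  w(as.data.frame(dataset$covariates), "covariates.csv")
  w(dataset$veg_table, "veg_table.csv")
  w(dataset$truth$states, "truth_states.csv")
  w(dataset$truth$rates, "truth_rates.csv")
  cfg <- dataset$truth$config
  scalars <- cfg[vapply(cfg, function(v) is.numeric(v) && is.null(dim(v)),
                        logical(1))]
  kv <- unlist(lapply(names(scalars), function(nm) {
    sprintf("%s%s: %s", nm,
            if (length(scalars[[nm]]) > 1)
              paste0("[", seq_along(scalars[[nm]]), "]") else "",
            format(scalars[[nm]], digits = 15))
  }))
  writeLines(c("# fullcycle ground truth (key: value)", kv),
             file.path(dir, "truth_config.txt"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  read1 <- function(name) read_delim_auto(file.path(dir, name))
  list(
    capture_table = read1("capture_table.csv"),
    microage_table = read1("microage_table.csv"),
    cmr = read1("cmr_histories.csv"),
    covariates = read1("covariates.csv"),
    veg_table = read1("veg_table.csv"),
    truth_states = read1("truth_states.csv"),
    truth_rates = read1("truth_rates.csv")
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end on in-memory tables: input validation,
#' stage-1 index models, the integrated population model, derived
#' demographic quantities, and the climate-vegetation regressions. Each
#' stage's artifact is returned (and optionally written as delimited text
#' with provenance headers).
#'
#' @param dataset list with `capture_table`, `microage_table`, `cmr`,
#'   `covariates` and optionally `veg_table` (e.g. an `fc_sim_dataset`).
#' @param config an [mcmc_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional directory for artifact tables.
#' @param min_years,min_mean_adults station filters (see
#'   [validate_inputs()]).
#' @return list of class `fc_pipeline`: `validation`, `stage1`,
#'   `index_summaries`, `ipm`, `effects`, `derived`, `diagnostics`, `veg`.
#' @export
run_pipeline <- function(dataset, config = mcmc_config(), seed = 1L,
                         out_dir = NULL, min_years = 4,
                         min_mean_adults = 1) {
  seeds <- derive_seeds(seed, 4)
  val <- validate_inputs(dataset$capture_table, min_years = min_years,
                         min_mean_adults = min_mean_adults)
  captures <- val$capture_table
  microage <- dataset$microage_table[
    dataset$microage_table$station_id %in% val$stations_kept, ]
  years <- sort(unique(captures$year))
  cov_years <- sort(unique(dataset$covariates$year))
  if (!all(head(years, -1) %in% cov_years))
    fc_stop("validation failed: covariate years %s-%s do not cover capture years %s-%s",
            min(cov_years), max(cov_years), min(years), max(years))
  stage1 <- fit_stage1(captures, microage, config = config, seed = seeds[1])
  summaries <- derive_age_indices(stage1)
  cmr <- dataset$cmr[dataset$cmr$station_id %in% unique(dataset$cmr$station_id), ]
  ipm <- fit_ipm(cmr, summaries, dataset$covariates, config = config,
                 seed = seeds[2])
  derived <- derive_quantities(ipm)
  effects <- tidy.fc_ipm(ipm)
  diagnostics <- dplyr::bind_rows(
    dplyr::mutate(gelman_rubin(stage1$draws), model = "stage1"),
    dplyr::mutate(gelman_rubin(ipm$draws), model = "ipm")
  )
  veg <- if (!is.null(dataset$veg_table))
    veg_response_table(dataset$veg_table) else NULL
  out <- structure(
    list(validation = val, stage1 = stage1, index_summaries = summaries,
         ipm = ipm, effects = effects, derived = derived,
         diagnostics = diagnostics, veg = veg, seed = seed,
         config = config),
    class = "fc_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- c(inputs = content_hash(dataset$capture_table))
    w <- function(x, name) write_output_table(
      x, file.path(out_dir, name), seed = seed,
      scale_preset = config$scale_preset, inputs = prov)
    w(as.data.frame(summaries), "index_summaries.csv")
    w(effects, "covariate_effects.csv")
    w(derived$trend, "trend.csv")
    w(derived$correlations, "correlations.csv")
    w(demographic_table(ipm), "demographic_table.csv")
    w(diagnostics, "diagnostics.csv")
    if (!is.null(veg)) w(veg, "veg_effects.csv")
  }
  out
}

#' @export
print.fc_pipeline <- function(x, ...) {
  cat("<fc_pipeline>\n")
  cat(sprintf("  stations: %d  years: %d  regions: %d\n",
              length(x$ipm$stations), length(x$ipm$years),
              length(x$ipm$regions)))
  cat(sprintf("  max Rhat: %.4f\n", max(x$diagnostics$rhat, na.rm = TRUE)))
  cat("  trend (%/yr):\n")
  print(x$derived$trend)
  invisible(x)
}
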