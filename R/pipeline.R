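#' Read a grain dry-weight series CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `cultivar,site,year,grain_class,day,weight_mg`, one row per observation.
#' Rows are grouped by unit and sorted by day. Duplicate (unit, day) rows
#' are averaged with a warning. `grain_class` must be `"superior"` or
#' `"inferior"`.
#'
#' @param path Path to the CSV file.
#' @return A long-format tibble with the six schema columns, ready for
#'   [fit_richards()].
#' @export
read_series_csv <- function(path) {
  raw <- read_checked_csv(
    path,
    required = c("cultivar", "site", "year", "grain_class", "day",
                 "weight_mg"),
    numeric_cols = c("year", "day", "weight_mg")
  )
  bad_class <- setdiff(unique(raw$grain_class), c("superior", "inferior"))
  if (length(bad_class) > 0) {
    abort(paste0("`grain_class` must be 'superior' or 'inferior'; found: ",
                 paste(bad_class, collapse = ", ")),
          class = "grainfill_error_value")
  }
  if (any(raw$weight_mg < 0) || any(raw$day < 0)) {
    abort("`day` and `weight_mg` must be non-negative.",
          class = "grainfill_error_value")
  }
  keys <- c("cultivar", "site", "year", "grain_class", "day")
  if (anyDuplicated(raw[keys]) > 0) {
    n_dup <- sum(duplicated(raw[keys]))
    warn(paste0(n_dup, " duplicate (unit, day) row(s) averaged."))
    raw <- raw |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(weight_mg = mean(.data$weight_mg), .groups = "drop")
  }
  dplyr::arrange(raw, .data$cultivar, .data$site, .data$year,
                 .data$grain_class, .data$day)
}

#' Read a per-unit trait table CSV
#'
#' Expects the key columns `cultivar,site,year` (plus `grain_class` when
#' traits are resolved by grain class) followed by numeric trait columns.
#' Row keys must be unique.
#'
#' @inheritParams read_series_csv
#' @return A tibble keyed by the unit columns.
#' @export
read_trait_csv <- function(path) {
  raw <- read_checked_csv(path, required = c("cultivar", "site", "year"))
  keys <- intersect(c("cultivar", "site", "year", "grain_class"), names(raw))
  if (anyDuplicated(raw[keys]) > 0) {
    abort("Trait table row keys are not unique.",
          class = "grainfill_error_schema")
  }
  raw
}

#' Write the per-unit characteristics table
#'
#' One row per fitted series with the estimated parameters, every derived
#' filling characteristic, the fit diagnostics and the accumulated warning
#' flags. Floating-point values are written at 6 significant digits; row
#' order follows the fit object, so repeated runs produce byte-identical
#' files.
#'
#' @param fit A `richards_fit` from [fit_richards()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_characteristics_csv <- function(fit, path) {
  if (!inherits(fit, "richards_fit")) {
    abort("`fit` must be a `richards_fit`.", class = "grainfill_error_schema")
  }
  if (nrow(fit$fits) == 0) {
    abort("No fitted series to write.", class = "grainfill_error_schema")
  }
  out <- fit$fits |>
    dplyr::select(dplyr::all_of(c(
      fit$options$keys,
      "A", "B", "K", "N", "R0", "GFR_max", "T_max", "W_max", "GFR_avg",
      "GFD", "t1", "t2", "frac_start", "frac_middle", "frac_late"
    )), R2 = "r_squared", "warnings") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' Collects the inputs and options of one end-to-end analysis run. Either
#' build it in code or load it from a YAML file via `config_file`.
#'
#' @param series Path to the observation CSV ([read_series_csv()] schema).
#' @param traits Optional path to a trait CSV ([read_trait_csv()] schema).
#' @param environment Optional path to an environment CSV keyed by
#'   `cultivar,site,year`.
#' @param out_dir Output directory (created if absent).
#' @param multistart,seed,gfd_fraction Fit options; see [fit_richards()].
#' @param alpha Significance level for the correlation stage.
#' @param x_cols Characteristic columns to correlate with traits; defaults
#'   to the full derived set.
#' @param y_cols Trait columns to correlate; defaults to every numeric
#'   non-key column of the trait table.
#' @param average_replicates Average replicate weights per day before
#'   fitting.
#' @param config_file Optional YAML file whose entries override the
#'   defaults above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(series, traits = NULL, environment = NULL,
                            out_dir = ".", multistart = 5, seed = 42,
                            gfd_fraction = 0.99, alpha = 0.05,
                            x_cols = NULL, y_cols = NULL,
                            average_replicates = FALSE,
                            config_file = NULL) {
  cfg <- list(series = series, traits = traits, environment = environment,
              out_dir = out_dir, multistart = multistart, seed = seed,
              gfd_fraction = gfd_fraction, alpha = alpha,
              x_cols = x_cols, y_cols = y_cols,
              average_replicates = average_replicates)
  if (!is.null(config_file)) {
    rlang::check_installed("yaml")
    over <- yaml::read_yaml(config_file)
    cfg[names(over)] <- over
  }
  if (!is.numeric(cfg$gfd_fraction) || cfg$gfd_fraction <= 0.9 ||
      cfg$gfd_fraction >= 0.9999) {
    abort("`gfd_fraction` must lie in (0.9, 0.9999).",
          class = "grainfill_error_domain")
  }
  check_alpha(cfg$alpha)
  structure(cfg, class = "pipeline_config")
}

#' Run the full grain-filling analysis pipeline
#'
#' Reads the observation series, fits the Richards model to every unit,
#' writes the characteristics table and a sub-phase contribution report,
#' and — when a trait table is supplied — the long-format correlation table
#' linking filling characteristics to traits. All randomness is governed by
#' the configured seed, so two runs with the same configuration produce
#' byte-identical outputs.
#'
#' Output files in `out_dir`: `characteristics.csv`, `subphases.csv`
#' (per-unit fractions plus an overall-mean row), `correlations.csv`
#' (only with traits), and `run_summary.json` (seed, options, per-unit
#' convergence and warnings).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fit object, the characteristics
#'   tibble, the correlation tibble (or `NULL`) and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a `pipeline_config`.",
          class = "grainfill_error_schema")
  }
  series <- read_series_csv(config$series)
  if (nrow(series) == 0) {
    abort("Series file contains no observations.",
          class = "grainfill_error_schema")
  }
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  fit <- fit_richards(series,
                      multistart = config$multistart, seed = config$seed,
                      gfd_fraction = config$gfd_fraction,
                      average_replicates = config$average_replicates)
  paths <- list(
    characteristics = file.path(config$out_dir, "characteristics.csv"),
    subphases = file.path(config$out_dir, "subphases.csv"),
    summary = file.path(config$out_dir, "run_summary.json")
  )
  write_characteristics_csv(fit, paths$characteristics)

  keys <- fit$options$keys
  per_unit <- dplyr::select(fit$fits, dplyr::all_of(c(
    keys, "t1", "t2", "frac_start", "frac_middle", "frac_late"
  )))
  overall <- per_unit |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean))
  subphases <- dplyr::bind_rows(
    dplyr::mutate(per_unit, scope = "unit", .before = 1),
    dplyr::mutate(overall, scope = "mean", .before = 1)
  ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_csv(subphases, paths$subphases)

  correlations <- NULL
  if (!is.null(config$traits)) {
    traits <- read_trait_csv(config$traits)
    trait_keys <- intersect(c("cultivar", "site", "year", "grain_class"),
                            names(traits))
    joined <- dplyr::inner_join(fit$fits, traits, by = trait_keys)
    x_cols <- config$x_cols %||%
      c("R0", "GFR_max", "T_max", "W_max", "GFR_avg", "GFD", "t1", "t2",
        "frac_middle")
    y_cols <- config$y_cols %||%
      setdiff(names(traits)[purrr::map_lgl(traits, is.numeric)],
              c(trait_keys, "year"))
    correlations <- trait_correlations(joined, x_cols, y_cols,
                                       alpha = config$alpha)
    paths$correlations <- file.path(config$out_dir, "correlations.csv")
    readr::write_csv(
      dplyr::mutate(correlations,
                    dplyr::across(dplyr::where(is.double),
                                  ~ signif(.x, 6))),
      paths$correlations
    )
  }

  summary <- list(
    seed = config$seed,
    multistart = config$multistart,
    gfd_fraction = config$gfd_fraction,
    n_series = nrow(fit$fits),
    n_converged = sum(fit$fits$converged),
    mean_frac_middle = mean(fit$fits$frac_middle),
    units = fit$fits |>
      dplyr::select(dplyr::all_of(keys), "sse", "r_squared", "converged",
                    "warnings") |>
      purrr::transpose()
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(fit = fit, characteristics = fit$fits,
                 correlations = correlations, paths = paths))
}

# shared CSV reader with schema and numeric validation
read_checked_csv <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "grainfill_error_io")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "grainfill_error_schema")
  }
  for (col in numeric_cols) {
    if (!is.numeric(raw[[col]])) {
      parsed <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(parsed) & !is.na(raw[[col]]))
      if (length(bad) > 0) {
        abort(paste0("Non-numeric `", col, "` at data row(s): ",
                     paste(head(bad, 5), collapse = ", ")),
              class = "grainfill_error_parse")
      }
      raw[[col]] <- parsed
    }
    if (any(is.na(raw[[col]]))) {
      abort(paste0("Missing values in required numeric column `", col, "`."),
            class = "grainfill_error_parse")
    }
  }
  raw
}

`%||%` <- function(x, y) if (is.null(x)) y else x
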