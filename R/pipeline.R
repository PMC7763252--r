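#' Pipeline configuration
#'
#' Bundles the paths and knobs of a full analysis run: panel and registry
#' locations, output directory, normalization pooling mode, restoration
#' method, forecast horizon, an optional frozen-weights file (to score new
#' observations under a fixed published weight set instead of recomputing
#' entropy weights), and a log level.
#'
#' @param panel path to the raw panel CSV.
#' @param registry path to the registry CSV, or `NULL` for the default
#'   20-indicator PESN catalogue.
#' @param out_dir output directory (created if absent).
#' @param pooling normalization pooling mode, `"global"` or `"per_year"`.
#' @param restore in-sample restoration method for GM(1,1).
#' @param horizon forecast horizon in years (>= 0).
#' @param frozen_weights optional path to a weights CSV; if given, entropy
#'   weighting is skipped.
#' @param quiet suppress progress messages.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(panel, registry = NULL, out_dir = "ecowarn-out",
                            pooling = c("global", "per_year"),
                            restore = c("difference", "derivative"),
                            horizon = 3, frozen_weights = NULL,
                            quiet = FALSE) {
  if (horizon < 0) stop("horizon must be >= 0")
  structure(list(panel = panel, registry = registry, out_dir = out_dir,
                 pooling = match.arg(pooling), restore = match.arg(restore),
                 horizon = as.integer(horizon),
                 frozen_weights = frozen_weights, quiet = isTRUE(quiet)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML-like key: value file
#'
#' One `key: value` pair per line, keys as in [pipeline_config()]; lines
#' starting with `#` are ignored.
#'
#' @param path path to the config file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", lines))
  vals <- stats::setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2))
  get <- function(k, default) if (k %in% names(vals)) vals[[k]] else default
  pipeline_config(
    panel = get("panel", stop("config must name a 'panel' file")),
    registry = get("registry", NULL), out_dir = get("out_dir", "ecowarn-out"),
    pooling = get("pooling", "global"), restore = get("restore", "difference"),
    horizon = as.numeric(get("horizon", 3)),
    frozen_weights = get("frozen_weights", NULL),
    quiet = as.logical(get("quiet", FALSE)))
}

#' Fit, test and forecast per-region GM(1,1) models
#'
#' The tail of the full pipeline, entered directly from precomputed
#' early-warning series: one GM(1,1) fit per region, the double accuracy
#' test, and forecasts for every region whose verdict is not "Failed".
#' Failed regions keep their fit and diagnostics (for inspection) but get no
#' forecast rows — the accuracy tests gate the prediction step.
#'
#' @param series data frame with columns `region`, `year`, `ewv` (one
#'   positive series per region, each of length >= 4), or a path to such a
#'   CSV.
#' @param horizon forecast horizon in years.
#' @param restore in-sample restoration method.
#' @return List of class `"ewv_models"`: `fits` (named list of `"gm11"`),
#'   `diagnostics` (one row per region), `fitted` (long data frame of
#'   observed/fitted/relative error), `forecast` (long data frame with
#'   graded predictions).
#' @export
run_from_ewv <- function(series, horizon = 3,
                         restore = c("difference", "derivative")) {
  restore <- match.arg(restore)
  if (is.character(series)) {
    if (!file.exists(series)) stop("series file not found: ", series)
    series <- utils::read.csv(series, stringsAsFactors = FALSE)
  }
  need <- c("region", "year", "ewv")
  if (!all(need %in% names(series)))
    stop("series must have columns region, year, ewv")
  regions <- unique(series$region)
  fits <- list(); diag_rows <- list(); fit_rows <- list(); fc_rows <- list()
  for (r in regions) {
    s <- series[series$region == r, ]
    if (anyDuplicated(s$year))
      stop("duplicate year for region '", r, "'")
    s <- s[order(s$year), ]
    if (any(s$ewv <= 0))
      stop("non-positive early-warning value for region '", r, "'")
    fit <- gm11(s$ewv, years = s$year, restore = restore)
    rep <- diagnose(fit)
    fits[[r]] <- fit
    diag_rows[[r]] <- diagnostics_row(rep, region = r)
    fit_rows[[r]] <- data.frame(region = r, year = s$year, observed = s$ewv,
                                fitted = fit$fitted,
                                residual = rep$residuals,
                                relative_error = rep$relative_errors,
                                stringsAsFactors = FALSE)
    if (rep$verdict != "Failed" && horizon > 0) {
      fc <- predict(fit, horizon = horizon)
      cls <- suppressWarnings(classify_grade(fc$predicted))
      fc_rows[[r]] <- data.frame(region = r, year = fc$year,
                                 predicted = fc$predicted,
                                 grade = cls$grade, status = cls$status,
                                 stringsAsFactors = FALSE)
    }
  }
  structure(list(fits = fits,
                 diagnostics = do.call(rbind, c(diag_rows,
                                                make.row.names = FALSE)),
                 fitted = do.call(rbind, c(fit_rows, make.row.names = FALSE)),
                 forecast = if (length(fc_rows))
                   do.call(rbind, c(fc_rows, make.row.names = FALSE))
                 else data.frame(region = character(), year = integer(),
                                 predicted = numeric(), grade = character(),
                                 status = character())),
            class = "ewv_models")
}

#' Run the full early-warning pipeline
#'
#' Panel validation, interpolation of missing interior cells, direction-aware
#' min-max normalization, entropy weighting (or frozen weights), composite
#' early-warning values with five-grade classification, per-region GM(1,1)
#' fits with the double accuracy test, and graded forecasts for regions that
#' pass. Writes `weights.csv`, `ewv.csv`, `diagnostics.csv`, `fitted.csv`,
#' `forecast.csv` and a human-readable `summary.txt` to the output directory;
#' data files carry no timestamps, so identical inputs give byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return List of class `"ewarn_run"` with elements `panel`, `normalized`,
#'   `weights`, `ews`, `models` (an `"ewv_models"`), and `files` (the written
#'   paths), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!config$quiet) message(...)
  registry <- if (is.null(config$registry)) default_registry()
              else read_registry(config$registry)
  say("conventions: pooling=", config$pooling, ", restore=", config$restore,
      ", diagnostics over k=2..n with population variance")
  panel <- read_panel(config$panel, registry)
  panel <- interpolate_missing(panel)
  normalized <- normalize_panel(panel, registry, pooling = config$pooling)
  weights <- if (is.null(config$frozen_weights)) {
    say("computing entropy weights from ", nrow(normalized), " observations")
    compute_weights(normalized, registry)
  } else {
    say("using frozen weights from ", config$frozen_weights)
    read_weights(config$frozen_weights)
  }
  ews <- compute_ews(normalized, weights)
  models <- run_from_ewv(
    data.frame(region = ews$region, year = ews$year, ewv = ews$ewv),
    horizon = config$horizon, restore = config$restore)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(config$out_dir, f)
  write_weights(weights, fp("weights.csv"))
  write_ews(ews, fp("ewv.csv"))
  utils::write.csv(models$diagnostics, fp("diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(models$fitted, fp("fitted.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(models$forecast, fp("forecast.csv"), row.names = FALSE,
                   quote = FALSE)
  failed <- models$diagnostics$region[models$diagnostics$verdict == "Failed"]
  summary_lines <- c(
    "ecological security early-warning pipeline",
    sprintf("observations: %d regions x %d years, %d indicators",
            length(unique(panel$region)), length(unique(panel$year)),
            length(panel_indicators(panel))),
    sprintf("pooling=%s restore=%s horizon=%d", config$pooling,
            config$restore, config$horizon),
    sprintf("verdicts: %s",
            paste(sprintf("%s=%s", models$diagnostics$region,
                          models$diagnostics$verdict), collapse = " ")),
    if (length(failed))
      sprintf("excluded from forecast (Failed verdict): %s",
              paste(failed, collapse = ", "))
    else "all regions passed the accuracy tests")
  writeLines(summary_lines, fp("summary.txt"))
  if (length(failed))
    say("regions excluded from forecast: ", paste(failed, collapse = ", "))
  invisible(structure(list(panel = panel, normalized = normalized,
                           weights = weights, ews = ews, models = models,
                           files = vapply(c("weights.csv", "ewv.csv",
                                            "diagnostics.csv", "fitted.csv",
                                            "forecast.csv", "summary.txt"),
                                          fp, "")),
                      class = "ewarn_run"))
}
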