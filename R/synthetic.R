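#' Configuration for a synthetic indicator panel
#'
#' Describes a region-by-year-by-indicator panel with known ground truth:
#' each (region, indicator) series is `baseline + slope * (year index) +
#' Gaussian noise`, truncated at a small positive floor. The default shape —
#' 7 regions, 8 years, 20 mixed-direction indicators across the four PESN
#' subsystems — mirrors the county-level study design the package targets.
#'
#' @param n_regions number of regions (>= 1).
#' @param start_year first calendar year.
#' @param n_years number of consecutive years (>= 4).
#' @param registry an [indicator_registry()]; defaults to the 20-indicator
#'   PESN catalogue.
#' @param baseline numeric, recycled over indicators: series level at year 1.
#' @param slope numeric, recycled: per-year trend added to each series;
#'   region r gets `slope * (1 + 0.1 * (r - 1))` so regions differ but stay
#'   monotone in the same direction.
#' @param noise_sd numeric, recycled: standard deviation of the additive
#'   Gaussian noise (>= 0).
#' @param seed integer seed governing all draws.
#' @return List of class `"synthetic_panel_config"`.
#' @export
synthetic_panel_config <- function(n_regions = 7, start_year = 2011,
                                   n_years = 8, registry = default_registry(),
                                   baseline = 10, slope = 0.5,
                                   noise_sd = 0.3, seed = 1L) {
  if (n_regions < 1) stop("need at least 1 region")
  if (n_years < 4) stop("need at least 4 years")
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  p <- nrow(registry)
  structure(list(n_regions = as.integer(n_regions),
                 start_year = as.integer(start_year),
                 n_years = as.integer(n_years),
                 registry = validate_registry(registry),
                 baseline = rep_len(baseline, p),
                 slope = rep_len(slope, p),
                 noise_sd = rep_len(noise_sd, p),
                 seed = as.integer(seed)),
            class = "synthetic_panel_config")
}

#' Generate a synthetic indicator panel
#'
#' Deterministic given the config's seed: the generator scopes its own RNG
#' state, so global random state is neither read nor disturbed. Generated
#' values are truncated at `1e-6` to keep every cell positive.
#'
#' @param config a [synthetic_panel_config()].
#' @return An `"indicator_panel"` with `n_regions * n_years` observations.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  reg <- config$registry
  years <- config$start_year + seq_len(config$n_years) - 1L
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  df <- data.frame(region = rep(regions, each = config$n_years),
                   year = rep(years, config$n_regions),
                   stringsAsFactors = FALSE)
  t_idx <- rep(seq_len(config$n_years) - 1L, config$n_regions)
  r_idx <- rep(seq_len(config$n_regions), each = config$n_years)
  for (j in seq_len(nrow(reg))) {
    slope_r <- config$slope[j] * (1 + 0.1 * (r_idx - 1))
    v <- config$baseline[j] + slope_r * t_idx +
      stats::rnorm(nrow(df), 0, config$noise_sd[j])
    if (all(v <= 0))
      stop("generation error: indicator '", reg$code[j],
           "' produced no positive values (baseline/slope too negative)")
    df[[reg$code[j]]] <- pmax(v, 1e-6)
  }
  as_panel(df, reg, complete = TRUE)
}

#' Generate a series exactly obeying the grey difference equation
#'
#' Builds `x[k] = (b - a * x1[k-1]) / (1 + 0.5 a)` recursively from
#' `x[1] = x0_1`, so the returned series satisfies
#' `x[k] + a * z[k] = b` with zero residual. Refitting it with [gm11()] must
#' recover `(a, b)` to numerical precision, which makes this the ground-truth
#' oracle for the whole grey-model stack.
#'
#' @param a development coefficient (`a != -2`).
#' @param b grey input.
#' @param x0_1 first value (> 0).
#' @param n series length (>= 4).
#' @return Positive numeric vector of length `n`.
#' @examples
#' x <- generate_grey_series(-0.05, 0.3, 0.2, 8)
#' gm11(x)$a   # -0.05 up to rounding
#' @export
generate_grey_series <- function(a, b, x0_1, n) {
  if (abs(1 + 0.5 * a) < .Machine$double.eps) stop("a = -2 is not allowed")
  if (x0_1 <= 0) stop("first value must be positive")
  if (n < 4) stop("need length >= 4")
  x <- numeric(n)
  x[1] <- x0_1
  cum <- x0_1
  for (k in 2:n) {
    x[k] <- (b - a * cum) / (1 + 0.5 * a)
    if (x[k] <= 0)
      stop("positivity error: generated value at k = ", k, " is <= 0; ",
           "choose parameters keeping the series positive")
    cum <- cum + x[k]
  }
  x
}

#' Load a packaged fixture
#'
#' Three published data objects ship with the package:
#' \describe{
#'   \item{`comprehensive_ewv`}{the study-area comprehensive early-warning
#'     series, 2011-2018 (data frame: `year`, `ewv`).}
#'   \item{`county_ewv`}{per-county early-warning values and safety grades,
#'     7 counties x 8 years (data frame: `region`, `year`, `ewv`, `esl`).}
#'   \item{`published_weights`}{the published 20-indicator weight set
#'     (a `"weight_table"` with type and comprehensive weights).}
#' }
#'
#' @param name one of `"comprehensive_ewv"`, `"county_ewv"`,
#'   `"published_weights"`.
#' @return The fixture data.
#' @export
load_fixture <- function(name = c("comprehensive_ewv", "county_ewv",
                                  "published_weights")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "ecowarn",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (name == "published_weights")
    weight_table(df$indicator, df$subsystem, df$comprehensive_weight,
                 df$type_weight)
  else df
}
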