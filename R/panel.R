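#' @title Indicator panels
#' @description An indicator panel holds raw indicator values keyed by
#'   (region, year, indicator). Internally it is a wide data frame with
#'   columns `region`, `year` and one numeric column per indicator code,
#'   carrying class `"indicator_panel"`. Rows are sorted by region then year
#'   and each region's years must form a contiguous ascending run (insert
#'   rows with `NA` cells for years with missing data, then
#'   [interpolate_missing()]).
#' @name indicator_panel
NULL

#' Construct and validate an indicator panel
#'
#' @param df data frame with columns `region`, `year`, and one column per
#'   indicator code in `registry`.
#' @param registry an [indicator_registry()].
#' @param complete if `TRUE`, require every cell to be finite (the state
#'   expected after interpolation).
#' @return The validated panel, sorted by region and year, with class
#'   `"indicator_panel"`.
#' @export
as_panel <- function(df, registry, complete = FALSE) {
  registry <- validate_registry(registry)
  if (!all(c("region", "year") %in% names(df)))
    stop("panel must have 'region' and 'year' columns")
  codes <- registry$code
  extra <- setdiff(names(df), c("region", "year", codes))
  if (length(extra))
    stop("panel has column(s) not in the registry: ",
         paste(extra, collapse = ", "))
  miss <- setdiff(codes, names(df))
  if (length(miss))
    stop("indicator(s) in registry but absent from panel: ",
         paste(miss, collapse = ", "))
  if (!is.numeric(df$year) || any(df$year != round(df$year), na.rm = TRUE))
    stop("'year' must be integer-valued")
  df$year <- as.integer(df$year)
  key <- paste(df$region, df$year)
  if (anyDuplicated(key))
    stop("duplicate (region, year) row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  df <- df[order(df$region, df$year), c("region", "year", codes)]
  rownames(df) <- NULL
  for (r in unique(df$region)) {
    yrs <- df$year[df$region == r]
    if (!identical(yrs, seq(yrs[1], length.out = length(yrs))))
      stop("years for region '", r, "' are not a contiguous ascending run; ",
           "add rows with NA cells for the missing years")
  }
  for (cd in codes) {
    if (!is.numeric(df[[cd]]))
      stop("indicator column '", cd, "' is not numeric")
    if (any(is.infinite(df[[cd]])))
      stop("non-finite value in indicator '", cd, "'")
    if (complete && anyNA(df[[cd]])) {
      i <- which(is.na(df[[cd]]))[1]
      stop("missing cell at (", df$region[i], ", ", df$year[i], ", ", cd,
           "); interpolate_missing() first")
    }
  }
  structure(df, indicators = codes,
            class = c("indicator_panel", "data.frame"))
}

#' Indicator codes of a panel
#' @param panel an `"indicator_panel"`.
#' @return Character vector of indicator codes (column order).
#' @export
panel_indicators <- function(panel) attr(panel, "indicators")

#' Read an indicator panel from CSV
#'
#' Accepts either the wide dialect (columns `region`, `year`, then one column
#' per indicator code) or the long dialect (columns `region`, `year`,
#' `indicator`, `value`). Comma separator, `.` decimal mark, UTF-8. Empty
#' cells become `NA` (to be filled by [interpolate_missing()]); any other
#' non-numeric text in a value cell is a parse error naming the offending
#' (region, year, indicator).
#'
#' @param path path to the CSV file.
#' @param registry an [indicator_registry()]; the panel must contain exactly
#'   its indicators.
#' @param format `"auto"` (default), `"wide"` or `"long"`.
#' @return An `"indicator_panel"`.
#' @export
read_panel <- function(path, registry, format = c("auto", "wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("panel file is empty: ", path)
  if (format == "auto")
    format <- if (all(c("indicator", "value") %in% names(raw))) "long" else "wide"
  if (format == "long") {
    need <- c("region", "year", "indicator", "value")
    if (!all(need %in% names(raw)))
      stop("long panel must have columns region, year, indicator, value")
    unknown <- setdiff(unique(raw$indicator), registry$code)
    if (length(unknown))
      stop("panel has indicator(s) not in the registry: ",
           paste(unknown, collapse = ", "))
    val <- parse_cells(raw$value, raw$region, raw$year, raw$indicator)
    wide <- stats::reshape(
      data.frame(region = raw$region, year = as.integer(raw$year),
                 indicator = raw$indicator, value = val,
                 stringsAsFactors = FALSE),
      direction = "wide", idvar = c("region", "year"),
      timevar = "indicator", v.names = "value")
    names(wide) <- sub("^value\\.", "", names(wide))
    df <- wide
  } else {
    df <- raw
    for (cd in setdiff(names(df), c("region", "year")))
      df[[cd]] <- parse_cells(df[[cd]], df$region, df$year, cd)
    df$year <- as.integer(raw$year)
  }
  as_panel(df, registry)
}

parse_cells <- function(cells, region, year, code) {
  cells <- trimws(cells)
  out <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(out) & !(cells == "" | toupper(cells) == "NA"))
  if (length(bad)) {
    i <- bad[1]
    cd <- if (length(code) > 1) code[i] else code
    stop("cannot parse value '", cells[i], "' at (", region[i], ", ",
         year[i], ", ", cd, ")")
  }
  out
}

#' Write an indicator panel to CSV
#'
#' Values are written as decimal text; with the default `digits = NA` the
#' full binary precision is preserved (`%.17g`), so
#' `read_panel(write_panel(p))` round-trips every cell bit-exactly.
#'
#' @param panel an `"indicator_panel"`.
#' @param path output path.
#' @param format `"wide"` (default) or `"long"`.
#' @param digits decimal digits to keep, or `NA` for full precision.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("wide", "long"), digits = NA) {
  format <- match.arg(format)
  codes <- panel_indicators(panel)
  fmt <- function(x) {
    out <- if (is.na(digits)) sprintf("%.17g", x)
           else sprintf(paste0("%.", digits, "f"), x)
    out[is.na(x)] <- ""
    out
  }
  if (format == "wide") {
    out <- data.frame(region = panel$region, year = panel$year,
                      stringsAsFactors = FALSE)
    for (cd in codes) out[[cd]] <- fmt(panel[[cd]])
  } else {
    out <- data.frame(
      region = rep(panel$region, times = length(codes)),
      year = rep(panel$year, times = length(codes)),
      indicator = rep(codes, each = nrow(panel)),
      value = fmt(unlist(panel[codes], use.names = FALSE)),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Fill missing interior cells by linear interpolation
#'
#' Each (region, indicator) series is taken in year order and interior `NA`
#' cells are replaced by linear interpolation between the nearest non-missing
#' neighbours (the adjacent-years rule). Missing values at a series endpoint
#' are refused: no extrapolation rule is defined.
#'
#' @param panel an `"indicator_panel"`.
#' @return The panel with every cell finite.
#' @export
interpolate_missing <- function(panel) {
  codes <- panel_indicators(panel)
  for (r in unique(panel$region)) {
    rows <- which(panel$region == r)
    for (cd in codes) {
      v <- panel[[cd]][rows]
      if (!anyNA(v)) next
      if (is.na(v[1]) || is.na(v[length(v)]))
        stop("missing value at a series endpoint for (", r, ", ", cd,
             "); interpolation between adjacent years cannot extrapolate")
      if (sum(!is.na(v)) < 2)
        stop("series (", r, ", ", cd, ") has fewer than two observed values")
      panel[[cd]][rows] <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                                         xout = seq_along(v))$y
    }
  }
  panel
}

#' Min-max normalize a panel by indicator direction
#'
#' Positive (developmental) indicators map `x -> (x - min) / (max - min)`;
#' negative (restrictive) indicators map `x -> (max - x) / (max - min)`, so
#' that 1 is always the safest observed state. By default min and max are
#' pooled over all (region, year) observations jointly, which keeps scores
#' comparable across years — a prerequisite for treating the composite index
#' as a time series. A per-year pooling mode is available for sensitivity
#' checks.
#'
#' @param panel a complete `"indicator_panel"` (no missing cells).
#' @param registry the matching [indicator_registry()].
#' @param pooling `"global"` (default) or `"per_year"`.
#' @param constant what to do with a constant indicator column
#'   (`max == min`): `"error"` (default; its entropy weight would be
#'   undefined) or `"midpoint"` to assign 0.5 everywhere, with a warning.
#' @return A `"normalized_panel"` (also an `"indicator_panel"`), all values
#'   in \[0, 1\].
#' @export
normalize_panel <- function(panel, registry,
                            pooling = c("global", "per_year"),
                            constant = c("error", "midpoint")) {
  pooling <- match.arg(pooling)
  constant <- match.arg(constant)
  registry <- validate_registry(registry)
  panel <- as_panel(panel, registry, complete = TRUE)
  codes <- panel_indicators(panel)
  groups <- if (pooling == "global") list(seq_len(nrow(panel)))
            else split(seq_len(nrow(panel)), panel$year)
  for (cd in codes) {
    neg <- registry$direction[registry$code == cd] == "negative"
    for (rows in groups) {
      x <- panel[[cd]][rows]
      lo <- min(x); hi <- max(x)
      if (hi == lo) {
        if (constant == "error")
          stop("indicator '", cd, "' is constant (max == min) over the ",
               "pooled observations; its normalized values are undefined")
        warning("indicator '", cd, "' is constant; assigning 0.5")
        panel[[cd]][rows] <- 0.5
      } else {
        panel[[cd]][rows] <- if (neg) (hi - x) / (hi - lo)
                             else (x - lo) / (hi - lo)
      }
    }
  }
  structure(panel, pooling = pooling,
            class = c("normalized_panel", class(panel)))
}
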