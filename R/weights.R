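#' Relative frequencies of a normalized indicator column
#'
#' Converts one indicator's normalized values across the m observations into
#' the frequency vector used by the entropy weight method:
#' `f_i = y_i / sum(y)`. Any exactly-zero frequency is then replaced by
#' 0.0001 before entropy evaluation — the conventional guard against
#' `0 * log(0)` — deliberately without renormalizing, so the vector may sum
#' to slightly more than 1 (by at most `1e-4` per replaced zero).
#'
#' @param column non-negative numeric vector (one indicator across
#'   observations), not all zero.
#' @return Frequency vector of the same length, entries positive.
#' @export
relative_frequencies <- function(column) {
  if (any(column < 0)) stop("column has negative values")
  s <- sum(column)
  if (s == 0) stop("degenerate column: all values are zero")
  f <- column / s
  f[f == 0] <- 1e-4
  f
}

#' Entropy of one indicator across observations
#'
#' `e = -(1/log(m)) * sum(f * log(f))` over the m observations. Equals 1 for
#' the uniform frequency vector and approaches 0 as the mass concentrates on
#' a single observation; low entropy means high information content and hence
#' high weight.
#'
#' @param frequencies positive frequency vector from
#'   [relative_frequencies()].
#' @param m number of observations (defaults to `length(frequencies)`).
#' @return Entropy value.
#' @export
indicator_entropy <- function(frequencies, m = length(frequencies)) {
  if (m < 2) stop("entropy needs at least 2 observations")
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  -sum(frequencies * log(frequencies)) / log(m)
}

#' Entropy weights of a normalized panel
#'
#' For each indicator, computes the entropy `e_j` of its normalized column
#' across all observations, the difference coefficient `b_j = 1 - e_j`, the
#' comprehensive weight `w_j = b_j / sum(b)`, and the type weight — the
#' comprehensive weight renormalized within the indicator's subsystem so that
#' each subsystem's type weights sum to 1.
#'
#' @param panel a `"normalized_panel"`.
#' @param registry the matching [indicator_registry()].
#' @return A data frame of class `"weight_table"` with columns `indicator`,
#'   `subsystem`, `entropy`, `difference_coefficient`, `comprehensive_weight`,
#'   `type_weight`.
#' @export
compute_weights <- function(panel, registry) {
  registry <- validate_registry(registry)
  codes <- panel_indicators(panel)
  m <- nrow(panel)
  if (m < 2) stop("need at least 2 observations to compute entropy weights")
  if (length(codes) < 1) stop("panel has no indicators")
  ej <- vapply(codes, function(cd)
    indicator_entropy(relative_frequencies(panel[[cd]]), m), numeric(1))
  bj <- 1 - ej
  if (sum(bj) <= 0)
    stop("zero information: every indicator column is uniform (entropy 1)")
  wj <- bj / sum(bj)
  sub <- registry$subsystem[match(codes, registry$code)]
  tw <- wj / stats::ave(wj, sub, FUN = sum)
  structure(data.frame(indicator = codes, subsystem = sub, entropy = ej,
                       difference_coefficient = bj, comprehensive_weight = wj,
                       type_weight = tw, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("weight_table", "data.frame"))
}

#' Assemble a weight table from fixed weights
#'
#' Wraps externally supplied comprehensive weights (e.g. a published weight
#' set) as a `"weight_table"` so new observations can be scored under frozen
#' weights. Type weights are derived by renormalizing within subsystem unless
#' supplied.
#'
#' @param indicator character vector of indicator codes.
#' @param subsystem character vector of subsystems.
#' @param comprehensive_weight numeric weights (should sum to ~1).
#' @param type_weight optional; derived from `comprehensive_weight` if `NULL`.
#' @return A `"weight_table"`.
#' @export
weight_table <- function(indicator, subsystem, comprehensive_weight,
                         type_weight = NULL) {
  if (is.null(type_weight))
    type_weight <- comprehensive_weight /
      stats::ave(comprehensive_weight, subsystem, FUN = sum)
  structure(data.frame(indicator = as.character(indicator),
                       subsystem = as.character(subsystem),
                       entropy = NA_real_, difference_coefficient = NA_real_,
                       comprehensive_weight = comprehensive_weight,
                       type_weight = type_weight, row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("weight_table", "data.frame"))
}

#' Write a weight table to CSV
#' @param weights a `"weight_table"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  utils::write.csv(as.data.frame(weights), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a weight table from CSV
#' @param path path to a CSV written by [write_weights()] or with at least
#'   columns `indicator`, `subsystem`, `comprehensive_weight`.
#' @return A `"weight_table"`.
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("indicator", "subsystem", "comprehensive_weight")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("weights file is missing column(s): ", paste(miss, collapse = ", "))
  weight_table(df$indicator, df$subsystem, df$comprehensive_weight,
               if ("type_weight" %in% names(df)) df$type_weight else NULL)
}
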