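#' Five-grade early-warning classification table
#'
#' Half-open intervals, lower bound inclusive: \[0, 0.2) grade I "Huge alarm",
#' \[0.2, 0.4) II "Moderate warning", \[0.4, 0.6) III "Light warning",
#' \[0.6, 0.8) IV "Good", \[0.8, 1.0) V "Excellent".
#'
#' @return Data frame with columns `lower`, `upper`, `grade`, `status`.
#' @export
grade_table <- function() {
  data.frame(lower = c(0, 0.2, 0.4, 0.6, 0.8),
             upper = c(0.2, 0.4, 0.6, 0.8, 1.0),
             grade = c("I", "II", "III", "IV", "V"),
             status = c("Huge alarm", "Moderate warning", "Light warning",
                        "Good", "Excellent"),
             stringsAsFactors = FALSE)
}

#' Classify an early-warning value into a safety grade
#'
#' Values at or above 1.0 (possible for forecasts of a growing index) clamp
#' to grade V and values below 0 clamp to grade I, each with a warning.
#'
#' @param value numeric vector of early-warning values; must be finite.
#' @return Data frame with columns `value`, `grade` (I..V) and `status`.
#' @examples
#' classify_grade(c(0.6448, 0.3460, 0.2))
#' @export
classify_grade <- function(value) {
  if (any(!is.finite(value)))
    stop("early-warning value must be finite")
  if (any(value >= 1 | value < 0))
    warning("value(s) outside [0, 1) clamped to the extreme grade")
  v <- pmin(pmax(value, 0), 1 - 1e-12)
  gt <- grade_table()
  i <- findInterval(v, gt$lower)
  data.frame(value = value, grade = gt$grade[i], status = gt$status[i],
             stringsAsFactors = FALSE)
}

#' Composite early-warning values, subscores and grades
#'
#' The composite early-warning value of one (region, year) observation is the
#' weighted sum of its normalized indicator values,
#' `P_i = sum_j w_j * y_ij`, with `w_j` the comprehensive weights; since the
#' weights sum to 1 and `y` lies in \[0, 1\], so does `P_i`. Subsystem
#' subscores use the type weights (renormalized within subsystem), so each
#' subscore is itself a \[0, 1\] index; weighting the subscores by their
#' subsystem's share of comprehensive weight recomposes `P_i` exactly.
#'
#' @param panel a `"normalized_panel"`.
#' @param weights a `"weight_table"` covering exactly the panel's indicators.
#' @return Data frame of class `"ews"` with columns `region`, `year`, `ewv`,
#'   `grade`, `status`, `p_score`, `e_score`, `s_score`, `n_score`.
#' @export
compute_ews <- function(panel, weights) {
  codes <- panel_indicators(panel)
  miss <- setdiff(weights$indicator, codes)
  if (length(miss))
    stop("indicator(s) in weights but absent from panel: ",
         paste(miss, collapse = ", "))
  miss <- setdiff(codes, weights$indicator)
  if (length(miss))
    stop("indicator(s) in panel but absent from weights: ",
         paste(miss, collapse = ", "))
  w <- weights[match(codes, weights$indicator), ]
  Y <- as.matrix(as.data.frame(panel)[codes])
  ewv <- drop(Y %*% w$comprehensive_weight)
  score_for <- function(ss) {
    j <- which(w$subsystem == ss)
    if (!length(j)) return(rep(NA_real_, nrow(Y)))
    drop(Y[, j, drop = FALSE] %*% w$type_weight[j])
  }
  cls <- classify_grade(ewv)
  structure(data.frame(region = panel$region, year = panel$year, ewv = ewv,
                       grade = cls$grade, status = cls$status,
                       p_score = score_for("P"), e_score = score_for("E"),
                       s_score = score_for("S"), n_score = score_for("N"),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("ews", "data.frame"))
}

#' Write an early-warning series to CSV
#' @param ews an `"ews"` data frame from [compute_ews()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ews <- function(ews, path) {
  utils::write.csv(as.data.frame(ews), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
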