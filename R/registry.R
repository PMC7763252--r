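#' Build an indicator registry
#'
#' The registry is the catalogue of indicators a panel is scored against:
#' a short unique code, a human-readable name, the subsystem it belongs to
#' (P population, E eco-environment, S socioeconomic, N natural resources),
#' and its direction. Positive (developmental) indicators are those where a
#' larger raw value means better ecological security; negative (restrictive)
#' indicators mean the opposite, and the two are normalized with mirrored
#' min-max formulas.
#'
#' @param code character vector of unique short identifiers.
#' @param name character vector of indicator names.
#' @param subsystem character vector, each one of `"P"`, `"E"`, `"S"`, `"N"`.
#' @param direction character vector, each `"positive"` or `"negative"`.
#' @param units character vector of measurement units (free text).
#' @return A data frame of class `"indicator_registry"` with one row per
#'   indicator.
#' @examples
#' indicator_registry(code = c("gdp", "noise"),
#'                    name = c("GDP per capita", "Noise exposure"),
#'                    subsystem = c("S", "E"),
#'                    direction = c("positive", "negative"),
#'                    units = c("yuan", "dB"))
#' @export
indicator_registry <- function(code, name = code, subsystem, direction,
                               units = "") {
  reg <- data.frame(code = as.character(code), name = as.character(name),
                    subsystem = as.character(subsystem),
                    direction = as.character(direction),
                    units = as.character(units),
                    stringsAsFactors = FALSE)
  validate_registry(reg)
}

validate_registry <- function(reg) {
  need <- c("code", "name", "subsystem", "direction", "units")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop("registry is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(reg$code))
    stop("duplicate indicator code(s): ",
         paste(unique(reg$code[duplicated(reg$code)]), collapse = ", "))
  bad <- !reg$subsystem %in% c("P", "E", "S", "N")
  if (any(bad))
    stop("invalid subsystem for ", paste(reg$code[bad], collapse = ", "),
         " (must be one of P, E, S, N)")
  bad <- !reg$direction %in% c("positive", "negative")
  if (any(bad))
    stop("invalid direction for ", paste(reg$code[bad], collapse = ", "),
         " (must be 'positive' or 'negative')")
  class(reg) <- c("indicator_registry", "data.frame")
  reg
}

#' Read an indicator registry from CSV
#'
#' Expects columns `code`, `name`, `subsystem`, `direction`, `units`.
#'
#' @param path path to a CSV file.
#' @return An `"indicator_registry"` data frame.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  validate_registry(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' The default PESN indicator registry
#'
#' Twenty indicators across the four PESN subsystems used for alpine
#' agricultural mountain-area ecological security early-warning: four
#' population indicators, six eco-environment indicators, six socioeconomic
#' indicators and four natural-resource indicators, each flagged positive or
#' negative.
#'
#' @return An `"indicator_registry"` data frame with 20 rows.
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "pesn_registry.csv",
                            package = "ecowarn", mustWork = TRUE))
}
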