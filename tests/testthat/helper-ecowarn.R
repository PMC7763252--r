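# shared builders for small in-code fixtures

small_registry <- function() {
  indicator_registry(
    code = c("gdp", "forest", "noise", "waste"),
    name = c("GDP per capita", "Forest cover", "Noise exposure",
             "Waste output"),
    subsystem = c("S", "N", "E", "E"),
    direction = c("positive", "positive", "negative", "negative"),
    units = c("yuan", "%", "dB", "t"))
}

# one small complete panel: 2 regions x 3 years x 4 indicators
small_panel <- function(registry = small_registry()) {
  df <- data.frame(
    region = rep(c("A", "B"), each = 3),
    year = rep(2011:2013, 2),
    gdp = c(1, 2, 4, 2, 3, 5),
    forest = c(10, 12, 14, 8, 9, 11),
    noise = c(60, 55, 50, 65, 62, 58),
    waste = c(5, 4, 3, 7, 6, 5))
  as_panel(df, registry)
}

# the comprehensive worked-example series (x0[1] plus the printed Y vector)
comprehensive_series <- function() {
  c(0.1893, 0.2905, 0.3505, 0.5768, 0.7200, 0.7774, 0.8047, 0.8771)
}
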