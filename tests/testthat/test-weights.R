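test_that("relative frequencies are proportional with the zero substitution", {
  expect_equal(relative_frequencies(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(relative_frequencies(c(2, 6)), c(0.25, 0.75))
  expect_equal(relative_frequencies(c(0, 1)), c(1e-4, 1))  # no renormalizing
  expect_error(relative_frequencies(c(0, 0)), "degenerate")
  expect_error(relative_frequencies(c(-1, 2)), "negative")
})

test_that("entropy is 1 at uniform, near 0 at concentration, exact in between", {
  expect_equal(indicator_entropy(rep(1 / 8, 8)), 1)
  expect_lt(indicator_entropy(c(1e-4, 1 - 1e-4)), 0.01)
  # hand-evaluated closed form: -(0.25 ln 0.25 + 0.75 ln 0.75) / ln 2
  expect_equal(indicator_entropy(c(0.25, 0.75)),
               -(0.25 * log(0.25) + 0.75 * log(0.75)) / log(2),
               tolerance = 1e-12)
  expect_equal(round(indicator_entropy(c(0.25, 0.75)), 4), 0.8113)
  expect_error(indicator_entropy(1), "at least 2")
})

test_that("identical columns split the weight equally", {
  reg <- indicator_registry(code = c("a", "b"), subsystem = c("P", "E"),
                            direction = "positive")
  df <- data.frame(region = "A", year = 2011:2014,
                   a = c(0.1, 0.4, 0.7, 1), b = c(0.1, 0.4, 0.7, 1))
  w <- compute_weights(as_panel(df, reg), reg)
  expect_equal(w$comprehensive_weight, c(0.5, 0.5))
  expect_equal(w$type_weight, c(1, 1))  # each alone in its subsystem
})

test_that("the more dispersed column gets the strictly larger weight", {
  # brute-force oracle on a 3-observation, 2-indicator panel: evaluate the
  # entropy-weight formulas directly and compare with compute_weights
  reg <- indicator_registry(code = c("flat", "spread"), subsystem = "P",
                            direction = "positive")
  df <- data.frame(region = "A", year = 2011:2013,
                   flat = c(0.48, 0.50, 0.52), spread = c(0.05, 0.50, 0.95))
  w <- compute_weights(as_panel(df, reg), reg)
  ent <- function(col) {
    f <- col / sum(col)
    -sum(f * log(f)) / log(3)
  }
  b <- 1 - c(ent(df$flat), ent(df$spread))
  expect_equal(w$comprehensive_weight, b / sum(b), tolerance = 1e-12)
  expect_gt(w$comprehensive_weight[2], w$comprehensive_weight[1])
})

test_that("published type weights equal comprehensive / subsystem share", {
  w <- load_fixture("published_weights")
  # e.g. population density: 0.0323 over the P-subsystem total 0.1788
  pd <- w[w$indicator == "pop_density", ]
  p_sum <- sum(w$comprehensive_weight[w$subsystem == "P"])
  expect_equal(p_sum, 0.1788, tolerance = 1e-9)
  expect_equal(pd$type_weight, 0.0323 / 0.1788, tolerance = 5e-4)
})

test_that("weights conserve mass and are invariant to permutation and duplication", {
  reg <- small_registry()
  for (seed in 1:5) {
    cfg <- synthetic_panel_config(n_regions = 3, n_years = 6, registry = reg,
                                  baseline = c(5, 8, 4, 6),
                                  slope = c(0.4, -0.2, 0.3, 0.1),
                                  noise_sd = 0.5, seed = seed)
    np <- normalize_panel(generate_panel(cfg), reg)
    w <- compute_weights(np, reg)
    expect_equal(sum(w$comprehensive_weight), 1, tolerance = 1e-9)
    expect_equal(as.vector(tapply(w$type_weight, w$subsystem, sum)),
                 rep(1, length(unique(w$subsystem))), tolerance = 1e-9)
    expect_true(all(w$comprehensive_weight >= 0))
    expect_true(all(w$entropy >= 0 & w$entropy <= 1))

    # permuting observations: identical weights
    perm <- as.data.frame(np)[sample(nrow(np)), ]
    w_perm <- compute_weights(
      structure(perm, indicators = panel_indicators(np),
                class = class(np)), reg)
    expect_equal(w_perm$comprehensive_weight, w$comprehensive_weight,
                 tolerance = 1e-12)

    # duplicating every observation: weights unchanged up to 1e-9. Tested on
    # zero-free columns: the f = 0 -> 0.0001 substitution is scale-breaking,
    # so a column's zero cells (min-max always produces one) would perturb
    # the algebraic invariance at ~1e-4 per zero.
    nz <- as.data.frame(np)
    for (cd in panel_indicators(np)) nz[[cd]] <- 0.05 + 0.9 * nz[[cd]]
    as_np <- function(df) structure(df, indicators = panel_indicators(np),
                                    class = class(np))
    w_nz <- compute_weights(as_np(nz), reg)
    dup2 <- rbind(nz, transform(nz, region = paste0(region, "_copy")))
    w_dup <- compute_weights(as_np(dup2), reg)
    expect_equal(w_dup$comprehensive_weight, w_nz$comprehensive_weight,
                 tolerance = 1e-9)
  }
})

test_that("an all-uniform panel is rejected as carrying zero information", {
  reg <- indicator_registry(code = c("a", "b"), subsystem = "P",
                            direction = "positive")
  df <- data.frame(region = "A", year = 2011:2014, a = 0.3, b = 0.7)
  expect_error(compute_weights(as_panel(df, reg), reg), "zero information")
})

test_that("weight tables round-trip through CSV", {
  w <- load_fixture("published_weights")
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights(w, path)
  w2 <- read_weights(path)
  expect_equal(w2$comprehensive_weight, w$comprehensive_weight)
  expect_equal(w2$type_weight, w$type_weight)
})
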