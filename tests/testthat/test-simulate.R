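test_that("simulated trees are deterministic, bifurcating, with positive lengths", {
  expect_error(simulate_tree(1), "at least 2")
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_true(all(t2$edge.length > 0))
  n1 <- ape::write.tree(simulate_tree(64, seed = 1))
  n2 <- ape::write.tree(simulate_tree(64, seed = 1))
  expect_identical(n1, n2)
  expect_false(identical(n1, ape::write.tree(simulate_tree(64, seed = 2))))
})

test_that("metacommunity simulation is deterministic and respects bounds", {
  cfg <- simulation_config(n_taxa = 40, sites = c(SL = 3, ML = 3, BL = 3),
                           replicates = 2, seed = 11)
  s1 <- simulate_metacommunity(cfg)
  s2 <- simulate_metacommunity(cfg)
  expect_identical(unclass(s1$table), unclass(s2$table))
  expect_identical(s1$env, s2$env)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))

  m <- unclass(s1$table)
  expect_true(all(m >= 0 & m == floor(m)))
  expect_true(all(colSums(m) > 0))
  spec <- cfg$env_spec
  for (k in seq_len(nrow(spec))) {
    v <- s1$env[[spec$variable[k]]]
    expect_true(all(v >= spec$lower[k] & v <= spec$upper[k]))
  }
  expect_equal(s1$env$DIN, s1$env$NO2 + s1$env$NO3 + s1$env$NH4, tolerance = 1e-9)
  expect_equal(s1$truth$regime, "selection")
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(n_taxa = 1), "at least 2")
  expect_error(simulation_config(selection_strength = -1), "non-negative")
  expect_error(simulation_config(niche_conservatism = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(breakpoint_spec = list(
    list(response = "r", driver = "nope", psi = 1, slope_left = 1,
         slope_right = 0, noise_sd = 0))), "nope")
  # psi outside the generated driver range is caught at generation time
  cfg <- simulation_config(n_taxa = 20, sites = c(SL = 3, ML = 3, BL = 3),
                           replicates = 1, seed = 2,
                           breakpoint_spec = list(
                             list(response = "r", driver = "DO", psi = 99,
                                  slope_left = 1, slope_right = 0, noise_sd = 0)))
  expect_error(simulate_metacommunity(cfg), "outside the generated range")
})

test_that("noiseless breakpoint responses lie exactly on the two-segment line", {
  cfg <- simulation_config(n_taxa = 20, sites = c(SL = 4, ML = 4, BL = 4),
                           replicates = 2, seed = 4,
                           breakpoint_spec = list(
                             list(response = "resp", driver = "DO", psi = 6.0,
                                  slope_left = 1, slope_right = 0, noise_sd = 0)))
  sim <- simulate_metacommunity(cfg)
  x <- sim$env$DO
  expected <- 1 * x + (0 - 1) * pmax(0, x - 6.0)
  expect_equal(sim$env$resp, expected, tolerance = 1e-12)
})

test_that("neutral pairs are less dissimilar than selection pairs at depth contrast", {
  # Monte-Carlo over replicate site pairs: mean Bray-Curtis between a surface
  # and a bottom sample under neutrality reflects sampling noise only and sits
  # below the selection regime's at the same depths.
  bc_cross <- function(regime, seed) {
    cfg <- simulation_config(n_taxa = 80, sites = c(SL = 5, ML = 2, BL = 5),
                             replicates = 2, assembly_regime = regime,
                             selection_strength = 10, niche_conservatism = 0.9,
                             seed = seed)
    sim <- simulate_metacommunity(cfg)
    bc <- bray_curtis(sim$table)
    lay <- layers(sim$table)
    mean(bc[lay == "SL", lay == "BL"])
  }
  neu <- vapply(1:6, function(s) bc_cross("neutral", s), 0)
  sel <- vapply(1:6, function(s) bc_cross("selection", 100 + s), 0)
  expect_lt(mean(neu), mean(sel))
  expect_gt(mean(sel) - mean(neu), 0.1)
})

test_that("selection_strength = 0 is statistically indistinguishable from neutral", {
  # 100 independent replicate pairs per regime, one Bray-Curtis value each,
  # so the two-sample comparison sees independent observations
  bc_one <- function(regime, strength, seed) {
    cfg <- simulation_config(n_taxa = 40, sites = c(SL = 1), replicates = 2,
                             assembly_regime = regime,
                             selection_strength = strength,
                             breakpoint_spec = list(), seed = seed)
    as.dist(bray_curtis(simulate_metacommunity(cfg)$table))[1]
  }
  bc0 <- vapply(1:100, function(s) bc_one("selection", 0, s), 0)
  bcN <- vapply(1:100, function(s) bc_one("neutral", 5, 1000 + s), 0)
  expect_gt(suppressWarnings(wilcox.test(bc0, bcN)$p.value), 0.01)
})

test_that("piecewise responses are continuous at the kink and replay identically", {
  d <- simulate_piecewise_response(200, 5, c(2, -1), noise_sd = 0, seed = 1)
  left <- 0 + 2 * 5
  eps <- 1e-6
  f <- function(x) 2 * x + (-1 - 2) * pmax(0, x - 5)
  expect_equal(f(5 - eps) - left, -2 * eps, tolerance = 1e-9)
  expect_equal(d$y, f(d$x), tolerance = 1e-12)

  d2 <- simulate_piecewise_response(50, 5, c(1.5, 1.5), noise_sd = 0, seed = 2)
  fit <- lm(y ~ x, data = d2)
  expect_equal(unname(coef(fit)[2]), 1.5, tolerance = 1e-9)
  expect_lt(sum(residuals(fit)^2), 1e-18)

  expect_identical(simulate_piecewise_response(30, 4, c(1, 0), noise_sd = 1, seed = 7),
                   simulate_piecewise_response(30, 4, c(1, 0), noise_sd = 1, seed = 7))
  expect_error(simulate_piecewise_response(30, 11, c(1, 0), x_range = c(0, 10)),
               "inside")
  expect_error(simulate_piecewise_response(4, 5, c(1, 0)), "at least 6")
})
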