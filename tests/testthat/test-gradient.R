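env_fixture <- function(n = 12, seed = 51) {
  set.seed(seed)
  data.frame(row.names = paste0("s", 1:n),
             pH = rnorm(n, 8, 0.2), DO = rnorm(n, 6.3, 0.5),
             NO3 = abs(rnorm(n, 0.02, 0.01)))
}

test_that("spearman screen recovers perfect monotone relations", {
  env <- env_fixture()
  resp <- data.frame(row.names = rownames(env),
                     same = env$pH,
                     anti = max(rank(env$pH)) + 1 - rank(env$pH))
  sc <- spearman_screen(resp, env, correction = "none")
  expect_equal(sc$rho[sc$response == "same" & sc$variable == "pH"], 1)
  expect_equal(sc$rho[sc$response == "anti" & sc$variable == "pH"], -1)
  expect_equal(sc$p[sc$response == "same" & sc$variable == "pH"], 0)
})

test_that("spearman screen handles missing and constant columns", {
  env <- env_fixture()
  env$flat <- 3
  resp <- data.frame(row.names = rownames(env), y = rnorm(12))
  resp$y[1:2] <- NA
  sc <- spearman_screen(resp, env)
  flat_row <- sc[sc$variable == "flat", ]
  expect_true(is.na(flat_row$rho))
  expect_equal(flat_row$flag, "constant")
  expect_equal(sc$n[sc$variable == "pH"], 10)  # pairwise deletion
})

test_that("spearman type-I rate under independence is near alpha", {
  set.seed(53)
  n <- 20
  hits <- replicate(1000, {
    rho <- cor(rnorm(n), rnorm(n), method = "spearman")
    t <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
    2 * pt(t, n - 2, lower.tail = FALSE) < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 2 * sqrt(0.05 * 0.95 / 1000) + 0.01)
})

test_that("mantel self-comparison gives r = 1 and the minimal p", {
  sim <- simulate_metacommunity(simulation_config(
    n_taxa = 25, sites = c(SL = 2, ML = 2, BL = 2), replicates = 2, seed = 54))
  dm <- bray_curtis(sim$table)
  mt <- mantel_test(dm, dm, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 100)
})

test_that("mantel p from sampled permutations matches the exhaustive 24-element null", {
  set.seed(55)
  m <- matrix(rpois(5 * 4, 6) + 1, 5, 4, dimnames = list(paste0("t", 1:5),
                                                         paste0("s", 1:4)))
  dm1 <- bray_curtis(community_table(m))
  env <- data.frame(row.names = colnames(m), DO = c(6.1, 6.4, 5.8, 7.0))
  dm2 <- env_distance(env, "DO")
  ex <- mantel_test(dm1, dm2, exhaustive = TRUE)
  expect_equal(ex$n_perm, 24)
  sm <- mantel_test(dm1, dm2, n_perm = 999, seed = 2)
  expect_equal(sm$r, ex$r, tolerance = 1e-12)
  mc_se <- sqrt(ex$p * (1 - ex$p) / 999)
  expect_lt(abs(sm$p - ex$p), 3 * mc_se + 2 / 1000)
})

test_that("mantel r agrees with the vegan implementation", {
  sim <- simulate_metacommunity(simulation_config(
    n_taxa = 30, sites = c(SL = 3, ML = 3, BL = 3), replicates = 1, seed = 56))
  dm1 <- bray_curtis(sim$table)
  dm2 <- env_distance(sim$env, "DO")
  ours <- mantel_test(dm1, dm2, method = "pearson", n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(dm1), as.dist(dm2), method = "pearson",
                       permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("mantel errors on mismatched sample sets, naming the difference", {
  d1 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d2 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "x"), c("a", "b", "x")))
  expect_error(mantel_test(d1, d2), "x")
})

test_that("linear fits recover exact lines and reject constants", {
  x <- seq(1, 10, 0.5)
  lf <- linear_fit(x, 2 * x + 1)
  expect_equal(lf$slope, 2, tolerance = 1e-12)
  expect_equal(lf$intercept, 1, tolerance = 1e-12)
  expect_equal(lf$r_squared, 1, tolerance = 1e-12)
  expect_equal(lf$p, 0)
  lc <- linear_fit(x, rep(3, length(x)))
  expect_equal(lc$slope, 0, tolerance = 1e-12)
  expect_equal(lc$r_squared, 0, tolerance = 1e-12)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
})

test_that("linear-fit p-values are uniform under the null", {
  set.seed(57)
  ps <- replicate(500, linear_fit(rnorm(15), rnorm(15))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("pairwise responses map onto pair-mean or pair-difference drivers", {
  pairs <- data.frame(sample_i = c("s1", "s1"), sample_j = c("s2", "s3"),
                      bc = c(0.4, 0.8))
  env <- data.frame(row.names = paste0("s", 1:3), DO = c(6, 7, 8))
  pm <- pairwise_gradient(pairs, env, "DO", "bc", how = "mean")
  expect_equal(pm$x, c(6.5, 7))
  pd <- pairwise_gradient(pairs, env, "DO", "bc", how = "diff")
  expect_equal(pd$x, c(1, 2))
  expect_equal(pm$y, pairs$bc)
})

test_that("threshold report yields one row per layer and flags failures", {
  set.seed(58)
  layers <- c("SL", "ML", "BL")
  psis <- c(SL = 3, ML = 5, BL = 7)
  dat <- do.call(rbind, lapply(layers, function(l) {
    d <- simulate_piecewise_response(60, psis[[l]], c(2, -1), noise_sd = 0.3,
                                     x_range = c(0, 10),
                                     seed = match(l, layers))
    data.frame(layer = l, DO = d$x, resp = d$y)
  }))
  rep1 <- threshold_report(dat, data.frame(response = "resp", driver = "DO"))
  expect_equal(nrow(rep1), 3)
  est <- setNames(rep1$psi, rep1$layer)
  expect_equal(order(est[layers]), order(psis[layers]))  # rank recovery
  expect_true(all(abs(est[layers] - psis[layers]) < 1))

  # a layer with no breakpoint is flagged, not dropped
  lin <- data.frame(layer = "LIN", DO = seq(1, 10, length = 40),
                    resp = 0.5 * seq(1, 10, length = 40))
  rep2 <- threshold_report(rbind(dat, lin),
                           data.frame(response = "resp", driver = "DO"))
  expect_equal(nrow(rep2), 4)
  expect_equal(rep2$flag[rep2$layer == "LIN"], "no_change_point")

  # too few points -> carried as flagged row
  tiny <- data.frame(layer = "TINY", DO = 1:4, resp = rnorm(4))
  rep3 <- threshold_report(rbind(dat, tiny),
                           data.frame(response = "resp", driver = "DO"))
  expect_true(nzchar(rep3$flag[rep3$layer == "TINY"]))
  expect_true(is.na(rep3$psi[rep3$layer == "TINY"]))
})
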