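test_that("betaMNTD matches hand values on the three-tip tree", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  # both samples only taxon A -> nearest neighbour is itself, distance 0
  ct0 <- make_ct(cbind(c(4, 0, 0), c(9, 0, 0)), taxa = c("A", "B", "C"))
  expect_equal(beta_mntd(ct0, tr, pair = c("s1", "s2")), 0)
  # sample1 = {A}, sample2 = {B}: 0.5 * (2 + 2) = 2
  ct1 <- make_ct(cbind(c(5, 0, 0), c(0, 3, 0)), taxa = c("A", "B", "C"))
  expect_equal(beta_mntd(ct1, tr, pair = c("s1", "s2")), 2)
})

test_that("betaMNTD equals the exhaustive min-over-pairs oracle and picante", {
  set.seed(13)
  for (r in 1:4) {
    tr <- simulate_tree(10, seed = r)
    m <- matrix(rbinom(10 * 4, 8, 0.4), 10, 4)
    m[, colSums(m) == 0] <- 1
    ct <- make_ct(m, taxa = tr$tip.label)
    D <- patristic(tr)
    rel <- relative_abundance(ct)
    got <- beta_mntd(ct, tr)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(got[i, j], bmntd_oracle(D, rel[, i], rel[, j]),
                   tolerance = 1e-12)
    }
    ref <- as.matrix(picante::comdistnt(t(unclass(ct)), D, abundance.weighted = TRUE))
    expect_equal(unname(got), unname(ref), tolerance = 1e-9)
  }
})

test_that("shared taxa can only decrease or preserve nearest-neighbour terms", {
  set.seed(14)
  tr <- simulate_tree(12, seed = 3)
  base <- matrix(0, 12, 2, dimnames = list(tr$tip.label, c("s1", "s2")))
  base[1:4, 1] <- c(3, 2, 1, 1)
  base[5:8, 2] <- c(4, 1, 2, 2)
  ct <- make_ct(base, taxa = tr$tip.label)
  b0 <- beta_mntd(ct, tr, pair = c("s1", "s2"))
  shared <- base
  shared[9, ] <- c(2, 2)  # add a taxon to both samples
  D <- patristic(tr)
  rel <- relative_abundance(make_ct(shared, taxa = tr$tip.label))
  # per-taxon nearest-neighbour distance never increases for taxa kept
  for (i in rownames(shared)[shared[, 1] > 0]) {
    old_partners <- rownames(base)[base[, 2] > 0]
    new_partners <- rownames(shared)[shared[, 2] > 0]
    expect_lte(min(D[i, new_partners]), min(D[i, old_partners]))
  }
})

test_that("taxa absent from the tree are reported by name", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  ct <- make_ct(cbind(c(1, 2), c(2, 1)), taxa = c("A", "ghost"))
  expect_error(beta_mntd(ct, tr), "ghost")
  expect_error(bnti(ct, tr, null_reps = 99), "ghost")
})

test_that("a star tree yields a degenerate null flagged as NA, never infinite", {
  star <- read_tree(text = "(A:1,B:1,C:1,D:1);")
  ct <- make_ct(cbind(c(3, 1, 0, 0), c(0, 0, 2, 2)), taxa = c("A", "B", "C", "D"))
  b <- bnti(ct, star, null_reps = 99, seed = 1)
  expect_true(is.na(b$bnti[1]))
  expect_equal(b$flag[1], "degenerate_null")
})

test_that("sampled taxa-shuffle null matches exhaustive enumeration on 4 tips", {
  tr <- simulate_tree(4, seed = 2)
  m <- cbind(c(5, 2, 0, 0), c(0, 1, 4, 0))
  ct <- make_ct(m, taxa = tr$tip.label)
  D <- patristic(tr)
  rel <- relative_abundance(ct)
  exact <- bnti_null_exhaustive(D, rel[, 1], rel[, 2])  # all 4! = 24 relabelings
  b <- bnti(ct, tr, null_reps = 999, seed = 3)
  mc_se <- sd(exact) / sqrt(999)
  expect_lt(abs(b$null_mean[1] - mean(exact)), 3 * mc_se)
  expect_lt(abs(b$null_sd[1] - sd(exact)), 4 * mc_se)
})

test_that("betaNTI of a community drawn from its own null is centred near zero", {
  tr <- simulate_tree(12, seed = 5)
  set.seed(55)
  m <- matrix(rbinom(12 * 6, 4, 0.3), 12, 6)  # sparse: presence sets differ
  m[, colSums(m) == 0] <- 1
  ct <- make_ct(m, taxa = tr$tip.label)
  zs <- vapply(1:40, function(s) {
    perm <- sample(nrow(m))
    mp <- m[perm, ]
    dimnames(mp) <- list(tr$tip.label, paste0("s", seq_len(ncol(m))))
    b <- bnti(community_table(mp), tr, null_reps = 199, seed = s)
    mean(b$bnti, na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)) + 0.15)
})

test_that("across-seed variance of betaNTI shrinks like 1/null_reps", {
  tr <- simulate_tree(15, seed = 6)
  set.seed(66)
  m <- matrix(0, 15, 2)
  m[1:9, 1] <- rpois(9, 4) + 1   # partially disjoint presence sets keep the
  m[6:15, 2] <- rpois(10, 4) + 1 # null distribution non-degenerate
  ct <- make_ct(m, taxa = tr$tip.label)
  z99 <- vapply(1:30, function(s) bnti(ct, tr, null_reps = 99, seed = s)$bnti[1], 0)
  z999 <- vapply(1:30, function(s) bnti(ct, tr, null_reps = 999, seed = s)$bnti[1], 0)
  ratio <- var(z99) / var(z999)
  expect_gt(ratio, 3)   # expected ~10, generous Monte-Carlo margin
})

test_that("RCbray hits its -1 and +1 boundaries on constructed pairs", {
  set.seed(17)
  pool <- matrix(rpois(30 * 6, 2), 30, 6)
  pool[, colSums(pool) == 0] <- 1
  # identical pair: BC_obs = 0, below every null draw
  ident <- cbind(a = pool[, 1] + 1, b = pool[, 1] + 1)
  ct_lo <- make_ct(cbind(ident, pool[, 2:6]))
  r_lo <- rc_bray(ct_lo, null_reps = 199, seed = 1)
  expect_equal(r_lo$rc_bray[r_lo$sample_i == "s1" & r_lo$sample_j == "s2"][1], -1)
  # disjoint pair: BC_obs = 1, above every null draw with a shared pool
  disj <- matrix(0, 30, 2)
  disj[1:15, 1] <- 3
  disj[16:30, 2] <- 3
  ct_hi <- make_ct(cbind(disj, pool[, 2:6] + 1))
  r_hi <- rc_bray(ct_hi, null_reps = 199, seed = 2)
  expect_equal(r_hi$rc_bray[r_hi$sample_i == "s1" & r_hi$sample_j == "s2"][1], 1)
})

test_that("a single-taxon pool is flagged degenerate", {
  ct <- make_ct(matrix(c(5, 8, 3), 1, 3), taxa = "only")
  r <- rc_bray(ct, null_reps = 99)
  expect_true(all(r$flag == "degenerate_pool"))
  expect_true(all(is.na(r$rc_bray)))
})

test_that("process classification follows the betaNTI/RC rules incl. boundaries", {
  b <- c(2.5, -3, 1.0, 0, 0, 2.0, -2.0, NA)
  r <- c(0, 0, 0.99, -0.99, 0, 0.5, 0.2, 0.3)
  p <- classify_processes(b, r)
  expect_equal(as.character(p),
               c("heterogeneous_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift",
                 "drift", "drift", NA))
})

test_that("assembly analysis returns per-group fractions that sum to one", {
  sim <- simulate_metacommunity(simulation_config(
    n_taxa = 40, sites = c(SL = 3, ML = 3, BL = 3), replicates = 2, seed = 12))
  res <- assembly_analysis(sim$table, sim$tree, null_reps = 99, seed = 3)
  sums <- tapply(res$fractions$fraction, res$fractions$group, sum)
  expect_equal(as.vector(sums), rep(1, 3), tolerance = 1e-9)
  df <- deterministic_fraction(res)
  for (g in names(df)) {
    fr <- res$fractions[res$fractions$group == g, ]
    expect_equal(df[[g]],
                 sum(fr$fraction[fr$process %in% c("heterogeneous_selection",
                                                   "homogeneous_selection")]),
                 tolerance = 1e-9)
  }
  expect_true(all(res$pairs$rc_bray >= -1 & res$pairs$rc_bray <= 1, na.rm = TRUE))
})
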