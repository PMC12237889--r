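rank_table <- function() {
  # t1 and t2 share ranks exactly; t3 reverses them; t4..t8 add noise taxa
  n <- 10
  set.seed(23)
  base <- sample(seq(10, 100, 10))
  m <- rbind(t1 = base, t2 = base * 2, t3 = max(base) + 10 - base,
             t4 = rpois(n, 20) + 1, t5 = rpois(n, 20) + 1,
             t6 = rpois(n, 20) + 1, t7 = rpois(n, 20) + 1,
             t8 = rpois(n, 20) + 1)
  colnames(m) <- paste0("s", seq_len(n))
  community_table(m)
}

test_that("perfectly concordant and discordant taxa produce signed edges", {
  net <- build_network(rank_table(), min_prevalence = 0, rho_threshold = 0.9,
                       alpha = 0.05, correction = "none")
  e <- net$edges
  up <- e[e$from == "t1" & e$to == "t2", ]
  expect_equal(up$rho, 1, tolerance = 1e-9)
  expect_equal(up$sign, "+")
  dn <- e[e$from == "t1" & e$to == "t3", ]
  expect_equal(dn$rho, -1, tolerance = 1e-9)
  expect_equal(dn$sign, "-")
})

test_that("edge filters are monotone in rho threshold and alpha", {
  ct <- rank_table()
  counts <- function(rho, alpha, corr = "none")
    nrow(build_network(ct, min_prevalence = 0, rho_threshold = rho,
                       alpha = alpha, correction = corr)$edges)
  expect_gte(counts(0.3, 0.05), counts(0.6, 0.05))
  expect_gte(counts(0.6, 0.05), counts(0.9, 0.05))
  expect_gte(counts(0.5, 0.05), counts(0.5, 0.01))
  expect_gte(counts(0.5, 0.05, "none"), counts(0.5, 0.05, "bonferroni"))
})

test_that("fewer than five samples or constant taxa are handled explicitly", {
  m <- matrix(rpois(12, 5) + 1, 3, 4)
  expect_error(build_network(make_ct(m)), "at least 5")
  set.seed(24)
  a <- sample(1:19, 6)
  b <- sample(1:19, 6)
  mm <- rbind(const = 5, t1 = a, t2 = 20 - a, t3 = b, t4 = 20 - b)
  colnames(mm) <- paste0("s", 1:6)  # equal totals -> const is constant in
  expect_warning(build_network(community_table(mm), min_prevalence = 0,
                               rho_threshold = 0.99, correction = "none"),
                 "const")          # relative abundance
})

test_that("topology reproduces closed forms for K4, a path, and two triangles", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  tk <- topology(k4, seed = 1)
  expect_equal(tk$average_degree, 3)
  expect_equal(tk$density, 1)
  expect_equal(tk$clustering_coefficient, 1)

  path <- igraph::graph_from_literal(A - B, B - C)
  tp <- topology(path, seed = 1)
  expect_equal(tp$average_degree, 4 / 3, tolerance = 1e-12)
  expect_equal(tp$density, 2 / 3, tolerance = 1e-12)
  expect_equal(tp$clustering_coefficient, 0)

  tri2 <- igraph::graph_from_literal(A - B, B - C, C - A, D - E, E - F, F - D)
  tt <- topology(tri2, seed = 1)
  expect_equal(tt$n_modules, 2)
  # Q for two disjoint triangles: 2 * (3/6 - (6/12)^2) = 0.5
  expect_equal(tt$modularity, 0.5, tolerance = 1e-9)
  expect_gt(tt$modularity, 0)
})

test_that("average degree and density closed forms hold on built networks", {
  sim <- simulate_metacommunity(simulation_config(
    n_taxa = 40, sites = c(SL = 4, ML = 4, BL = 4), replicates = 2, seed = 19))
  net <- build_network(sim$table, min_prevalence = 0.2, rho_threshold = 0.5)
  pr <- topology(net, seed = 2)
  expect_equal(pr$average_degree, 2 * pr$n_edges / pr$n_nodes, tolerance = 1e-12)
  expect_equal(pr$density, 2 * pr$n_edges / (pr$n_nodes * (pr$n_nodes - 1)),
               tolerance = 1e-12)
  expect_true(pr$positive_edge_fraction >= 0 && pr$positive_edge_fraction <= 1)
  # seeded Louvain is reproducible
  expect_equal(topology(net, seed = 2)$modularity, pr$modularity)
})

test_that("independent taxa pass the uncorrected p filter at about the alpha rate", {
  # disjoint taxon pairs -> independent tests; see the acceptance suite for
  # the full-size calibration
  set.seed(29)
  n <- 30
  m <- matrix(rlnorm(200 * n, 3, 1), 200, n)
  ct <- make_ct(round(m) + 1)
  net <- build_network(ct, min_prevalence = 0, rho_threshold = 0,
                       alpha = 0.05, correction = "none")
  pairs <- paste0("t", seq(1, 199, 2), "|t", seq(2, 200, 2))
  hits <- with(net$edges, paste0(from, "|", to))
  rate <- mean(pairs %in% hits)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
})

test_that("compare_layers returns one deterministic row per layer", {
  sim <- simulate_metacommunity(simulation_config(
    n_taxa = 50, sites = c(SL = 4, ML = 4, BL = 4), replicates = 2, seed = 20))
  cmp <- compare_layers(sim$table, seed = 1, min_prevalence = 0.2,
                        rho_threshold = 0.5)
  expect_equal(nrow(cmp$properties), 3)
  expect_setequal(cmp$properties$layer, c("SL", "ML", "BL"))
  cmp2 <- compare_layers(sim$table, seed = 1, min_prevalence = 0.2,
                         rho_threshold = 0.5)
  expect_equal(cmp$properties, cmp2$properties)

  # identical per-layer tables give identical property rows
  tabs <- list(L1 = sim$table, L2 = sim$table)
  cmp3 <- compare_layers(tabs, seed = 1, min_prevalence = 0.2, rho_threshold = 0.5)
  expect_equal(cmp3$properties$n_edges[1], cmp3$properties$n_edges[2])
  expect_equal(cmp3$properties$modularity[1], cmp3$properties$modularity[2])
})

test_that("a correlated layer is denser than an independent-taxa layer", {
  set.seed(33)
  n <- 20; T <- 30
  z <- rnorm(n)
  # only half the taxa load on the shared factor, so it survives the
  # relative-abundance closure
  corr <- t(vapply(1:T, function(i) {
    load <- if (i <= T / 2) 1.2 else 0
    round(exp(2 + load * z + 0.4 * rnorm(n)) * 10)
  }, numeric(n)))
  indep <- t(vapply(1:T, function(i) round(exp(2 + rnorm(n)) * 10), numeric(n)))
  ct_c <- make_ct(corr + 1, samples = paste0("c", 1:n))
  ct_i <- make_ct(indep + 1, samples = paste0("i", 1:n))
  cmp <- compare_layers(list(corr = ct_c, indep = ct_i), seed = 1,
                        min_prevalence = 0, rho_threshold = 0.6)
  d <- setNames(cmp$properties$density, cmp$properties$layer)
  expect_gt(d["corr"], d["indep"])
})
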