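# Synthetic-data generators: phylogenies, gradient-structured communities
# with known assembly regime, and piecewise-linear responses with known
# breakpoints.  Everything is seeded; identical (config, seed) replays
# byte-identically.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a random rooted bifurcating phylogeny
#'
#' Pure-birth (Yule) tree via [ape::rphylo()], giving an ultrametric rooted
#' tree with strictly positive branch lengths — the natural substrate for
#' Brownian-motion trait evolution.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @return a `phylo` object with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be at least 2")
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  validate_tree(tr)
}

default_env_spec <- function() {
  data.frame(
    variable = c("Temp", "Salinity", "pH", "DO", "NO2", "NO3", "NH4",
                 "TN", "PO4", "TOC", "COD", "Chla"),
    SL = c(30.5, 33.2, 8.15, 6.9, 0.005, 0.004, 0.010, 6.5, 0.005, 1.8, 1.2, 2.5),
    ML = c(26.5, 33.6, 8.00, 6.3, 0.010, 0.015, 0.015, 7.4, 0.015, 1.6, 1.1, 1.5),
    BL = c(24.5, 34.0, 7.85, 5.7, 0.015, 0.025, 0.020, 8.2, 0.025, 1.4, 1.0, 0.8),
    sd = c(1.2, 0.3, 0.12, 0.35, 0.004, 0.008, 0.005, 0.5, 0.006, 0.3, 0.2, 0.4),
    lower = c(0, 0, 6.5, 0.1, 0, 0, 0, 0, 0, 0, 0, 0),
    upper = c(40, 40, 9.0, 12, 1, 1, 1, 20, 1, 10, 10, 20),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the metacommunity simulator
#'
#' Defaults emulate a subtropical gulf depth-layer survey: 21/16/19 sites in
#' surface/middle/bottom layers with five replicate samples each (280
#' samples), a few hundred taxa, environmental gradients structured by
#' layer, and taxa whose environmental optima evolved along the phylogeny
#' (Brownian motion) so that selection leaves a phylogenetic signal.
#'
#' @param n_taxa number of taxa.
#' @param sites named integer vector: sites per layer.
#' @param replicates replicate samples per site.
#' @param env_spec data.frame with columns `variable`, one mean column per
#'   layer, `sd`, `lower`, `upper`; see `microstab:::default_env_spec()`.
#' @param assembly_regime `"selection"` or `"neutral"`.
#' @param selection_strength non-negative; Gaussian niche decay rate per
#'   squared standardized deviation of the driver from a taxon's optimum
#'   (0 collapses to the neutral regime).
#' @param niche_conservatism in `[0, 1]`: share of optimum variance inherited
#'   along the tree (Brownian motion) versus independent noise.
#' @param selection_driver environmental variable carrying the selective
#'   gradient.
#' @param mean_depth,depth_sdlog log-normal per-sample sequencing depth.
#' @param sad_sdlog log-sd of the regional log-normal species-abundance
#'   distribution; the default 2 gives the strongly uneven abundances and
#'   sparse presence typical of amplicon surveys.
#' @param breakpoint_spec list of piecewise response definitions, each a list
#'   with `response`, `driver`, `psi`, `slope_left`, `slope_right`,
#'   `noise_sd`, optional `intercept`; responses are appended to the
#'   environmental table with the true breakpoint recorded in the truth.
#' @param seed master seed.
#' @return object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_taxa = 300,
                              sites = c(SL = 21, ML = 16, BL = 19),
                              replicates = 5,
                              env_spec = default_env_spec(),
                              assembly_regime = c("selection", "neutral"),
                              selection_strength = 5,
                              niche_conservatism = 0.8,
                              selection_driver = "DO",
                              mean_depth = 10000,
                              depth_sdlog = 0.3,
                              sad_sdlog = 2,
                              breakpoint_spec = list(
                                list(response = "beta_response", driver = "DO",
                                     psi = 6.3, slope_left = 0.25,
                                     slope_right = 0.02, noise_sd = 0.05)),
                              seed = 1) {
  assembly_regime <- match.arg(assembly_regime)
  if (n_taxa < 2) stop("n_taxa must be at least 2")
  if (selection_strength < 0) stop("selection_strength must be non-negative")
  if (niche_conservatism < 0 || niche_conservatism > 1)
    stop("niche_conservatism must lie in [0, 1]")
  layers <- setdiff(colnames(env_spec), c("variable", "sd", "lower", "upper"))
  if (!all(names(sites) %in% layers))
    stop("sites names must match env_spec layer columns")
  if (!selection_driver %in% env_spec$variable)
    stop("selection_driver '", selection_driver, "' absent from env_spec")
  for (bp in breakpoint_spec) {
    need <- c("response", "driver", "psi", "slope_left", "slope_right", "noise_sd")
    miss <- setdiff(need, names(bp))
    if (length(miss))
      stop("breakpoint_spec entry missing fields: ", paste(miss, collapse = ", "))
    if (!bp$driver %in% env_spec$variable)
      stop("breakpoint_spec driver '", bp$driver, "' absent from env_spec")
  }
  structure(list(n_taxa = n_taxa, sites = sites, replicates = replicates,
                 env_spec = env_spec, assembly_regime = assembly_regime,
                 selection_strength = selection_strength,
                 niche_conservatism = niche_conservatism,
                 selection_driver = selection_driver,
                 mean_depth = mean_depth, depth_sdlog = depth_sdlog,
                 sad_sdlog = sad_sdlog,
                 breakpoint_spec = breakpoint_spec, seed = seed),
            class = "simulation_config")
}

#' Simulate a depth-stratified metacommunity with known ground truth
#'
#' Under the selection regime each taxon carries an environmental optimum
#' evolved on the tree (Brownian motion mixed with independent noise by
#' `niche_conservatism`); expected relative abundance decays Gaussian-wise
#' with the standardized distance between a sample's driver value and the
#' optimum, scaled by `selection_strength`.  Counts are multinomial draws at
#' log-normal sequencing depths.  Under the neutral regime expected
#' abundances are a shared log-normal species-abundance distribution,
#' independent of the environment.
#'
#' @param config a [simulation_config()].
#' @return list of class `metacommunity_sim` with elements `table`
#'   ([community_table()] with layer labels), `env` (data.frame incl.
#'   `layer` and any piecewise response columns), `tree` (`phylo`), and
#'   `truth` (regime, optima, breakpoints, seed).
#' @export
simulate_metacommunity <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    tree <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
    tree$tip.label <- paste0("t", seq_len(config$n_taxa))

    spec <- config$env_spec
    layer_names <- names(config$sites)
    sample_layer <- rep(layer_names, config$sites[layer_names] * config$replicates)
    site_of <- unlist(lapply(layer_names, function(l)
      rep(seq_len(config$sites[[l]]), each = config$replicates)))
    sample_ids <- unlist(lapply(layer_names, function(l) {
      as.vector(t(outer(sprintf("%s%02d", l, seq_len(config$sites[[l]])),
                        paste0("_r", seq_len(config$replicates)), paste0)))
    }))
    n_samp <- length(sample_ids)

    env <- data.frame(row.names = sample_ids)
    for (k in seq_len(nrow(spec))) {
      v <- spec$variable[k]
      mu <- unlist(spec[k, layer_names])[sample_layer]
      site_eff <- rnorm(sum(config$sites), 0, spec$sd[k] / 2)
      site_idx <- cumsum(c(0, config$sites[layer_names]))[match(sample_layer, layer_names)] + site_of
      x <- mu + site_eff[site_idx] + rnorm(n_samp, 0, spec$sd[k])
      env[[v]] <- pmin(pmax(x, spec$lower[k]), spec$upper[k])
    }
    env$DIN <- env$NO2 + env$NO3 + env$NH4
    env$layer <- sample_layer

    base <- rlnorm(config$n_taxa, meanlog = 0, sdlog = config$sad_sdlog)
    driver <- env[[config$selection_driver]]
    optima <- NULL
    if (config$assembly_regime == "selection") {
      bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
      z_bm <- as.numeric(scale(bm))
      z_iid <- rnorm(config$n_taxa)
      cc <- config$niche_conservatism
      z <- sqrt(cc) * z_bm + sqrt(1 - cc) * z_iid
      optima <- mean(driver) + z * sd(driver) * 1.2
      names(optima) <- tree$tip.label
    }
    sx <- sd(driver)
    depths <- pmax(50, round(rlnorm(n_samp, log(config$mean_depth), config$depth_sdlog)))
    counts <- matrix(0, config$n_taxa, n_samp,
                     dimnames = list(tree$tip.label, sample_ids))
    for (s in seq_len(n_samp)) {
      if (config$assembly_regime == "selection" && config$selection_strength > 0) {
        lw <- log(base) - config$selection_strength *
          ((driver[s] - optima) / sx)^2 / 2
        p <- exp(lw - max(lw))
      } else {
        p <- base
      }
      counts[, s] <- rmultinom(1, depths[s], p / sum(p))
    }
    # multinomial sampling can leave a sample empty only if depth were 0;
    # depths are bounded below so every column sum is positive

    truth <- list(regime = config$assembly_regime,
                  selection_strength = config$selection_strength,
                  niche_conservatism = config$niche_conservatism,
                  selection_driver = config$selection_driver,
                  optima = optima, seed = config$seed,
                  breakpoints = config$breakpoint_spec)

    for (bp in config$breakpoint_spec) {
      x <- env[[bp$driver]]
      if (bp$psi <= min(x) || bp$psi >= max(x))
        stop("breakpoint psi = ", bp$psi, " for driver '", bp$driver,
             "' falls outside the generated range [",
             signif(min(x), 4), ", ", signif(max(x), 4), "]")
      intercept <- bp$intercept %||% 0
      env[[bp$response]] <- intercept + bp$slope_left * x +
        (bp$slope_right - bp$slope_left) * pmax(0, x - bp$psi) +
        rnorm(length(x), 0, bp$noise_sd)
    }

    tab <- community_table(counts, layer = sample_layer)
    structure(list(table = tab, env = env, tree = tree, truth = truth),
              class = "metacommunity_sim")
  })
}

#' @export
print.metacommunity_sim <- function(x, ...) {
  cat(sprintf("metacommunity_sim: %d taxa x %d samples (%s regime)\n",
              nrow(x$table), ncol(x$table), x$truth$regime))
  invisible(x)
}

#' Simulate a piecewise-linear response with a known breakpoint
#'
#' Generates `y = intercept + slope_left * x + (slope_right - slope_left) *
#' max(0, x - psi_true) + N(0, noise_sd)` on `x` drawn uniformly over
#' `x_range` — a continuous broken-stick relation, the standalone fixture
#' for segmented-regression recovery checks.
#'
#' @param n number of points (>= 6).
#' @param psi_true breakpoint, strictly inside `x_range`.
#' @param slopes length-2 numeric: left and right slopes.
#' @param intercept intercept of the left segment.
#' @param noise_sd Gaussian noise standard deviation.
#' @param x_range length-2 numeric range for the driver.
#' @param seed integer seed.
#' @return data.frame with columns `x`, `y`.
#' @export
simulate_piecewise_response <- function(n, psi_true, slopes, intercept = 0,
                                        noise_sd = 0, x_range = c(0, 10),
                                        seed = 1) {
  if (n < 6) stop("n must be at least 6")
  if (psi_true <= x_range[1] || psi_true >= x_range[2])
    stop("psi_true must lie strictly inside x_range")
  with_seed(seed, {
    x <- sort(runif(n, x_range[1], x_range[2]))
    y <- intercept + slopes[1] * x +
      (slopes[2] - slopes[1]) * pmax(0, x - psi_true) +
      rnorm(n, 0, noise_sd)
    data.frame(x = x, y = y)
  })
}
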