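# Composed pipeline: simulate (or load) -> diversity -> assembly ->
# networks -> per-sample metrics -> thresholds, fully seeded, with every
# product written to the output directory and the configuration serialized
# alongside as provenance.

#' Pipeline run configuration
#'
#' Either point `community`/`tree`/`env` at input files (TSV / newick / TSV)
#' or leave them `NULL` to simulate inputs from `sim`.  All stage parameters
#' and the master seed live here; the whole object is serialized to
#' `provenance.json` in the output directory so any run is reproducible
#' from its artifacts.
#'
#' @param community,tree,env optional input file paths.
#' @param sim a [simulation_config()] used when inputs are not given.
#' @param null_reps permutations for betaNTI and RCbray nulls.
#' @param min_prevalence,rho_threshold,alpha,correction network filters, see
#'   [build_network()].
#' @param removal_fraction,removal_reps robustness parameters.
#' @param conn_null_reps shuffle nulls for [connectedness()].
#' @param min_seg segmented-regression guard, see [segmented_fit()].
#' @param targets data.frame with `response`/`driver` columns for
#'   [threshold_report()]; `NULL` selects defaults (Simpson diversity vs pH,
#'   stability vs DO, complexity vs NO3, plus any simulated piecewise
#'   responses vs their drivers).
#' @param run_assembly set `FALSE` to skip the null-model stage.
#' @param seed master seed; every stage derives its own stream from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(community = NULL, tree = NULL, env = NULL,
                       sim = simulation_config(),
                       null_reps = 999, min_prevalence = 0.2,
                       rho_threshold = 0.6, alpha = 0.05, correction = "BH",
                       removal_fraction = 0.5, removal_reps = 100,
                       conn_null_reps = 100, min_seg = 3,
                       targets = NULL, run_assembly = TRUE, seed = 42) {
  structure(list(community = community, tree = tree, env = env, sim = sim,
                 null_reps = null_reps, min_prevalence = min_prevalence,
                 rho_threshold = rho_threshold, alpha = alpha,
                 correction = correction,
                 removal_fraction = removal_fraction,
                 removal_reps = removal_reps,
                 conn_null_reps = conn_null_reps, min_seg = min_seg,
                 targets = targets, run_assembly = run_assembly, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing each product to
#' `out_dir` in its documented format: `community.tsv`, `env.tsv`,
#' `tree.nwk` (+ `truth.json` for simulated inputs), `alpha.tsv`,
#' `bray_curtis.tsv`, `group_tests.json`, `pairwise.tsv`, `fractions.json`,
#' `network_<layer>.graphml`, `network_properties.tsv`, `metrics.tsv`,
#' `thresholds.tsv` and `provenance.json`.  A rerun with an identical
#' configuration and seed writes byte-identical products.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory products.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  n_warn <- 0L
  count_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    n_warn <<- n_warn + 1L
    say("  warning: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  # pre-flight validation before any computation
  if (!is.null(config$community)) {
    for (f in c(config$community, config$env))
      if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
    if (config$run_assembly && is.null(config$tree))
      stop("pre-flight: assembly stage enabled but no tree supplied")
    if (!is.null(config$tree) && !file.exists(config$tree))
      stop("input file not found: ", config$tree)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  say("stage: inputs")
  truth <- NULL
  if (is.null(config$community)) {
    simc <- config$sim
    simc$seed <- derive_seed(config$seed, "sim")
    sim <- simulate_metacommunity(simc)
    tab <- sim$table; env <- sim$env; tree <- sim$tree; truth <- sim$truth
    write_results(tab, p("community.tsv"))
    env_out <- data.frame(sample = rownames(env), env, check.names = FALSE)
    write_results(env_out, p("env.tsv"))
    ape::write.tree(tree, p("tree.nwk"))
    tr_out <- truth
    tr_out$optima <- as.list(tr_out$optima)
    write_results(tr_out, p("truth.json"))
  } else {
    tab <- read_community_table(config$community)
    env <- if (!is.null(config$env)) read_env_table(config$env) else NULL
    tree <- if (!is.null(config$tree)) read_tree(config$tree) else NULL
    if (!is.null(env)) {
      al <- count_warn(align_samples(tab, env))
      if ("layer" %in% colnames(env))
        layers(tab) <- setNames(env[colnames(tab), "layer"], colnames(tab))
    }
  }
  groups <- attr(tab, "layer") %||% rep("all", ncol(tab))

  say("stage: diversity")
  alpha <- alpha_diversity(tab)
  write_results(alpha, p("alpha.tsv"))
  bc <- bray_curtis(tab)
  write_results(bc, p("bray_curtis.tsv"))
  gt <- count_warn(group_dissimilarity(bc, setNames(groups, colnames(tab))))
  write_results(list(kruskal_p = unname(gt$kruskal$p.value %||% NA),
                     summary = gt$summary), p("group_tests.json"))

  assembly <- NULL
  if (config$run_assembly) {
    say("stage: assembly (null_reps = ", config$null_reps, ")")
    assembly <- count_warn(assembly_analysis(
      tab, tree, groups = groups, null_reps = config$null_reps,
      seed = derive_seed(config$seed, "assembly")))
    write_results(assembly, p("pairwise.tsv"))
    frl <- split(setNames(assembly$fractions$fraction, assembly$fractions$process),
                 assembly$fractions$group)
    write_results(lapply(frl, as.list), p("fractions.json"))
  }

  say("stage: networks")
  layer_tabs <- if (length(unique(groups)) > 1) split_layers(tab)
                else setNames(list(tab), unique(groups))
  cmp <- count_warn(compare_layers(layer_tabs,
                                   seed = derive_seed(config$seed, "net"),
                                   min_prevalence = config$min_prevalence,
                                   rho_threshold = config$rho_threshold,
                                   alpha = config$alpha,
                                   correction = config$correction))
  for (g in names(cmp$networks))
    write_results(cmp$networks[[g]], p(paste0("network_", g, ".graphml")))
  if (!is.null(cmp$properties))
    write_results(cmp$properties, p("network_properties.tsv"))

  say("stage: per-sample metrics")
  metrics <- NULL
  for (g in names(cmp$networks)) {
    mt <- count_warn(per_sample_metrics(
      layer_tabs[[g]], cmp$networks[[g]],
      removal_fraction = config$removal_fraction,
      n_reps = config$removal_reps, null_reps = config$conn_null_reps,
      seed = derive_seed(config$seed, "metrics", g)))
    metrics <- rbind(metrics, cbind(layer = g, mt))
  }
  if (!is.null(metrics)) write_results(metrics, p("metrics.tsv"))

  say("stage: thresholds")
  resp <- data.frame(row.names = alpha$sample, simpson = alpha$simpson)
  if (!is.null(metrics)) {
    resp[metrics$sample, "stability"] <- metrics$stability
    resp[metrics$sample, "complexity"] <- metrics$complexity
  }
  thr <- NULL
  if (!is.null(env)) {
    dat <- cbind(resp[rownames(env), , drop = FALSE], env)
    dat$layer <- groups[match(rownames(env), colnames(tab))]
    targets <- config$targets
    if (is.null(targets)) {
      targets <- data.frame(response = c("simpson", "stability", "complexity"),
                            driver = c("pH", "DO", "NO3"),
                            stringsAsFactors = FALSE)
      if (!is.null(truth))
        for (bp in truth$breakpoints)
          targets <- rbind(targets, data.frame(response = bp$response,
                                               driver = bp$driver))
      targets <- targets[targets$response %in% colnames(dat) &
                         targets$driver %in% colnames(dat), , drop = FALSE]
    }
    thr <- threshold_report(dat, targets, layer_col = "layer",
                            min_seg = config$min_seg)
    write_results(thr, p("thresholds.tsv"))
  }

  prov <- list(package = "microstab",
               version = as.character(utils::packageVersion("microstab")),
               seed = config$seed,
               n_warnings = n_warn,
               config = serialize_config(config))
  write_results(prov, p("provenance.json"))
  say("done: ", out_dir, " (", n_warn, " warnings)")
  invisible(list(table = tab, env = env, tree = tree, truth = truth,
                 alpha = alpha, bray_curtis = bc, group_tests = gt,
                 assembly = assembly, networks = cmp, metrics = metrics,
                 thresholds = thr, provenance = prov))
}

serialize_config <- function(config) {
  out <- unclass(config)
  if (inherits(out$sim, "simulation_config")) {
    s <- unclass(out$sim)
    s$sites <- as.list(s$sites)
    out$sim <- s
  }
  out
}
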