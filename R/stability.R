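# Community complexity (cohesion) and stability (robustness) metrics.
# Cohesion follows the null-corrected connectedness construction: observed
# pairwise correlations minus their mean under per-taxon abundance shuffles,
# averaged over positive / negative partners, then abundance-weighted per
# sample.  Robustness is the taxon fraction persisting (not isolated) after
# random node removal from the co-occurrence network.

#' Null-corrected per-taxon connectedness
#'
#' Pearson correlations between taxa on relative abundances, corrected by
#' subtracting the mean correlation across `null_reps` null datasets in
#' which each taxon's abundances are shuffled independently across samples
#' (samples re-normalised after shuffling, so the null carries the same
#' compositional closure as the data).  A taxon's positive connectedness is
#' the mean of its positive corrected correlations with other taxa;
#' negative connectedness the mean of the negative ones.
#'
#' @param table a [community_table()] with at least 5 samples.
#' @param null_reps number of shuffle null datasets (>= 1).
#' @param seed integer seed.
#' @param method correlation inside the construction; Pearson per the
#'   original cohesion definition, Spearman available.
#' @return data.frame with columns `taxon`, `pos_connectedness` (>= 0),
#'   `neg_connectedness` (<= 0), and `mean_corrected` (signed mean of all
#'   corrected correlations with other taxa; centred at zero for
#'   independent taxa).
#' @export
connectedness <- function(table, null_reps = 100, seed = 1,
                          method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (null_reps < 1) stop("null_reps must be at least 1")
  if (ncol(table) < 5) stop("need at least 5 samples")
  m <- unclass(table)
  attr(m, "layer") <- NULL
  rel <- t(relative_abundance(table))  # samples x taxa
  cst <- apply(rel, 2, function(v) var(v) == 0)
  if (any(cst))
    warning("constant taxa assigned zero connectedness: ",
            paste(colnames(rel)[cst], collapse = ", "))
  obs <- suppressWarnings(cor(rel, method = method))
  obs[is.na(obs)] <- 0
  nsum <- matrix(0, ncol(rel), ncol(rel))
  with_seed(derive_seed(seed, "connectedness"), {
    for (r in seq_len(null_reps)) {
      ms <- t(apply(m, 1, sample))        # shuffle counts within each taxon
      shuf <- t(sweep(ms, 2, colSums(ms), "/"))  # re-close the null samples
      cn <- suppressWarnings(cor(shuf, method = method))
      cn[is.na(cn)] <- 0
      nsum <- nsum + cn
    }
  })
  corr <- obs - nsum / null_reps
  diag(corr) <- NA
  pos <- apply(corr, 1, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else 0
  })
  neg <- apply(corr, 1, function(v) {
    v <- v[!is.na(v) & v < 0]
    if (length(v)) mean(v) else 0
  })
  avg <- apply(corr, 1, function(v) mean(v[!is.na(v)]))
  pos[cst] <- 0
  neg[cst] <- 0
  avg[cst] <- 0
  data.frame(taxon = colnames(rel), pos_connectedness = pos,
             neg_connectedness = neg, mean_corrected = avg,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample cohesion
#'
#' `cohesion_pos(sample) = sum_i relabund_i(sample) * pos_connectedness_i`,
#' and analogously for the negative side — the abundance-weighted average
#' connectedness of the community in each sample.
#'
#' @param table a [community_table()].
#' @param conn data.frame from [connectedness()] on the same taxa.
#' @return data.frame with columns `sample`, `cohesion_pos` (>= 0),
#'   `cohesion_neg` (<= 0).
#' @export
cohesion <- function(table, conn) {
  rel <- relative_abundance(table)
  miss <- setdiff(rownames(rel), conn$taxon)
  if (length(miss))
    stop("connectedness missing for taxa: ", paste(miss, collapse = ", "))
  pos <- conn$pos_connectedness[match(rownames(rel), conn$taxon)]
  neg <- conn$neg_connectedness[match(rownames(rel), conn$taxon)]
  data.frame(sample = colnames(rel),
             cohesion_pos = as.numeric(crossprod(rel, pos)),
             cohesion_neg = as.numeric(crossprod(rel, neg)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Network robustness to random node removal
#'
#' Mean, over `n_reps` draws, of the fraction of taxa remaining in the graph
#' after removing `floor(removal_fraction * n)` random nodes and then
#' deleting any node left with degree zero (secondary extinction by
#' isolation).  With `sample_subset`, robustness is computed on the induced
#' subgraph of those taxa — the per-sample stability used downstream.
#'
#' @param net a `cooccurrence_network` or igraph graph.
#' @param removal_fraction fraction of nodes removed per draw, in \[0, 1\].
#' @param n_reps number of random removal draws.
#' @param seed integer seed.
#' @param sample_subset optional character vector of taxa; the induced
#'   subgraph is used.
#' @param targeted remove highest-degree nodes first instead of at random
#'   (deterministic order up to ties broken by the seed).
#' @return robustness in \[0, 1\], or `NA` when the induced subgraph is
#'   empty (flagged via a warning).
#' @export
robustness <- function(net, removal_fraction = 0.5, n_reps = 100, seed = 1,
                       sample_subset = NULL, targeted = FALSE) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  if (removal_fraction < 0 || removal_fraction > 1)
    stop("removal_fraction must lie in [0, 1]")
  if (!is.null(sample_subset)) {
    keep <- intersect(igraph::V(g)$name, sample_subset)
    if (!length(keep)) {
      warning("induced subgraph empty; robustness undefined")
      return(NA_real_)
    }
    g <- igraph::induced_subgraph(g, keep)
  }
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  n_remove <- floor(removal_fraction * n)
  deg <- rowSums(A)
  with_seed(derive_seed(seed, "robustness", n, n_remove), {
    surv <- vapply(seq_len(n_reps), function(r) {
      removed <- if (n_remove == 0) integer(0)
        else if (targeted) order(deg, runif(n), decreasing = TRUE)[seq_len(n_remove)]
        else sample.int(n, n_remove)
      keep <- setdiff(seq_len(n), removed)
      if (!length(keep)) return(0)
      sub <- A[keep, keep, drop = FALSE]
      sum(rowSums(sub) > 0) / n
    }, 0)
    mean(surv)
  })
}

#' Per-sample complexity and stability metrics
#'
#' For every sample: complexity = the cohesion statistic (positive cohesion
#' by default; negative or total absolute cohesion by option), and
#' stability = robustness of the layer network's induced subgraph on the
#' taxa detected in that sample.
#'
#' @param table a [community_table()] (one layer).
#' @param net the `cooccurrence_network` built from the same table.
#' @param removal_fraction,n_reps,null_reps,seed see [robustness()] and
#'   [connectedness()].
#' @param complexity `"cohesion_pos"` (default), `"cohesion_neg_abs"` or
#'   `"cohesion_total_abs"`.
#' @return data.frame with one row per sample: `sample`, `cohesion_pos`,
#'   `cohesion_neg`, `complexity`, `stability`, `flag`.
#' @export
per_sample_metrics <- function(table, net, removal_fraction = 0.5,
                               n_reps = 100, null_reps = 100, seed = 1,
                               complexity = c("cohesion_pos",
                                              "cohesion_neg_abs",
                                              "cohesion_total_abs")) {
  complexity <- match.arg(complexity)
  conn <- connectedness(table, null_reps = null_reps, seed = seed)
  coh <- cohesion(table, conn)
  coh$complexity <- switch(complexity,
    cohesion_pos = coh$cohesion_pos,
    cohesion_neg_abs = abs(coh$cohesion_neg),
    cohesion_total_abs = coh$cohesion_pos + abs(coh$cohesion_neg))
  m <- unclass(table)
  coh$stability <- NA_real_
  coh$flag <- ""
  for (k in seq_len(nrow(coh))) {
    present <- rownames(m)[m[, coh$sample[k]] > 0]
    st <- withCallingHandlers(
      robustness(net, removal_fraction = removal_fraction, n_reps = n_reps,
                 seed = derive_seed(seed, "stab", coh$sample[k]),
                 sample_subset = present),
      warning = function(w) invokeRestart("muffleWarning"))
    coh$stability[k] <- st
    if (is.na(st)) coh$flag[k] <- "empty_subgraph"
  }
  coh
}
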