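# Null-model partitioning of community assembly: betaMNTD / betaNTI against
# a taxa-shuffle phylogenetic null, abundance-based Raup-Crick with
# Bray-Curtis, and the five-way process classification.

# Patristic distances and relative abundances for the taxa universe of a
# table: every table taxon that is a tree tip (zero-count taxa included, so
# the taxa-shuffle null relabels across the full universe).  Taxa with
# nonzero counts must be tips; errors name the missing ones.
assembly_inputs <- function(table, tree) {
  m <- unclass(table)
  present <- rownames(m)[rowSums(m) > 0]
  miss <- setdiff(present, tree$tip.label)
  if (length(miss))
    stop("taxa missing from tree: ", paste(miss, collapse = ", "))
  universe <- rownames(m)[rownames(m) %in% tree$tip.label]
  D <- patristic(tree, universe)
  P <- relative_abundance(table)[universe, , drop = FALSE]
  list(D = D, P = P)
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For samples A and B, `0.5 * (sum_i f_iA * min_j d(i, j) + sum_j f_jB *
#' min_i d(i, j))` where `f` are relative abundances, `d` patristic
#' distances, and the minima run over taxa present in the other sample
#' (a taxon shared by both samples contributes distance zero).
#'
#' @param table a [community_table()]; taxa with nonzero counts must be tips
#'   of `tree`.
#' @param tree a `phylo` object.
#' @param pair optional length-2 vector of sample ids (or indices); when
#'   given, the single betaMNTD value is returned.
#' @return a symmetric sample-by-sample matrix, or a single number when
#'   `pair` is given.
#' @export
beta_mntd <- function(table, tree, pair = NULL) {
  inp <- assembly_inputs(table, tree)
  M <- cpp_bmntd_all(inp$D, inp$P)
  dimnames(M) <- list(colnames(table), colnames(table))
  if (!is.null(pair)) return(M[pair[1], pair[2]])
  M
}

# reps x n_taxa matrix of 0-based taxa-shuffle permutations
null_perms <- function(n_taxa, reps) {
  t(vapply(seq_len(reps), function(i) sample.int(n_taxa) - 1L,
           integer(n_taxa)))
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a taxa-shuffle null: taxon
#' labels are permuted across the (pruned) tree's tips `null_reps` times and
#' betaMNTD recomputed; `betaNTI = (obs - mean(null)) / sd(null)`.  Pairs
#' whose null distribution is degenerate (zero standard deviation, e.g. on a
#' star tree) are returned as `NA` with `flag = "degenerate_null"`, never as
#' infinities.
#'
#' @inheritParams beta_mntd
#' @param null_reps number of taxa-shuffle permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return data.frame with one row per unordered sample pair: `sample_i`,
#'   `sample_j`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`, `flag`.
#' @export
bnti <- function(table, tree, null_reps = 999, seed = 1) {
  if (null_reps < 99) stop("null_reps must be at least 99")
  if (ncol(table) < 2) stop("need at least two samples")
  inp <- assembly_inputs(table, tree)
  obs <- cpp_bmntd_all(inp$D, inp$P)
  perms <- with_seed(derive_seed(seed, "bnti"),
                     null_perms(nrow(inp$D), null_reps))
  nulls <- cpp_bmntd_null(inp$D, inp$P, perms)  # reps x npairs
  S <- ncol(table)
  ut <- which(upper.tri(obs), arr.ind = TRUE)
  ids <- colnames(table)
  nm <- colMeans(nulls)
  nsd <- apply(nulls, 2, sd)
  obs_v <- obs[upper.tri(obs)]
  z <- ifelse(nsd > 1e-12, (obs_v - nm) / nsd, NA_real_)
  data.frame(sample_i = ids[ut[, 1]], sample_j = ids[ut[, 2]],
             bmntd_obs = obs_v, null_mean = nm, null_sd = nsd,
             bnti = z,
             flag = ifelse(nsd > 1e-12, "", "degenerate_null"),
             stringsAsFactors = FALSE)
}

#' Abundance-based Raup-Crick with Bray-Curtis (RCbray)
#'
#' For each sample pair, null communities are assembled from the regional
#' pool (all samples of `table`): each null sample draws its observed
#' richness with probability proportional to taxon occurrence frequency,
#' then fills to its observed total abundance with probability proportional
#' to regional relative abundance.  With `BC_obs` the observed Bray-Curtis,
#' `RC = 2 * ((n_less + 0.5 * n_ties) / null_reps - 0.5)`, in \[-1, 1\].
#'
#' Per-pair random streams are derived from `seed` by stable integer mixing,
#' so results do not depend on pair order.
#'
#' @inheritParams bnti
#' @param pairs optional two-column matrix/data.frame of sample ids
#'   restricting the computation to those pairs (the regional pool stays the
#'   full table).
#' @return data.frame with one row per unordered sample pair: `sample_i`,
#'   `sample_j`, `bc_obs`, `rc_bray`, `flag`.
#' @export
rc_bray <- function(table, null_reps = 999, seed = 1, pairs = NULL) {
  if (null_reps < 99) stop("null_reps must be at least 99")
  if (ncol(table) < 2) stop("need at least two samples")
  m <- unclass(table)
  attr(m, "layer") <- NULL
  occ <- rowSums(m > 0)
  ab <- rowSums(m)
  pool_n <- sum(occ > 0)
  bc <- as.matrix(bray_curtis(table))
  rich <- colSums(m > 0)
  tot <- round(colSums(m))
  ids <- colnames(m)
  if (is.null(pairs)) {
    ut <- which(upper.tri(bc), arr.ind = TRUE)
  } else {
    pairs <- as.matrix(pairs)
    ut <- cbind(match(pairs[, 1], ids), match(pairs[, 2], ids))
    if (anyNA(ut)) stop("unknown samples in pairs")
  }
  res <- data.frame(sample_i = ids[ut[, 1]], sample_j = ids[ut[, 2]],
                    bc_obs = bc[ut], rc_bray = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  if (pool_n < 2) {
    res$flag <- "degenerate_pool"
    return(res)
  }
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    bcn <- with_seed(derive_seed(seed, "rc", ids[i], ids[j]),
                     cpp_rc_null_bc(occ, ab, rich[i], tot[i],
                                    rich[j], tot[j], null_reps))
    obs <- res$bc_obs[k]
    less <- sum(bcn < obs - 1e-12)
    ties <- sum(abs(bcn - obs) <= 1e-12)
    res$rc_bray[k] <- 2 * ((less + 0.5 * ties) / null_reps - 0.5)
  }
  res
}

#' Five-way assembly process classification
#'
#' `betaNTI > 2`: heterogeneous selection; `betaNTI < -2`: homogeneous
#' selection.  With `|betaNTI| <= 2` (selection not detected; the boundary
#' value 2 falls on the stochastic side): `RC > 0.95` dispersal limitation,
#' `RC < -0.95` homogenizing dispersal, otherwise drift.
#'
#' @param bnti numeric vector of betaNTI values (NA = degenerate null).
#' @param rc numeric vector of RCbray values, same length.
#' @return factor with levels `heterogeneous_selection`,
#'   `homogeneous_selection`, `dispersal_limitation`,
#'   `homogenizing_dispersal`, `drift`; NA where betaNTI is NA.
#' @export
classify_processes <- function(bnti, rc) {
  stopifnot(length(bnti) == length(rc))
  lev <- c("heterogeneous_selection", "homogeneous_selection",
           "dispersal_limitation", "homogenizing_dispersal", "drift")
  out <- rep(NA_character_, length(bnti))
  out[!is.na(bnti) & bnti > 2] <- "heterogeneous_selection"
  out[!is.na(bnti) & bnti < -2] <- "homogeneous_selection"
  sto <- !is.na(bnti) & abs(bnti) <= 2
  out[sto & !is.na(rc) & rc > 0.95] <- "dispersal_limitation"
  out[sto & !is.na(rc) & rc < -0.95] <- "homogenizing_dispersal"
  out[sto & !is.na(rc) & abs(rc) <= 0.95] <- "drift"
  factor(out, levels = lev)
}

#' Full assembly partitioning by group
#'
#' Runs [bnti()] and [rc_bray()] within each group (the regional pool for a
#' pair is the union of samples in its group, typically a depth layer),
#' classifies every pair, and reports per-group process fractions.
#'
#' @inheritParams bnti
#' @param groups per-sample group labels; defaults to the table's layers,
#'   or a single group when absent.
#' @return object of class `assembly_result`: list with `pairs` (per-pair
#'   data.frame incl. `group`, `bnti`, `rc_bray`, `process`), `fractions`
#'   (group x process proportions over classified pairs), `excluded`
#'   (flagged pair count per group), `params`.
#' @export
assembly_analysis <- function(table, tree, groups = NULL,
                              null_reps = 999, seed = 1) {
  groups <- groups %||% attr(table, "layer") %||% rep("all", ncol(table))
  if (!is.null(names(groups))) groups <- groups[colnames(table)]
  idx_by_group <- split(seq_len(ncol(table)), groups)
  pairs <- NULL
  for (g in names(idx_by_group)) {
    idx <- idx_by_group[[g]]
    if (length(idx) < 2) {
      warning("group '", g, "' has fewer than 2 samples; skipped")
      next
    }
    sub <- subset_samples(table, idx, drop_empty_taxa = TRUE)
    b <- bnti(sub, tree, null_reps = null_reps, seed = derive_seed(seed, g, 1))
    r <- rc_bray(sub, null_reps = null_reps, seed = derive_seed(seed, g, 2))
    stopifnot(identical(b$sample_i, r$sample_i),
              identical(b$sample_j, r$sample_j))
    df <- data.frame(group = g, b[, c("sample_i", "sample_j", "bmntd_obs", "bnti")],
                     bc_obs = r$bc_obs, rc_bray = r$rc_bray,
                     flag = ifelse(nzchar(b$flag), b$flag, r$flag),
                     stringsAsFactors = FALSE)
    pairs <- rbind(pairs, df)
  }
  if (is.null(pairs)) stop("no group with at least 2 samples")
  pairs$process <- classify_processes(pairs$bnti, pairs$rc_bray)
  lev <- levels(pairs$process)
  fr <- do.call(rbind, lapply(split(pairs, pairs$group), function(d) {
    ok <- !is.na(d$process)
    tb <- table(factor(d$process[ok], levels = lev))
    data.frame(group = d$group[1], process = lev,
               fraction = as.numeric(tb) / max(1, sum(ok)),
               n_pairs = sum(ok), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  rownames(fr) <- NULL
  excluded <- vapply(split(pairs, pairs$group),
                     function(d) sum(is.na(d$process)), 0L)
  structure(list(pairs = pairs, fractions = fr, excluded = excluded,
                 params = list(null_reps = null_reps, seed = seed)),
            class = "assembly_result")
}

#' Fraction of pairs with |betaNTI| > 2 per group
#' @param x an `assembly_result`.
#' @return named numeric vector of deterministic fractions.
#' @export
deterministic_fraction <- function(x) {
  stopifnot(inherits(x, "assembly_result"))
  vapply(split(x$pairs, x$pairs$group), function(d) {
    ok <- !is.na(d$bnti)
    if (!any(ok)) return(NA_real_)
    mean(abs(d$bnti[ok]) > 2)
  }, 0)
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly_result: %d sample pairs, %d group(s), null_reps = %d\n",
              nrow(x$pairs), length(unique(x$pairs$group)),
              x$params$null_reps))
  df <- deterministic_fraction(x)
  cat("deterministic fraction (|betaNTI| > 2):",
      paste(sprintf("%s = %.3f", names(df), df), collapse = ", "), "\n")
  if (any(x$excluded > 0))
    cat("pairs excluded (degenerate null/pool):",
        paste(sprintf("%s = %d", names(x$excluded), x$excluded), collapse = ", "), "\n")
  invisible(x)
}
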