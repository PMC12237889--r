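#' Alpha-diversity indices per sample
#'
#' Richness (observed taxa), Shannon entropy (natural log), Simpson index
#' and bias-corrected Chao1.  "Simpson" defaults to the Gini-Simpson form
#' `1 - sum(p_i^2)` (bounded in \[0, 1\]); the inverse-Simpson form
#' `1 / sum(p_i^2)` is available via `simpson`.  Chao1 is
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts, so it needs raw (unnormalized) counts.
#'
#' @param table a [community_table()].
#' @param simpson `"gini"` (default) or `"inverse"`.
#' @return data.frame with columns `sample`, `richness`, `shannon`,
#'   `simpson`, `chao1` and, when the table carries them, `layer`.
#' @export
alpha_diversity <- function(table, simpson = c("gini", "inverse")) {
  simpson <- match.arg(simpson)
  m <- t(unclass(table))  # samples x taxa for vegan
  richness <- rowSums(m > 0)
  shannon <- vegan::diversity(m, index = "shannon")
  simp <- vegan::diversity(m, index = if (simpson == "gini") "simpson" else "invsimpson")
  f1 <- rowSums(m == 1)
  f2 <- rowSums(m == 2)
  chao1 <- richness + f1 * (f1 - 1) / (2 * (f2 + 1))
  out <- data.frame(sample = rownames(m), richness = as.integer(richness),
                    shannon = as.numeric(shannon), simpson = as.numeric(simp),
                    chao1 = as.numeric(chao1), stringsAsFactors = FALSE,
                    row.names = NULL)
  lay <- attr(table, "layer")
  if (!is.null(lay)) out$layer <- lay
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on per-sample relative abundances via [vegan::vegdist()], so
#' entries lie in \[0, 1\] regardless of sequencing depth.
#'
#' @param table a [community_table()] with at least two samples.
#' @return symmetric matrix of class `dist_matrix` with zero diagonal and
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  if (ncol(table) < 2) stop("need at least two samples")
  d <- as.matrix(vegan::vegdist(t(relative_abundance(table)), method = "bray"))
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Within-group dissimilarity distributions and group tests
#'
#' Collects within-group pairwise distances per group label, compares groups
#' with a Kruskal-Wallis test plus pairwise Wilcoxon rank-sum tests
#' (Benjamini-Hochberg adjusted), and assigns a compact letter display:
#' groups sharing a letter are not significantly different.
#'
#' Within-group distances are not independent observations (two pairs
#' sharing a sample are positively correlated), so the rank tests' nominal
#' p-values are anti-conservative.  `n_perm > 0` therefore also computes a
#' calibrated permutation p-value for the Kruskal-Wallis statistic by
#' permuting sample labels and recollecting within-group distances —
#' exact by exchangeability.
#'
#' @param dm a symmetric distance matrix with sample dimnames (e.g. from
#'   [bray_curtis()]).
#' @param labels per-sample group labels, named by sample id or in dimname
#'   order.
#' @param alpha significance level for the letter display.
#' @param n_perm label permutations for the calibrated p-value (0 disables).
#' @param seed integer seed for the permutation stream.
#' @return list with `within` (named list of distance vectors), `summary`
#'   (per-group n, median, mean, letters), `kruskal` (htest),
#'   `kruskal_p_perm` (permutation p or NA), `pairwise` (matrix of adjusted
#'   p-values).
#' @export
group_dissimilarity <- function(dm, labels, alpha = 0.05, n_perm = 0,
                                seed = 1) {
  dm <- as.matrix(dm)
  ids <- rownames(dm)
  if (!is.null(names(labels))) labels <- labels[ids]
  labels <- as.character(labels)
  keep <- names(which(table(labels) >= 2))
  dropped <- setdiff(unique(labels), keep)
  if (length(dropped))
    warning("groups with fewer than 2 samples excluded: ",
            paste(dropped, collapse = ", "))
  within <- lapply(keep, function(g) {
    idx <- which(labels == g)
    dm[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  })
  names(within) <- keep
  vals <- unlist(within, use.names = FALSE)
  grp <- factor(rep(names(within), lengths(within)), levels = keep)
  kw <- if (length(keep) >= 2) kruskal.test(vals, grp) else NULL
  kw_perm <- NA_real_
  if (!is.null(kw) && n_perm > 0) {
    kw_stat <- function(lab) {
      w <- lapply(keep, function(g) {
        idx <- which(lab == g)
        dm[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
      })
      v <- unlist(w, use.names = FALSE)
      f <- factor(rep(keep, lengths(w)), levels = keep)
      unname(kruskal.test(v, f)$statistic)
    }
    obs <- unname(kw$statistic)
    ge <- with_seed(derive_seed(seed, "gdperm"), {
      sum(vapply(seq_len(n_perm), function(k)
        kw_stat(sample(labels)) >= obs - 1e-12, TRUE))
    })
    kw_perm <- (1 + ge) / (1 + n_perm)
  }
  pw <- NULL
  letters_out <- setNames(rep("a", length(keep)), keep)
  if (length(keep) >= 2) {
    pwt <- suppressWarnings(pairwise.wilcox.test(vals, grp, p.adjust.method = "BH"))
    pw <- pwt$p.value
    letters_out <- cld_letters(pw, keep, alpha)
  }
  summary <- data.frame(group = keep,
                        n = lengths(within),
                        median = vapply(within, median, 0),
                        mean = vapply(within, mean, 0),
                        letters = letters_out[keep],
                        row.names = NULL, stringsAsFactors = FALSE)
  list(within = within, summary = summary, kruskal = kw,
       kruskal_p_perm = kw_perm, pairwise = pw)
}

# Compact letter display from a pairwise adjusted-p matrix: build the
# "not significantly different" graph over groups and letter its maximal
# cliques, so any two groups sharing a letter are statistically alike.
cld_letters <- function(pmat, groups, alpha) {
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in rownames(pmat)) for (j in colnames(pmat)) {
    p <- pmat[i, j]
    if (!is.na(p) && p < alpha) {
      adj[i, j] <- FALSE
      adj[j, i] <- FALSE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  cl <- igraph::max_cliques(g)
  cl <- cl[order(-vapply(cl, length, 0L))]
  out <- setNames(rep("", k), groups)
  for (ci in seq_along(cl)) {
    members <- groups[as.integer(cl[[ci]])]
    out[members] <- paste0(out[members], letters[ci])
  }
  out
}
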