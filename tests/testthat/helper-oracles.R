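# Fixtures built in code plus independent brute-force oracles used to
# freeze expected values.  Oracles deliberately share no code with the
# implementation paths they check.

make_ct <- function(counts, taxa = NULL, samples = NULL, layer = NULL) {
  taxa <- taxa %||% paste0("t", seq_len(nrow(counts)))
  samples <- samples %||% paste0("s", seq_len(ncol(counts)))
  dimnames(counts) <- list(taxa, samples)
  community_table(counts, layer = layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Bray-Curtis by naive double loop on relative abundances.
bc_oracle <- function(m) {
  rel <- sweep(m, 2, colSums(m), "/")
  S <- ncol(m)
  out <- matrix(0, S, S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    num <- 0; den <- 0
    for (k in seq_len(nrow(m))) {
      num <- num + abs(rel[k, i] - rel[k, j])
      den <- den + rel[k, i] + rel[k, j]
    }
    out[i, j] <- if (den > 0) num / den else 0
  }
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

# Patristic distances by recursive traversal of the phylo edge list,
# independent of ape::cophenetic.phylo.
patristic_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(start) {
    d <- rep(NA_real_, nn)
    d[start] <- 0
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(d[u])) {
          d[u] <- d[v] + adj[[v]][r, 2]
          queue <- c(queue, u)
        }
      }
    }
    d[seq_len(ntip)]
  }
  out <- t(vapply(seq_len(ntip), dist_from, numeric(ntip)))
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# Abundance-weighted betaMNTD by direct exhaustive minimisation over taxa
# pairs, given a distance matrix D (rownames = taxa) and two named relative
# abundance vectors.
bmntd_oracle <- function(D, fa, fb) {
  ia <- names(fa)[fa > 0]; ib <- names(fb)[fb > 0]
  term_a <- sum(vapply(ia, function(i) fa[i] * min(D[i, ib]), 0))
  term_b <- sum(vapply(ib, function(j) fb[j] * min(D[ia, j]), 0))
  0.5 * (term_a + term_b)
}

# All permutations of 1..n (n small), independent of the package helper.
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Exhaustive taxa-shuffle betaMNTD null for one sample pair: every
# permutation of taxon -> tip assignment, evaluated with bmntd_oracle by
# permuting the rows/cols of the distance matrix.
bnti_null_exhaustive <- function(D, fa, fb) {
  n <- nrow(D)
  P <- perms_oracle(n)
  vapply(seq_len(nrow(P)), function(k) {
    Dp <- D[P[k, ], P[k, ]]
    dimnames(Dp) <- dimnames(D)
    bmntd_oracle(Dp, fa, fb)
  }, 0)
}
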