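#' Construct a validated community table
#'
#' The central observational object of the package: a taxa-by-samples matrix
#' of non-negative integer counts with unique taxon and sample identifiers,
#' optionally carrying a per-sample layer label (e.g. surface/middle/bottom
#' water, `"SL"`/`"ML"`/`"BL"`).
#'
#' @param counts numeric matrix, taxa in rows and samples in columns, with
#'   rownames (taxon ids) and colnames (sample ids).
#' @param layer optional character vector of per-sample group labels, either
#'   named by sample id or in column order.
#' @return An object of class `community_table`: the validated count matrix
#'   with a `layer` attribute.
#' @examples
#' m <- matrix(c(5, 3, 0, 0, 2, 1), nrow = 3,
#'             dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' ct <- community_table(m)
#' sample_sums(ct)
#' @export
community_table <- function(counts, layer = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry taxon rownames and sample colnames")
  dup_t <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_t))
    stop("duplicate taxon identifiers: ", paste(dup_t, collapse = ", "))
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative, missing or non-integer counts at (taxon, sample): ",
         paste(sprintf("(%s, %s)", rownames(counts)[bad[, 1]],
                       colnames(counts)[bad[, 2]]), collapse = ", "))
  empty <- colnames(counts)[colSums(counts) == 0]
  if (length(empty))
    stop("samples with zero total count: ", paste(empty, collapse = ", "))
  storage.mode(counts) <- "double"
  if (!is.null(layer)) {
    if (!is.null(names(layer))) {
      miss <- setdiff(colnames(counts), names(layer))
      if (length(miss))
        stop("layer labels missing for samples: ", paste(miss, collapse = ", "))
      layer <- unname(layer[colnames(counts)])
    } else if (length(layer) != ncol(counts)) {
      stop("layer must have one label per sample")
    }
    layer <- as.character(layer)
  }
  structure(counts, layer = layer, class = c("community_table", "matrix"))
}

#' Read a taxa-by-samples count table from TSV
#'
#' Expects a tab-separated file with a header row whose first column holds
#' identifiers.  `orientation = "taxa"` (the default, QIIME-style feature
#' table) takes rows as taxa; `"samples"` transposes after reading.
#'
#' @param path path to a TSV file.
#' @param orientation `"taxa"` if rows are taxa, `"samples"` if rows are
#'   samples.
#' @return A [community_table()].
#' @export
read_community_table <- function(path, orientation = c("taxa", "samples")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("table must have an identifier column plus data columns")
  ids <- as.character(df[[1]])
  num <- df[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        i <- which(is.na(vn))[1]
        stop(sprintf("non-numeric count at row '%s', column '%s'",
                     ids[i], colnames(num)[j]))
      }
      num[[j]] <- vn
    }
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  community_table(m)
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa x %d samples\n", nrow(x), ncol(x)))
  lay <- attr(x, "layer")
  if (!is.null(lay)) {
    tb <- table(lay)
    cat("layers:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  cat(sprintf("total count %.0f; median sample depth %.0f\n",
              sum(x), median(colSums(x))))
  invisible(x)
}

#' Per-sample relative abundances
#'
#' @param x a [community_table()] or plain count matrix (taxa x samples).
#' @return matrix of the same shape whose columns each sum to 1.
#' @export
relative_abundance <- function(x) {
  m <- unclass(x)
  attr(m, "layer") <- NULL
  sweep(m, 2, colSums(m), "/")
}

#' Per-sample total counts
#' @param x a [community_table()].
#' @export
sample_sums <- function(x) colSums(unclass(x))

#' Layer labels of a community table
#' @param x a [community_table()].
#' @export
layers <- function(x) attr(x, "layer")

#' Assign layer labels
#' @param x a [community_table()].
#' @param value character labels, named by sample or in column order.
#' @export
`layers<-` <- function(x, value) {
  community_table(unclass(x), layer = value)
}

#' Subset a community table to selected samples
#'
#' Taxa absent from every retained sample are kept (zero rows carry
#' information for occurrence-based nulls when the caller wants them) unless
#' `drop_empty_taxa` is set.
#'
#' @param x a [community_table()].
#' @param samples character vector of sample ids or logical/integer index.
#' @param drop_empty_taxa drop taxa with zero total count in the subset.
#' @export
subset_samples <- function(x, samples, drop_empty_taxa = FALSE) {
  m <- unclass(x)
  lay <- attr(x, "layer")
  if (is.character(samples)) {
    miss <- setdiff(samples, colnames(m))
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    idx <- match(samples, colnames(m))
  } else idx <- which(rep_len(TRUE, ncol(m)))[samples]
  m2 <- m[, idx, drop = FALSE]
  if (drop_empty_taxa) m2 <- m2[rowSums(m2) > 0, , drop = FALSE]
  community_table(m2, layer = if (!is.null(lay)) lay[idx])
}

#' Split a community table by layer label
#' @param x a [community_table()] with layer labels.
#' @return named list of `community_table`s, one per layer.
#' @export
split_layers <- function(x) {
  lay <- attr(x, "layer")
  if (is.null(lay)) stop("community table carries no layer labels")
  out <- lapply(split(seq_len(ncol(x)), lay), function(i)
    subset_samples(x, i, drop_empty_taxa = TRUE))
  out
}

#' Read a sample-by-variable environmental table from TSV
#'
#' First column holds sample ids; remaining columns are numeric environmental
#' variables, except an optional `layer` column of group labels.  Missing
#' values are permitted.  If columns `NO2`, `NO3` and `NH4` are all present
#' and `DIN` is absent, DIN is derived as their sum; if `DIN` is present it
#' is checked against that sum where all three components are non-missing.
#'
#' @param path path to a TSV file.
#' @return data.frame with rownames = sample ids, numeric columns, and an
#'   optional character `layer` column.
#' @export
read_env_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate sample identifiers: ", paste(dup, collapse = ", "))
  df <- df[, -1, drop = FALSE]
  rownames(df) <- ids
  validate_env_table(df)
}

validate_env_table <- function(df) {
  num_cols <- setdiff(colnames(df), "layer")
  for (j in num_cols) {
    if (!is.numeric(df[[j]])) {
      suppressWarnings(v <- as.numeric(df[[j]]))
      df[[j]] <- v
    }
  }
  if (all(c("NO2", "NO3", "NH4") %in% colnames(df))) {
    din <- df$NO2 + df$NO3 + df$NH4
    if (!"DIN" %in% colnames(df)) {
      df$DIN <- din
    } else {
      ok <- !is.na(din) & !is.na(df$DIN)
      if (any(abs(df$DIN[ok] - din[ok]) > 1e-9))
        stop("DIN column inconsistent with NO2 + NO3 + NH4 for samples: ",
             paste(rownames(df)[ok][abs(df$DIN[ok] - din[ok]) > 1e-9], collapse = ", "))
    }
  }
  df
}

#' Align a community table with an environmental table
#'
#' Explicit join on sample identifiers.  Unmatched samples on either side are
#' reported via warning, never silently dropped: community samples without
#' environmental data are retained in the returned table (usable for
#' diversity and assembly) and listed so gradient analyses can exclude them.
#'
#' @param table a [community_table()].
#' @param env data.frame from [read_env_table()].
#' @return list with `table` (unchanged), `env` (reordered to the shared
#'   samples), `shared`, `community_only`, `env_only` sample id vectors.
#' @export
align_samples <- function(table, env) {
  cs <- colnames(table)
  es <- rownames(env)
  shared <- intersect(cs, es)
  conly <- setdiff(cs, es)
  eonly <- setdiff(es, cs)
  if (length(conly))
    warning("community samples without environmental data (kept for diversity/assembly, excluded from gradient analyses): ",
            paste(conly, collapse = ", "))
  if (length(eonly))
    warning("environmental samples without community data: ",
            paste(eonly, collapse = ", "))
  list(table = table, env = env[shared, , drop = FALSE],
       shared = shared, community_only = conly, env_only = eonly)
}
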