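# Driver screening (Spearman, Mantel, linear regression) and the threshold
# report that runs segmented fits per (layer, response, driver) target.

#' Spearman screen of responses against environmental variables
#'
#' Midrank Spearman correlation and t-approximation p-value for every
#' (response, variable) pair, Benjamini-Hochberg adjusted within each
#' response.  Missing values are pairwise-deleted; constant columns are
#' flagged with `NA` correlations.
#'
#' @param responses data.frame of per-sample response columns (rownames =
#'   sample ids, or a `sample` column).
#' @param env data.frame of environmental variables (rownames = sample ids);
#'   a `layer` column is ignored.
#' @param correction `"BH"` or `"none"`.
#' @return data.frame with columns `response`, `variable`, `n`, `rho`, `p`,
#'   `p_adj`, `flag`.
#' @export
spearman_screen <- function(responses, env, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  if ("sample" %in% colnames(responses)) {
    rownames(responses) <- responses$sample
    responses$sample <- NULL
  }
  shared <- intersect(rownames(responses), rownames(env))
  if (length(shared) < 5) stop("fewer than 5 shared samples")
  responses <- responses[shared, , drop = FALSE]
  env <- env[shared, setdiff(colnames(env), "layer"), drop = FALSE]
  out <- NULL
  for (rv in colnames(responses)) {
    rows <- NULL
    for (ev in colnames(env)) {
      x <- responses[[rv]]; e <- env[[ev]]
      ok <- !is.na(x) & !is.na(e)
      n <- sum(ok)
      if (n < 5) {
        rows <- rbind(rows, data.frame(response = rv, variable = ev, n = n,
                                       rho = NA_real_, p = NA_real_,
                                       flag = "too_few", stringsAsFactors = FALSE))
        next
      }
      if (var(x[ok]) == 0 || var(e[ok]) == 0) {
        rows <- rbind(rows, data.frame(response = rv, variable = ev, n = n,
                                       rho = NA_real_, p = NA_real_,
                                       flag = "constant", stringsAsFactors = FALSE))
        next
      }
      rho <- cor(x[ok], e[ok], method = "spearman")
      r2 <- min(rho^2, 1 - 1e-15)
      tstat <- abs(rho) * sqrt((n - 2) / (1 - r2))
      p <- 2 * pt(tstat, n - 2, lower.tail = FALSE)
      rows <- rbind(rows, data.frame(response = rv, variable = ev, n = n,
                                     rho = rho, p = p, flag = "",
                                     stringsAsFactors = FALSE))
    }
    rows$p_adj <- if (correction == "BH") p.adjust(rows$p, "BH") else rows$p
    out <- rbind(out, rows)
  }
  out[, c("response", "variable", "n", "rho", "p", "p_adj", "flag")]
}

#' Mantel test between two distance matrices
#'
#' Correlation of the upper-triangle entries, with the permutation p-value
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)` under simultaneous
#' row/column permutations of the second matrix.  With `exhaustive = TRUE`
#' (sample count <= 8) every one of the `n!` label permutations is
#' enumerated and `p = #\{r_perm >= r_obs\} / n!` (the identity included).
#'
#' @param dm1,dm2 symmetric distance matrices with matching sample dimnames.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of sampled permutations.
#' @param seed integer seed.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list with `r`, `p`, `n_perm`, `method`.
#' @export
mantel_test <- function(dm1, dm2, method = c("spearman", "pearson"),
                        n_perm = 999, seed = 1, exhaustive = FALSE) {
  method <- match.arg(method)
  dm1 <- as.matrix(dm1); dm2 <- as.matrix(dm2)
  if (!is.null(rownames(dm1)) && !is.null(rownames(dm2))) {
    if (!setequal(rownames(dm1), rownames(dm2))) {
      stop("sample sets differ: only in dm1: ",
           paste(setdiff(rownames(dm1), rownames(dm2)), collapse = ", "),
           "; only in dm2: ",
           paste(setdiff(rownames(dm2), rownames(dm1)), collapse = ", "))
    }
    dm2 <- dm2[rownames(dm1), rownames(dm1)]
  }
  n <- nrow(dm1)
  ut <- upper.tri(dm1)
  r_obs <- cor(dm1[ut], dm2[ut], method = method)
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to 8 samples")
    perms <- all_permutations(n)
    rs <- vapply(seq_len(nrow(perms)), function(k) {
      p <- perms[k, ]
      cor(dm1[ut], dm2[p, p][ut], method = method)
    }, 0)
    p_val <- mean(rs >= r_obs - 1e-12)
    return(list(r = r_obs, p = p_val, n_perm = nrow(perms), method = method,
                exhaustive = TRUE))
  }
  ge <- with_seed(derive_seed(seed, "mantel"), {
    sum(vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      cor(dm1[ut], dm2[p, p][ut], method = method) >= r_obs - 1e-12
    }, TRUE))
  })
  list(r = r_obs, p = (1 + ge) / (1 + n_perm), n_perm = n_perm,
       method = method, exhaustive = FALSE)
}

# All n! permutations of 1..n as a matrix (rows); n <= 8.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Euclidean distance matrix of a standardized environmental variable
#'
#' Convenience builder for the second matrix of a Mantel test.
#'
#' @param env data.frame with rownames = sample ids.
#' @param variable column name.
#' @return symmetric matrix of absolute standardized differences.
#' @export
env_distance <- function(env, variable) {
  v <- env[[variable]]
  names(v) <- rownames(env)
  v <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  as.matrix(stats::dist(v))
}

#' Ordinary least-squares line with F-test p-value
#'
#' @param x,y numeric vectors; `x` must be non-constant, `n >= 3`.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0) stop("x is constant")
  if (var(y) == 0)
    return(list(slope = 0, intercept = y[1], r_squared = 0, p = 1,
                n = length(x)))
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate inputs
  p <- if (is.null(sm$fstatistic)) 1
       else unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                      lower.tail = FALSE))
  if (sm$r.squared >= 1 - 1e-12) p <- 0
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p = p, n = length(x))
}

#' Pairwise response against a scalar driver
#'
#' Turns a sample-pair quantity (beta dissimilarity, betaNTI, ...) and a
#' per-sample driver into paired vectors for regression: the driver value of
#' a pair is the mean (default) or absolute difference of the two samples'
#' values.  Pairwise points are not independent; regressions on them should
#' be read with the "naive" p-value caveat.
#'
#' @param pairs data.frame with `sample_i`, `sample_j` and a value column.
#' @param env data.frame with rownames = sample ids.
#' @param driver environmental column name.
#' @param value name of the value column in `pairs`.
#' @param how `"mean"` or `"diff"`.
#' @return data.frame with columns `x` (driver) and `y` (pair value).
#' @export
pairwise_gradient <- function(pairs, env, driver, value, how = c("mean", "diff")) {
  how <- match.arg(how)
  v <- env[[driver]]
  names(v) <- rownames(env)
  xi <- v[pairs$sample_i]; xj <- v[pairs$sample_j]
  x <- if (how == "mean") (xi + xj) / 2 else abs(xi - xj)
  data.frame(x = unname(x), y = pairs[[value]])
}

#' Segmented-regression threshold report over (layer, response, driver) targets
#'
#' Runs [segmented_fit()] for each requested target within each layer and
#' assembles one row per (layer, response, driver) with the breakpoint,
#' slopes, fit quality and significance flag.  Failed fits are carried as
#' flagged rows, never dropped.
#'
#' @param data data.frame holding response and driver columns plus a layer
#'   column.
#' @param targets data.frame with columns `response` and `driver`.
#' @param layer_col name of the layer column (set `NULL` to fit once on all
#'   rows).
#' @param min_seg passed to [segmented_fit()].
#' @return data.frame of class `threshold_report`: `layer`, `response`,
#'   `driver`, `psi`, `slope_left`, `slope_right`, `intercept`,
#'   `r_squared`, `p_value`, `delta_aic`, `n`, `significant`,
#'   `no_change_point`, `flag`.
#' @export
threshold_report <- function(data, targets, layer_col = "layer", min_seg = 3) {
  layers <- if (is.null(layer_col)) "all" else unique(data[[layer_col]])
  out <- NULL
  for (lay in layers) {
    d <- if (is.null(layer_col)) data else data[data[[layer_col]] == lay, , drop = FALSE]
    for (k in seq_len(nrow(targets))) {
      rv <- targets$response[k]; dv <- targets$driver[k]
      row <- data.frame(layer = lay, response = rv, driver = dv,
                        psi = NA_real_, slope_left = NA_real_,
                        slope_right = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        delta_aic = NA_real_, n = NA_integer_,
                        significant = NA, no_change_point = NA,
                        flag = "", stringsAsFactors = FALSE)
      fit <- tryCatch(segmented_fit(d[[dv]], d[[rv]], min_seg = min_seg),
                      error = function(e) conditionMessage(e))
      if (is.character(fit)) {
        row$flag <- fit
      } else {
        row[c("psi", "slope_left", "slope_right", "intercept", "r_squared",
              "p_value", "delta_aic")] <-
          list(fit$psi, fit$slope_left, fit$slope_right, fit$intercept,
               fit$r_squared, fit$p_value, fit$delta_aic)
        row$n <- fit$n
        row$significant <- fit$significant
        row$no_change_point <- fit$no_change_point
        if (fit$no_change_point) row$flag <- "no_change_point"
      }
      out <- rbind(out, row)
    }
  }
  class(out) <- c("threshold_report", "data.frame")
  out
}
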