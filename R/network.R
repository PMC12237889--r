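# Spearman co-occurrence networks over taxa, and the topological summaries
# usually reported for them (degree, density, clustering, modularity).

#' Build a Spearman co-occurrence network
#'
#' All-pairs Spearman rank correlation (midrank ties) on per-sample relative
#' abundances of taxa present in at least `min_prevalence` of samples.
#' P-values use the t approximation; edges are retained when `|rho| >=
#' rho_threshold` and the adjusted p-value is below `alpha`.  Isolated taxa
#' are dropped from the graph but counted.
#'
#' @param table a [community_table()] with at least 5 samples.
#' @param min_prevalence minimum fraction of samples a taxon must occur in.
#' @param rho_threshold minimum absolute Spearman correlation for an edge.
#' @param alpha significance level applied to adjusted p-values.
#' @param correction multiple-testing correction: `"BH"`, `"bonferroni"` or
#'   `"none"`.
#' @return object of class `cooccurrence_network`: list with `graph`
#'   (igraph, edge attributes `rho`, `p`, `p_adj`, `sign`, `weight = |rho|`),
#'   `edges` (data.frame), `n_candidate_taxa`, `n_isolated`, `params`.
#' @export
build_network <- function(table, min_prevalence = 0.2, rho_threshold = 0.6,
                          alpha = 0.05, correction = c("BH", "bonferroni", "none")) {
  correction <- match.arg(correction)
  if (ncol(table) < 5) stop("need at least 5 samples for rank correlations")
  rel <- relative_abundance(table)
  prev <- rowMeans(unclass(table) > 0)
  rel <- rel[prev >= min_prevalence, , drop = FALSE]
  if (nrow(rel) < 2) stop("fewer than 2 taxa pass the prevalence filter")
  cst <- apply(rel, 1, function(v) var(v) == 0)
  if (any(cst)) {
    warning("constant taxa skipped: ", paste(rownames(rel)[cst], collapse = ", "))
    rel <- rel[!cst, , drop = FALSE]
  }
  n <- ncol(rel)
  sc <- spearman_matrix(t(rel), n)
  rho <- sc$rho
  p <- sc$p
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(from = rownames(rel)[ut[, 1]],
                      to = rownames(rel)[ut[, 2]],
                      rho = rho[upper.tri(rho)],
                      p = p[upper.tri(p)], stringsAsFactors = FALSE)
  edges$p_adj <- p.adjust(edges$p, method = if (correction == "BH") "BH"
                          else if (correction == "bonferroni") "bonferroni" else "none")
  keep <- !is.na(edges$rho) & abs(edges$rho) >= rho_threshold & edges$p_adj < alpha
  edges <- edges[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "+", "-")
  edges$weight <- abs(edges$rho)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = rownames(rel))
  iso <- sum(igraph::degree(g) == 0)
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  structure(list(graph = g, edges = edges,
                 n_candidate_taxa = nrow(rel), n_isolated = iso,
                 params = list(min_prevalence = min_prevalence,
                               rho_threshold = rho_threshold,
                               alpha = alpha, correction = correction)),
            class = "cooccurrence_network")
}

# Spearman rho and t-approximation p-values for all column pairs of x
# (observations in rows).  Constant columns give NA.
spearman_matrix <- function(x, n) {
  rho <- suppressWarnings(cor(x, method = "spearman", use = "everything"))
  diag(rho) <- NA
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- abs(rho) * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(tstat, df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  list(rho = rho, p = p)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (|rho| >= %.2f, %s p < %.2g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$params$rho_threshold, x$params$correction, x$params$alpha))
  if (nrow(x$edges))
    cat(sprintf("positive edges: %.1f%%; isolated taxa dropped: %d\n",
                100 * mean(x$edges$sign == "+"), x$n_isolated))
  invisible(x)
}

#' Topological properties of a co-occurrence network
#'
#' Average degree `2E/N`, density `2E/(N(N-1))`, clustering coefficient
#' (mean local clustering over nodes with degree >= 2, the
#' Watts-Strogatz/Gephi convention; `clustering = "global"` gives the
#' triangle-ratio transitivity), module count and modularity from seeded
#' Louvain on `|rho|` weights, and the positive edge fraction.
#'
#' @param net a `cooccurrence_network` or a plain igraph graph.
#' @param seed integer seed for the Louvain pass.
#' @param clustering `"local_average"` (default) or `"global"`.
#' @return one-row data.frame of class `network_properties`.
#' @export
topology <- function(net, seed = 1, clustering = c("local_average", "global")) {
  clustering <- match.arg(clustering)
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) {
    # every candidate node was isolated and dropped: report a zeroed row
    # with modularity flagged undefined rather than failing the layer
    return(structure(data.frame(n_nodes = 0L, n_edges = 0L,
                                average_degree = 0, density = 0,
                                clustering_coefficient = 0,
                                n_modules = 0L, modularity = NA_real_,
                                positive_edge_fraction = NA_real_),
                     class = c("network_properties", "data.frame")))
  }
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) w <- rep(1, e)
  deg <- igraph::degree(g)
  avg_degree <- 2 * e / n
  density <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  cc <- if (e == 0) 0 else if (clustering == "local_average") {
    loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
    loc <- loc[deg >= 2]
    if (length(loc)) mean(loc, na.rm = TRUE) else 0
  } else igraph::transitivity(g, type = "global")
  if (e > 0) {
    comm <- with_seed(seed, igraph::cluster_louvain(g, weights = w))
    n_modules <- length(unique(igraph::membership(comm)))
    modularity <- igraph::modularity(comm)
  } else {
    n_modules <- n
    modularity <- NA_real_  # undefined without edges
  }
  pos_frac <- if (e == 0) NA_real_ else {
    sgn <- igraph::edge_attr(g, "sign")
    if (is.null(sgn)) 1 else mean(sgn == "+")
  }
  structure(data.frame(n_nodes = n, n_edges = e, average_degree = avg_degree,
                       density = density, clustering_coefficient = cc,
                       n_modules = n_modules, modularity = modularity,
                       positive_edge_fraction = pos_frac),
            class = c("network_properties", "data.frame"))
}

#' Per-layer co-occurrence networks and their properties
#'
#' Builds one network per layer with identical parameters and returns a
#' properties table with one row per layer; layers failing the build
#' preconditions are omitted with a warning.
#'
#' @param table a [community_table()] with layer labels (or a named list of
#'   community tables).
#' @param seed integer seed passed to [topology()].
#' @param ... parameters forwarded to [build_network()].
#' @return list with `networks` (named list of `cooccurrence_network`) and
#'   `properties` (data.frame, one row per layer).
#' @export
compare_layers <- function(table, seed = 1, ...) {
  tabs <- if (is.list(table) && !inherits(table, "community_table"))
    table else split_layers(table)
  nets <- list()
  props <- NULL
  for (g in names(tabs)) {
    net <- tryCatch(build_network(tabs[[g]], ...), error = function(e) {
      warning("layer '", g, "' omitted: ", conditionMessage(e))
      NULL
    })
    if (is.null(net)) next
    nets[[g]] <- net
    pr <- cbind(layer = g, topology(net, seed = derive_seed(seed, g)))
    props <- rbind(props, pr)
  }
  if (!is.null(props)) rownames(props) <- NULL
  list(networks = nets, properties = props)
}
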