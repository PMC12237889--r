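#' Read and validate a rooted phylogeny from a newick file
#'
#' Wraps [ape::read.tree()] with the validation the downstream phylogenetic
#' null models require: unique tip labels, branch lengths present on every
#' edge, and no negative lengths.  Trees without branch lengths are rejected
#' because patristic distances would be undefined.
#'
#' @param path path to a newick file (or a newick string via `text`).
#' @param text optional newick string, bypassing `path`.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path = NULL, text = NULL) {
  src <- if (!is.null(text)) text else paste(readLines(path, warn = FALSE), collapse = "")
  offset <- newick_paren_offset(src)
  if (!is.na(offset))
    stop(sprintf("unparseable newick: unbalanced parenthesis at character %d", offset))
  tr <- tryCatch(ape::read.tree(text = src), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("unparseable newick near character 1: not a valid tree string")
  validate_tree(tr)
}

# First character offset at which the parenthesis nesting breaks, NA if balanced.
newick_paren_offset <- function(s) {
  ch <- strsplit(s, "")[[1]]
  depth <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") depth <- depth + 1L
    if (ch[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  if (depth != 0L) return(length(ch))
  NA_integer_
}

validate_tree <- function(tr) {
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup)) stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; tips affected: ",
         paste(head(tr$tip.label, 5), collapse = ", "),
         if (length(tr$tip.label) > 5) ", ...")
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0)) {
    bad_edges <- which(is.na(tr$edge.length) | tr$edge.length < 0)
    tips <- tr$edge[bad_edges, 2]
    tips <- tips[tips <= length(tr$tip.label)]
    stop("missing or negative branch lengths",
         if (length(tips)) paste0(" at tips: ",
                                  paste(tr$tip.label[tips], collapse = ", ")))
  }
  tr
}

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the tip-to-tip path, computed via
#' [ape::cophenetic.phylo()].
#'
#' @param tree a `phylo` object.
#' @param tips optional character vector restricting (and ordering) the tips.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
patristic <- function(tree, tips = NULL) {
  d <- ape::cophenetic.phylo(tree)
  if (!is.null(tips)) {
    miss <- setdiff(tips, rownames(d))
    if (length(miss)) stop("taxa missing from tree: ", paste(miss, collapse = ", "))
    d <- d[tips, tips, drop = FALSE]
  }
  d
}
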