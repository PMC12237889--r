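# Writers with a round-trip guarantee: reading a written file reconstructs
# an equal object.  TSV is the canonical table dialect (tab-separated,
# UTF-8, '.' decimal); networks go to GraphML, fits and summaries to JSON.

supported_outputs <- function() {
  c("assembly_result -> tsv", "cooccurrence_network -> graphml",
    "segmented_fit -> json", "threshold_report -> tsv",
    "dist_matrix -> tsv", "community_table -> tsv", "data.frame -> tsv",
    "list -> json")
}

unsupported <- function(x, format) {
  stop(sprintf("unsupported (product, format) pair: (%s, %s); supported: %s",
               class(x)[1], format, paste(supported_outputs(), collapse = "; ")))
}

#' Write a pipeline product to disk
#'
#' Dispatches on the product's class; the supported (product, format) pairs
#' are assembly results and generic tables to TSV, co-occurrence networks
#' to GraphML, segmented fits and list-like summaries to JSON.  Every
#' writer round-trips: [read_results()] on the written file reconstructs an
#' equal object.
#'
#' @param results a pipeline product.
#' @param path output file path.
#' @param format `"tsv"`, `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format) {
  UseMethod("write_results")
}

write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.assembly_result <- function(results, path, format = "tsv") {
  format <- match.arg(format, c("tsv", "json", "graphml"))
  if (format != "tsv") unsupported(results, format)
  df <- results$pairs
  df$process <- as.character(df$process)
  write_tsv(df, path,
            comments = sprintf("assembly_result null_reps=%d seed=%d",
                               results$params$null_reps, results$params$seed))
  invisible(path)
}

#' @export
write_results.cooccurrence_network <- function(results, path, format = "graphml") {
  format <- match.arg(format, c("tsv", "json", "graphml"))
  if (format != "graphml") unsupported(results, format)
  g <- results$graph
  g <- igraph::set_graph_attr(g, "params",
                              as.character(jsonlite::toJSON(results$params,
                                                            auto_unbox = TRUE)))
  g <- igraph::set_graph_attr(g, "n_candidate_taxa", results$n_candidate_taxa)
  g <- igraph::set_graph_attr(g, "n_isolated", results$n_isolated)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
write_results.segmented_fit <- function(results, path, format = "json") {
  format <- match.arg(format, c("tsv", "json", "graphml"))
  if (format != "json") unsupported(results, format)
  obj <- list(psi = results$psi, intercept = results$intercept,
              slope_left = results$slope_left,
              slope_right = results$slope_right,
              r_squared = results$r_squared, p_value = results$p_value,
              n = results$n, delta_aic = results$delta_aic,
              significant = results$significant,
              no_change_point = results$no_change_point,
              data = results$data)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
write_results.threshold_report <- function(results, path, format = "tsv") {
  format <- match.arg(format, c("tsv", "json", "graphml"))
  if (format != "tsv") unsupported(results, format)
  write_tsv(as.data.frame(results), path, comments = "threshold_report")
}

#' @export
write_results.dist_matrix <- function(results, path, format = "tsv") {
  format <- match.arg(format, c("tsv", "json", "graphml"))
  if (format != "tsv") unsupported(results, format)
  df <- data.frame(sample = rownames(results),
                   as.data.frame(unclass(results), check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path, comments = "dist_matrix")
}

#' @export
write_results.community_table <- function(results, path, format = "tsv") {
  format <- match.arg(format, c("tsv", "json", "graphml"))
  if (format != "tsv") unsupported(results, format)
  df <- data.frame(taxon = rownames(results),
                   as.data.frame(unclass(results), check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @export
write_results.data.frame <- function(results, path, format = "tsv") {
  format <- match.arg(format, c("tsv", "json", "graphml"))
  if (format != "tsv") unsupported(results, format)
  write_tsv(results, path)
}

#' @export
write_results.list <- function(results, path, format = "json") {
  format <- match.arg(format, c("tsv", "json", "graphml"))
  if (format != "json") unsupported(results, format)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a written pipeline product back
#'
#' Inverse of [write_results()] for the declared product types.
#'
#' @param path file path.
#' @param type one of `"assembly_result"`, `"cooccurrence_network"`,
#'   `"segmented_fit"`, `"dist_matrix"`, `"threshold_report"`, `"table"`.
#' @return the reconstructed object.
#' @export
read_results <- function(path, type = c("assembly_result",
                                        "cooccurrence_network",
                                        "segmented_fit", "dist_matrix",
                                        "threshold_report", "table")) {
  type <- match.arg(type)
  switch(type,
    assembly_result = {
      hdr <- readLines(path, n = 1)
      meta <- regmatches(hdr, gregexpr("[a-z_]+=[0-9]+", hdr))[[1]]
      kv <- strsplit(meta, "=")
      params <- setNames(lapply(kv, function(z) as.integer(z[2])),
                         vapply(kv, `[`, "", 1))
      df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
      df$process <- factor(df$process,
                           levels = levels(classify_processes(0, 0)))
      lev <- levels(df$process)
      fr <- do.call(rbind, lapply(split(df, df$group), function(d) {
        ok <- !is.na(d$process)
        tb <- table(factor(d$process[ok], levels = lev))
        data.frame(group = d$group[1], process = lev,
                   fraction = as.numeric(tb) / max(1, sum(ok)),
                   n_pairs = sum(ok), row.names = NULL,
                   stringsAsFactors = FALSE)
      }))
      rownames(fr) <- NULL
      excluded <- vapply(split(df, df$group),
                         function(d) sum(is.na(d$process)), 0L)
      structure(list(pairs = df, fractions = fr, excluded = excluded,
                     params = params), class = "assembly_result")
    },
    cooccurrence_network = {
      g <- igraph::read_graph(path, format = "graphml")
      params <- jsonlite::fromJSON(igraph::graph_attr(g, "params"))
      edges <- igraph::as_data_frame(g, what = "edges")
      net <- list(graph = igraph::delete_graph_attr(
                    igraph::delete_graph_attr(
                      igraph::delete_graph_attr(g, "params"),
                      "n_candidate_taxa"), "n_isolated"),
                  edges = edges,
                  n_candidate_taxa = igraph::graph_attr(g, "n_candidate_taxa"),
                  n_isolated = igraph::graph_attr(g, "n_isolated"),
                  params = params)
      class(net) <- "cooccurrence_network"
      net
    },
    segmented_fit = {
      obj <- jsonlite::fromJSON(path)
      segmented_fit(obj$data$x, obj$data$y)
    },
    dist_matrix = {
      df <- read.delim(path, comment.char = "#", check.names = FALSE,
                       stringsAsFactors = FALSE)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
      structure(m, class = c("dist_matrix", "matrix"))
    },
    threshold_report = {
      df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
      class(df) <- c("threshold_report", "data.frame")
      df
    },
    table = read.delim(path, comment.char = "#", check.names = FALSE,
                       stringsAsFactors = FALSE)
  )
}
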