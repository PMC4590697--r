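#' Read a scored interaction edge list
#'
#' Parses a tab-separated file of pairwise gene interactions with a confidence
#' score in `[0, 1]`, the tabular subset of formats exported by integrative
#' interaction databases (HIPPIE-style scored edge lists, HPRD flat files).
#'
#' A header line is auto-detected: if the first line contains the configured
#' column names the file is read with a header and columns are matched by
#' name; otherwise the first three columns are taken as
#' (`gene_a`, `gene_b`, `score`) in order.
#'
#' @param path path to a tab-separated file.
#' @param col_gene_a,col_gene_b,col_score column names used when a header is
#'   present. Ignored for headerless files.
#' @return a `data.frame` of class `"scored_edges"` with character columns
#'   `gene_a`, `gene_b` and numeric column `score`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_a\tgene_b\tscore", "TP53\tMDM2\t0.9", "TP53\tEP300\t0.68"), tf)
#' read_scored_edges(tf)
#' @export
read_scored_edges <- function(path, col_gene_a = "gene_a", col_gene_b = "gene_b",
                              col_score = "score") {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    any(c(col_gene_a, col_gene_b, col_score) %in% strsplit(first, "\t", fixed = TRUE)[[1L]])
  raw <- utils::read.delim(path, header = has_header, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    return(new_scored_edges(data.frame(gene_a = character(), gene_b = character(),
                                       score = numeric(), stringsAsFactors = FALSE)))
  }
  if (has_header) {
    missing <- setdiff(c(col_gene_a, col_gene_b, col_score), names(raw))
    if (length(missing) > 0L)
      stop("edge list is missing configured column(s): ", paste(missing, collapse = ", "))
    df <- data.frame(gene_a = raw[[col_gene_a]], gene_b = raw[[col_gene_b]],
                     score_chr = raw[[col_score]], stringsAsFactors = FALSE)
  } else {
    if (ncol(raw) < 3L)
      stop("edge list needs at least three columns (gene_a, gene_b, score); found ", ncol(raw))
    df <- data.frame(gene_a = raw[[1L]], gene_b = raw[[2L]],
                     score_chr = raw[[3L]], stringsAsFactors = FALSE)
  }
  score <- suppressWarnings(as.numeric(df$score_chr))
  bad <- which(is.na(score))
  if (length(bad) > 0L) {
    lines <- bad + as.integer(has_header)  # file line numbers
    stop("non-numeric interaction score at line(s) ",
         paste(utils::head(lines, 10L), collapse = ", "),
         " (value(s): ", paste(utils::head(df$score_chr[bad], 10L), collapse = ", "), ")")
  }
  out_of_range <- which(score < 0 | score > 1)
  if (length(out_of_range) > 0L)
    stop("interaction scores must lie in [0, 1]; offending line(s): ",
         paste(utils::head(out_of_range + as.integer(has_header), 10L), collapse = ", "))
  if (any(!nzchar(df$gene_a)) || any(!nzchar(df$gene_b)))
    stop("empty gene identifier in edge list")
  new_scored_edges(data.frame(gene_a = df$gene_a, gene_b = df$gene_b, score = score,
                              stringsAsFactors = FALSE))
}

new_scored_edges <- function(df) {
  stopifnot(is.data.frame(df), all(c("gene_a", "gene_b", "score") %in% names(df)))
  class(df) <- c("scored_edges", "data.frame")
  df
}

#' Construct a scored edge list from vectors
#'
#' In-memory constructor mirroring [read_scored_edges()], with the same
#' validation. Useful for programmatic and simulated inputs.
#'
#' @param gene_a,gene_b character vectors of gene ids.
#' @param score numeric confidence scores in `[0, 1]`.
#' @return a `"scored_edges"` data.frame.
#' @export
scored_edges <- function(gene_a, gene_b, score) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  score <- as.numeric(score)
  if (length(gene_a) != length(gene_b) || length(gene_a) != length(score))
    stop("gene_a, gene_b and score must have equal length")
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("interaction scores must be numeric in [0, 1]")
  if (any(!nzchar(gene_a)) || any(!nzchar(gene_b)))
    stop("empty gene identifier")
  new_scored_edges(data.frame(gene_a = gene_a, gene_b = gene_b, score = score,
                              stringsAsFactors = FALSE))
}

#' Build a thresholded protein-protein interaction network
#'
#' Retains interactions whose confidence score passes `min_score`, removes
#' self-interactions, and collapses duplicate records (including records with
#' the two gene ids in reversed order) into one undirected edge. When the same
#' unordered pair carries several scores, the maximum is kept before
#' thresholding (the strongest evidence for the pair). Only genes that appear
#' in a retained edge become nodes: the network describes its members, and
#' genes that pass no interaction are simply absent.
#'
#' The comparison defaults to `score >= min_score` ("no smaller than" the
#' cutoff), the convention used by medium-confidence PPI thresholding; a
#' strict comparison is available for symmetry with co-expression networks.
#'
#' @param edges a `"scored_edges"` data.frame (see [read_scored_edges()]).
#' @param min_score confidence cutoff in `[0, 1]`. The conventional medium
#'   confidence threshold for HIPPIE-style scores is `0.68` (the median of the
#'   score distribution); `0.77` is the usual stringent reanalysis cutoff.
#' @param comparison `">="` (default) or `">"`.
#' @return an undirected simple [igraph::graph] with an edge attribute
#'   `score` (the retained maximum score per pair).
#' @examples
#' e <- scored_edges(c("a", "b", "a", "c"), c("b", "a", "a", "d"),
#'                   c(0.9, 0.9, 0.99, 0.5))
#' g <- build_ppi_network(e, min_score = 0.68)
#' igraph::ecount(g)  # 1: the a-b edge; self-loop and low-score edge dropped
#' @export
build_ppi_network <- function(edges, min_score = 0.68, comparison = c(">=", ">")) {
  comparison <- match.arg(comparison)
  if (!is.numeric(min_score) || length(min_score) != 1L || min_score < 0 || min_score > 1)
    stop("min_score must be a single value in [0, 1]")
  df <- as.data.frame(edges, stringsAsFactors = FALSE)
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  if (nrow(df) > 0L) {
    lo <- pmin(df$gene_a, df$gene_b)
    hi <- pmax(df$gene_a, df$gene_b)
    key <- paste(lo, hi, sep = "\r")
    score <- tapply(df$score, key, max)
    parts <- strsplit(names(score), "\r", fixed = TRUE)
    df <- data.frame(gene_a = vapply(parts, `[[`, "", 1L),
                     gene_b = vapply(parts, `[[`, "", 2L),
                     score = as.numeric(score), stringsAsFactors = FALSE)
    keep <- if (comparison == ">=") df$score >= min_score else df$score > min_score
    df <- df[keep, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  stopifnot(igraph::is_simple(g))
  g
}

#' Build a co-expression network from an expression matrix
#'
#' Links two genes when the Pearson correlation coefficient (PCC) of their
#' expression profiles across tissues exceeds `min_pcc`. The comparison is
#' strict (`> min_pcc`) by default, the usual convention for co-expression
#' cutoffs such as PCC > 0.4. Genes with zero variance across tissues carry
#' no correlation signal and are excluded before computing correlations.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene ids), tissues in
#'   columns; non-negative FPKM-like values.
#' @param min_pcc correlation cutoff in `[-1, 1]`; default `0.4`.
#' @param comparison `">"` (default) or `">="`.
#' @param log_transform if `TRUE`, apply `log2(x + 1)` before correlating.
#' @return an undirected simple [igraph::graph] over the retained genes that
#'   gained at least one edge.
#' @export
build_coexpression_network <- function(expr, min_pcc = 0.4, comparison = c(">", ">="),
                                       log_transform = FALSE) {
  comparison <- match.arg(comparison)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix must have gene ids as rownames")
  if (ncol(expr) < 3L)
    stop("at least 3 tissues are required for a stable correlation network; found ", ncol(expr))
  if (any(expr < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  if (log_transform) expr <- log2(expr + 1)
  v <- apply(expr, 1L, stats::var)
  constant <- v == 0 | is.na(v)
  if (all(constant)) {
    warning("all genes are constant across tissues; returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (any(constant)) expr <- expr[!constant, , drop = FALSE]
  cc <- stats::cor(t(expr))
  adj <- if (comparison == ">") cc > min_pcc else cc >= min_pcc
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows and tissues in columns, with the first column holding
#' the gene id and a header line of tissue labels.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene id column plus >= 1 tissue column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a network as an edge-list TSV plus a node table
#'
#' @param net an igraph network.
#' @param edge_path,node_path output file paths; `NULL` skips that file.
#' @return invisibly, the edge data.frame.
#' @export
write_network <- function(net, edge_path, node_path = NULL) {
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("gene_a", "gene_b")
  utils::write.table(el, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_path)) {
    nodes <- data.frame(gene_id = igraph::V(net)$name,
                        degree = unname(igraph::degree(net)),
                        stringsAsFactors = FALSE)
    utils::write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(el)
}
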