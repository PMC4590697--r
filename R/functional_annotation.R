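#' Assemble an annotation set by multi-source intersection
#'
#' Genes supported by at least `min_sources` of the supplied evidence sources
#' form the annotation set; each member carries its support count. The
#' canonical use is essential-gene assembly: membership in two or more of
#' four curated essentiality resources.
#'
#' @param sources list of character vectors of gene ids (one per source).
#' @param min_sources minimum number of supporting sources; default 2.
#' @param name label for the set.
#' @return list of class `"annotation_set"`: `name`, `genes` (character),
#'   `source_count` (named integer over members).
#' @export
intersect_sources <- function(sources, min_sources = 2, name = "annotation") {
  if (!is.list(sources) || length(sources) == 0L)
    stop("sources must be a non-empty list of gene id vectors")
  if (min_sources > length(sources))
    stop("min_sources (", min_sources, ") exceeds the number of sources (",
         length(sources), ")")
  counts <- table(unlist(lapply(sources, function(s) unique(as.character(s)))))
  keep <- counts >= min_sources
  structure(list(name = name,
                 genes = names(counts)[keep],
                 source_count = stats::setNames(as.integer(counts[keep]),
                                                names(counts)[keep])),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

annotation_genes <- function(annotation) {
  if (inherits(annotation, "annotation_set")) annotation$genes
  else as.character(annotation)
}

#' Annotated fraction per gene group
#'
#' For each group of genes, the fraction carrying the annotation, always
#' reported with its numerator and denominator. Used for hub fraction by
#' branch, essential fraction by branch, and essential fraction by degree
#' bin. Empty groups are omitted with a warning.
#'
#' @param groups named list of character vectors of gene ids.
#' @param annotation an `"annotation_set"` or character vector of gene ids.
#' @return data.frame with columns `group`, `n`, `n_annotated`, `fraction`.
#' @export
fraction_by_group <- function(groups, annotation) {
  stopifnot(is.list(groups), length(groups) > 0L)
  ann <- annotation_genes(annotation)
  empty <- vapply(groups, length, 1L) == 0L
  if (any(empty)) {
    warning("empty group(s) omitted: ", paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  rows <- lapply(names(groups), function(g) {
    members <- unique(as.character(groups[[g]]))
    k <- sum(members %in% ann)
    data.frame(group = g, n = length(members), n_annotated = k,
               fraction = k / length(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Fisher tests of hub status across gene categories
#'
#' For every pair of category labels, a two-sided Fisher exact test on the
#' 2x2 table of (hub, non-hub) x (category A, category B). The canonical use
#' is comparing hub-gene proportions across brain-expression categories
#' (fetus-biased / adult-biased / unbiased) of young genes.
#'
#' @param cent a `"centrality_table"` with an `is_hub` column.
#' @param categories named character vector, gene id -> category label.
#'   Genes absent from `cent` are ignored; categories left with no genes are
#'   excluded.
#' @return data.frame with columns `category_a`, `category_b`, `hub_a`,
#'   `nonhub_a`, `hub_b`, `nonhub_b`, `odds_ratio`, `p_value`.
#' @export
hub_by_category_test <- function(cent, categories) {
  stopifnot(is.data.frame(cent), "is_hub" %in% names(cent))
  categories <- categories[names(categories) %in% cent$gene_id]
  if (length(categories) == 0L) stop("no categorized gene is in the centrality table")
  hub <- stats::setNames(cent$is_hub, cent$gene_id)[names(categories)]
  labs <- sort(unique(as.character(categories)))
  labs <- labs[vapply(labs, function(l) sum(categories == l) > 0L, TRUE)]
  if (length(labs) < 2L) stop("need at least two non-empty categories")
  combs <- utils::combn(labs, 2L)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    tab <- matrix(c(sum(hub[categories == a]), sum(!hub[categories == a]),
                    sum(hub[categories == b]), sum(!hub[categories == b])),
                  nrow = 2L,
                  dimnames = list(c("hub", "nonhub"), c(a, b)))
    ft <- stats::fisher.test(tab)
    data.frame(category_a = a, category_b = b,
               hub_a = tab[1L, 1L], nonhub_a = tab[2L, 1L],
               hub_b = tab[1L, 2L], nonhub_b = tab[2L, 2L],
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Guilt-by-connection report for a focal gene
#'
#' Enumerates the first-layer (direct) linking partners of a focal gene and
#' the fraction of them carrying a functional annotation — the
#' guilt-by-connection evidence that the focal gene shares that function
#' (genes with similar functions tend to cluster in interaction networks).
#'
#' @param net igraph network containing the focal gene.
#' @param focal gene id.
#' @param annotation an `"annotation_set"` or character vector of gene ids.
#' @return list of class `"gbc_report"`: `focal_gene`, `partners`,
#'   `annotated_partners`, `n_partners`, `n_annotated`, `fraction`.
#' @export
guilt_by_connection <- function(net, focal, annotation) {
  nm <- igraph::V(net)$name
  if (!focal %in% nm) stop("focal gene '", focal, "' absent from network")
  partners <- setdiff(neighbor_sets(net)[[focal]], focal)
  if (length(partners) == 0L) stop("isolated focal gene '", focal, "': no partners")
  ann <- intersect(partners, annotation_genes(annotation))
  structure(list(focal_gene = focal, partners = partners,
                 annotated_partners = ann,
                 n_partners = length(partners), n_annotated = length(ann),
                 fraction = length(ann) / length(partners)),
            class = "gbc_report")
}

#' @export
print.gbc_report <- function(x, ...) {
  cat(sprintf("Guilt by connection for %s: %d of %d partners annotated (%.1f%%)\n",
              x$focal_gene, x$n_annotated, x$n_partners, 100 * x$fraction))
  invisible(x)
}

#' Read a one- or two-column annotation TSV
#'
#' One column (`gene_id`) yields a character vector of ids; a second
#' (`label`) column yields a named character vector gene id -> label, the
#' form consumed by [hub_by_category_test()].
#'
#' @param path TSV path with a header.
#' @return character vector of gene ids, or named character vector of labels.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) stop("annotation table needs a gene_id column")
  if ("label" %in% names(df))
    stats::setNames(as.character(df$label), as.character(df$gene_id))
  else as.character(df$gene_id)
}
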