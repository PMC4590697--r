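#' Read a parent-child duplicate-pair table
#'
#' @param path TSV with columns `parent_id`, `child_id` and optional
#'   `mechanism`.
#' @return data.frame with columns `parent_id`, `child_id`, `mechanism`.
#' @export
read_duplicate_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("parent_id", "child_id") %in% names(df)))
    stop("pairs table needs columns parent_id, child_id")
  if (!"mechanism" %in% names(df)) df$mechanism <- NA_character_
  if (any(df$parent_id == df$child_id)) stop("parent_id equal to child_id in pairs table")
  df[, c("parent_id", "child_id", "mechanism")]
}

neighbor_sets <- function(net) {
  adj <- igraph::as_adj_list(net, mode = "all")
  nm <- igraph::V(net)$name
  stats::setNames(lapply(adj, function(v) nm[as.integer(v)]), nm)
}

shared_fraction_one <- function(nbr, parent, child, denominator) {
  np <- setdiff(nbr[[parent]], c(parent, child))
  nc <- setdiff(nbr[[child]], c(parent, child))
  num <- length(intersect(np, nc))
  den <- switch(denominator,
                child = length(nc),
                parent = length(np),
                union = length(union(np, nc)))
  if (den == 0L) 0 else num / den
}

#' Fraction of linking partners shared between a duplicate pair
#'
#' For a parent-child duplicate gene pair, the fraction of common linking
#' partners: `|N(parent) intersect N(child) \ {parent, child}|` divided by a
#' configurable exposure. The default denominator is the child's partner
#' count (excluding the parent itself), reading the quantity as "what
#' fraction of the child's partners were inherited from the parent". The
#' `"parent"` denominator instead asks what fraction of the parent's
#' partners the child retained — the natural estimator of a per-edge
#' retention probability — and `"union"` gives the Jaccard index of the two
#' neighbourhoods. A child whose only partner is the parent has no partners
#' to attribute and returns 0.
#'
#' @param net an igraph network containing both genes.
#' @param parent,child gene ids.
#' @param denominator `"child"` (default), `"parent"` or `"union"`.
#' @return a number in `[0, 1]`.
#' @export
shared_partner_fraction <- function(net, parent, child,
                                    denominator = c("child", "parent", "union")) {
  denominator <- match.arg(denominator)
  nm <- igraph::V(net)$name
  missing <- setdiff(c(parent, child), nm)
  if (length(missing) > 0L)
    stop("gene(s) absent from network: ", paste(missing, collapse = ", "))
  if (parent == child) stop("parent and child must differ")
  shared_fraction_one(neighbor_sets(net), parent, child, denominator)
}

#' Shared-partner fractions for a table of duplicate pairs
#'
#' Vectorized form of [shared_partner_fraction()]. Pairs with either gene
#' absent from the network are skipped with a warning; pairs whose child has
#' no partner besides the parent are kept (fraction 0) and flagged
#' degenerate.
#'
#' @inheritParams shared_partner_fraction
#' @param pairs data.frame with columns `parent_id`, `child_id`.
#' @return data.frame with columns `parent_id`, `child_id`, `fraction`,
#'   `degenerate`.
#' @export
shared_partner_fractions <- function(net, pairs,
                                     denominator = c("child", "parent", "union")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(pairs), all(c("parent_id", "child_id") %in% names(pairs)))
  nbr <- neighbor_sets(net)
  nm <- names(nbr)
  present <- pairs$parent_id %in% nm & pairs$child_id %in% nm
  if (any(!present))
    warning(sum(!present), " pair(s) skipped: gene(s) absent from network")
  pairs <- pairs[present, , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(data.frame(parent_id = character(), child_id = character(),
                      fraction = numeric(), degenerate = logical()))
  frac <- mapply(function(p, c) shared_fraction_one(nbr, p, c, denominator),
                 pairs$parent_id, pairs$child_id)
  denom_side <- if (denominator == "parent") pairs$parent_id else pairs$child_id
  degen <- mapply(function(p, c, side) {
    length(setdiff(nbr[[side]], c(p, c))) == 0L
  }, pairs$parent_id, pairs$child_id,
     if (denominator == "parent") pairs$parent_id else pairs$child_id)
  data.frame(parent_id = pairs$parent_id, child_id = pairs$child_id,
             fraction = unname(frac), degenerate = unname(degen),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partner inheritance of duplicate pairs versus a random-pair null
#'
#' Computes the mean shared-partner fraction over the observed duplicate
#' pairs and compares it with a null in which, for each replicate, the same
#' number of uniform random gene pairs (distinct genes, first drawn gene in
#' the parent role) is sampled from the network and their mean shared
#' fraction recorded. Reported are the null mean, the fold of the observed
#' mean over the null mean, and a one-sided empirical p-value (the fraction
#' of null replicates at least as large as the observed mean).
#'
#' @inheritParams shared_partner_fractions
#' @param reps number of null replicates, >= 100.
#' @param seed integer seed; the result is bit-for-bit reproducible given
#'   `(seed, reps)`.
#' @return list of class `"inheritance_summary"`: `n_pairs`,
#'   `mean_shared_fraction`, `null_mean_shared_fraction`, `fold_over_null`,
#'   `p_value`, `null_reps`, `seed`, `denominator`, `per_pair` (the
#'   data.frame from [shared_partner_fractions()]), `null_means`.
#' @export
inheritance_vs_random <- function(net, pairs, reps = 1000, seed = 1,
                                  denominator = c("child", "parent", "union")) {
  denominator <- match.arg(denominator)
  if (reps < 100) stop("reps must be >= 100 (the null would be too coarse)")
  per_pair <- shared_partner_fractions(net, pairs, denominator = denominator)
  if (nrow(per_pair) == 0L) stop("no duplicate pair has both genes in the network")
  nm <- igraph::V(net)$name
  if (length(nm) < 2L * nrow(per_pair))
    stop("network too small for a ", nrow(per_pair), "-pair null")
  nbr <- neighbor_sets(net)
  observed <- mean(per_pair$fraction)
  n_pairs <- nrow(per_pair)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  null_means <- vapply(seq_len(reps), function(r) {
    a <- sample(nm, n_pairs, replace = TRUE)
    b <- vapply(a, function(x) sample(setdiff(nm, x), 1L), "")
    mean(mapply(function(p, c) shared_fraction_one(nbr, p, c, denominator), a, b))
  }, 1)
  null_mean <- mean(null_means)
  structure(list(n_pairs = n_pairs,
                 mean_shared_fraction = observed,
                 null_mean_shared_fraction = null_mean,
                 fold_over_null = if (null_mean > 0) observed / null_mean else Inf,
                 p_value = mean(null_means >= observed),
                 null_reps = as.integer(reps), seed = as.integer(seed),
                 denominator = denominator, per_pair = per_pair,
                 null_means = null_means),
            class = "inheritance_summary")
}

#' @export
print.inheritance_summary <- function(x, ...) {
  cat(sprintf(paste0("Partner inheritance over %d duplicate pairs: %.1f%% shared",
                     " (random-pair null %.2f%%, fold %.1f, empirical p = %.3g)\n"),
              x$n_pairs, 100 * x$mean_shared_fraction,
              100 * x$null_mean_shared_fraction, x$fold_over_null, x$p_value))
  invisible(x)
}

# Novel (non-inherited) partners of each child gene: the child's partners
# excluding the parent and everything shared with the parent.
new_link_partners <- function(net, pairs) {
  nbr <- neighbor_sets(net)
  nm <- names(nbr)
  keep <- pairs$parent_id %in% nm & pairs$child_id %in% nm
  pairs <- pairs[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs$parent_id[i]; c <- pairs$child_id[i]
    novel <- setdiff(nbr[[c]], c(p, c, nbr[[p]]))
    if (length(novel) == 0L) NULL
    else data.frame(child_id = c, partner_id = novel, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Equal-size tercile labels (3 = high .. 1 = low) by descending metric rank,
# ties broken by gene id.
centrality_terciles <- function(cent, metric) {
  ord <- order(-cent[[metric]], cent$gene_id)
  n <- nrow(cent)
  base <- n %/% 3L; extra <- n %% 3L
  sizes <- rep(base, 3L) + c(rep(1L, extra), rep(0L, 3L - extra))
  lab <- integer(n)
  lab[ord] <- rep(c(3L, 2L, 1L), times = sizes)  # high, moderate, low
  stats::setNames(lab, cent$gene_id)
}

#' Centrality preference of young genes' new linking partners
#'
#' After removing the interactions a young (child) gene shares with its
#' parent, the remaining novel partners are classified into high / moderate /
#' low centrality levels — network-wide terciles of equal gene count, ranked
#' by the chosen metric — and the observed tercile counts are tested against
#' the expectation proportional to tercile sizes with a chi-square
#' goodness-of-fit test. Under preferential attachment the high tercile is
#' over-represented.
#'
#' The centrality table used for the terciles is an explicit argument: for
#' observational data pass the centralities of the analyzed network itself;
#' when calibrating against a growth simulation, centralities of the network
#' with the tested novel links removed avoid the self-link bias (a counted
#' link raises its own target's final degree; see the methods vignette).
#'
#' @param net igraph network.
#' @param cent a `"centrality_table"` covering the network genes.
#' @param pairs duplicate-pair data.frame (`parent_id`, `child_id`),
#'   children being the young genes under test.
#' @param metric `"degree"` (default) or `"betweenness"`.
#' @return list of class `"attachment_test"`: `observed_counts`,
#'   `expected_counts` (named low/moderate/high), `statistic`, `p_value`,
#'   `test = "chi_square"`, `metric`, `n_links`.
#' @export
new_link_centrality_preference <- function(net, cent, pairs,
                                           metric = c("degree", "betweenness")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(cent), metric %in% names(cent))
  links <- new_link_partners(net, pairs)
  if (is.null(links) || nrow(links) == 0L) stop("no new links to test")
  terc <- centrality_terciles(cent, metric)
  lab <- terc[links$partner_id]
  if (anyNA(lab)) stop("centrality table does not cover all partner genes")
  obs <- vapply(1:3, function(l) sum(lab == l), 1L)
  sizes <- vapply(1:3, function(l) sum(terc == l), 1L)
  ct <- stats::chisq.test(obs, p = sizes / sum(sizes))
  names(obs) <- c("low", "moderate", "high")
  structure(list(observed_counts = obs,
                 expected_counts = stats::setNames(as.numeric(ct$expected),
                                                   c("low", "moderate", "high")),
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 test = "chi_square", metric = metric, n_links = nrow(links)),
            class = "attachment_test")
}

#' Age preference of young genes' new linking partners
#'
#' Tests whether the novel (non-inherited) partners of young genes are
#' biased toward old genes, against a random expectation in which each young
#' gene draws the same number of partners uniformly from the network's aged
#' genes (excluding itself). The observed and expected old/young counts form
#' a 2x2 table assessed with a two-sided Fisher exact test.
#'
#' @param net igraph network.
#' @param ages an `"age_table"` (its young-branch set defines young/old).
#' @param pairs duplicate-pair data.frame.
#' @param seed integer seed for the random expectation draw.
#' @return list of class `"attachment_test"` with the 2x2 `table`
#'   (rows observed/expected, columns old/young), `odds_ratio`, `p_value`,
#'   `test = "fisher_exact"`, `seed`.
#' @export
new_link_age_preference <- function(net, ages, pairs, seed = 1) {
  stopifnot(inherits(ages, "age_table"))
  links <- new_link_partners(net, pairs)
  if (is.null(links) || nrow(links) == 0L) stop("no new links to test")
  cls <- classify_young_old(ages)
  age_of <- stats::setNames(as.character(cls$age_class), cls$gene_id)
  aged_net_genes <- intersect(igraph::V(net)$name, cls$gene_id)
  if (length(aged_net_genes) < 2L) stop("too few aged network genes")
  lab <- age_of[links$partner_id]
  links <- links[!is.na(lab), , drop = FALSE]
  lab <- lab[!is.na(lab)]
  if (nrow(links) == 0L) stop("no aged new-link partner")
  obs <- c(old = sum(lab == "old"), young = sum(lab == "young"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  per_child <- table(links$child_id)
  exp_lab <- unlist(lapply(names(per_child), function(ch) {
    pool <- setdiff(aged_net_genes, ch)
    age_of[sample(pool, min(per_child[[ch]], length(pool)))]
  }))
  expd <- c(old = sum(exp_lab == "old"), young = sum(exp_lab == "young"))
  tab <- rbind(observed = obs, expected = expd)
  ft <- stats::fisher.test(tab)
  structure(list(table = tab, observed_counts = obs, expected_counts = expd,
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                 test = "fisher_exact", seed = as.integer(seed),
                 n_links = sum(obs)),
            class = "attachment_test")
}

#' @export
print.attachment_test <- function(x, ...) {
  cat(sprintf("Attachment test (%s): statistic = %s, p = %.4g over %d links\n",
              x$test,
              if (!is.null(x$statistic)) sprintf("%.2f", x$statistic)
              else sprintf("OR %.2f", x$odds_ratio),
              x$p_value, x$n_links))
  invisible(x)
}

#' Origination-mechanism composition of young genes
#'
#' Fractions of young genes per origination mechanism; duplication-based
#' combines DNA- and RNA-level duplication. Genes without a mechanism label
#' are reported separately as unannotated and excluded from the fractions'
#' denominator.
#'
#' @param ages an `"age_table"` with mechanism labels.
#' @param young_branches branch set; defaults to the table's own.
#' @return list with `n_young`, `n_unannotated`, `fractions` (named:
#'   dna_duplication, rna_duplication, de_novo, duplication_based).
#' @export
mechanism_composition <- function(ages, young_branches = NULL) {
  stopifnot(inherits(ages, "age_table"))
  cls <- classify_young_old(ages, young_branches)
  young <- ages$genes[cls$age_class == "young", , drop = FALSE]
  unann <- sum(is.na(young$mechanism))
  ann <- young$mechanism[!is.na(young$mechanism)]
  n <- length(ann)
  frac <- function(lab) if (n > 0) sum(ann == lab) / n else NA_real_
  f <- c(dna_duplication = frac("dna_duplication"),
         rna_duplication = frac("rna_duplication"),
         de_novo = frac("de_novo"))
  f <- c(f, duplication_based = unname(f["dna_duplication"] + f["rna_duplication"]))
  list(n_young = nrow(young), n_unannotated = unann, fractions = f)
}

#' Remove young genes' novel links from a network
#'
#' Returns the network with each child gene's novel (non-inherited) links
#' deleted, i.e. the ancestral interaction structure as it stood before the
#' tested attachments. Centralities computed on this network give an
#' unbiased reference for [new_link_centrality_preference()] when
#' calibrating against growth simulations: evaluated on the final network,
#' every counted link has itself raised its target's degree, inflating the
#' high-centrality tercile even under a uniform attachment kernel.
#'
#' @param net igraph network.
#' @param pairs duplicate-pair data.frame (`parent_id`, `child_id`).
#' @return an igraph network with the novel links removed.
#' @export
remove_novel_links <- function(net, pairs) {
  links <- new_link_partners(net, pairs)
  if (is.null(links) || nrow(links) == 0L) return(net)
  ends <- as.vector(rbind(links$child_id, links$partner_id))
  igraph::delete_edges(net, igraph::get_edge_ids(net, ends))
}
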