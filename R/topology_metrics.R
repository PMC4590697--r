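#' Per-gene network centralities, hub flags and core/periphery layers
#'
#' Computes, for every node of an undirected simple network, its degree (the
#' number of adjacent edges), its betweenness
#' \deqn{B(v) = \sum_{i \ne j \ne v} K(ivj) / K(ij)}
#' where `K(ij)` is the number of shortest paths between `i` and `j` and
#' `K(ivj)` the number of those passing through `v` (summed over unordered
#' pairs; disconnected pairs contribute 0), a hub flag, and a degree-ranked
#' layer assignment from network core (layer 1) to periphery.
#'
#' Betweenness is unnormalized by default, matching the formula above; set
#' `normalized = TRUE` to divide by `(n-1)(n-2)/2` for cross-network
#' comparison.
#'
#' @param net an undirected [igraph::graph] with named vertices.
#' @param hub_min_degree minimum degree for the hub flag; 6 is the
#'   conventional medium-connectivity cutoff for genome-scale PPI networks.
#'   Use `hub_at_median = TRUE` to derive the cutoff from this network.
#' @param n_layers number of core/periphery layers (default 5, i.e. 20%
#'   quantile shells).
#' @param hub_at_median if `TRUE`, `hub_min_degree` is replaced by the
#'   network's median degree.
#' @param normalized normalize betweenness? Default `FALSE`.
#' @return data.frame of class `"centrality_table"` with columns `gene_id`,
#'   `degree`, `betweenness`, `layer`, `is_hub`.
#' @export
centrality_table <- function(net, hub_min_degree = 6, n_layers = 5,
                             hub_at_median = FALSE, normalized = FALSE) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("empty network")
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = normalized)
  cent <- data.frame(gene_id = igraph::V(net)$name,
                     degree = as.integer(unname(deg)),
                     betweenness = unname(btw),
                     stringsAsFactors = FALSE)
  class(cent) <- c("centrality_table", "data.frame")
  if (hub_at_median) hub_min_degree <- stats::median(cent$degree)
  cent <- assign_layers(cent, n_layers = n_layers)
  flag_hubs(cent, min_degree = hub_min_degree)
}

#' Flag hub genes by a minimum-degree cutoff
#'
#' @param cent a `"centrality_table"` (or any data.frame with `degree`).
#' @param min_degree hubs satisfy `degree >= min_degree`; default 6.
#' @return `cent` with a logical `is_hub` column.
#' @export
flag_hubs <- function(cent, min_degree = 6) {
  stopifnot(is.data.frame(cent), "degree" %in% names(cent))
  if (!is.numeric(min_degree) || min_degree < 1) stop("min_degree must be >= 1")
  cent$is_hub <- cent$degree >= min_degree
  cent
}

#' Assign core/periphery layers by degree rank
#'
#' Ranks genes by degree (descending, ties broken by gene id for
#' reproducibility) and slices the ranking into `n_layers` contiguous groups
#' of near-equal size (sizes differ by at most one; the extra genes go to the
#' top layers). Layer 1 is the network core (highest degrees), layer
#' `n_layers` the periphery.
#'
#' @param cent data.frame with columns `gene_id` and `degree`.
#' @param n_layers number of layers, >= 2; default 5.
#' @return `cent` with an integer `layer` column.
#' @export
assign_layers <- function(cent, n_layers = 5) {
  stopifnot(is.data.frame(cent), all(c("gene_id", "degree") %in% names(cent)))
  n_layers <- as.integer(n_layers)
  if (n_layers < 2L) stop("n_layers must be >= 2")
  n <- nrow(cent)
  if (n < n_layers) stop("fewer genes (", n, ") than layers (", n_layers, ")")
  ord <- order(-cent$degree, cent$gene_id)
  base <- n %/% n_layers
  extra <- n %% n_layers
  sizes <- rep(base, n_layers) + c(rep(1L, extra), rep(0L, n_layers - extra))
  layer <- integer(n)
  layer[ord] <- rep(seq_len(n_layers), times = sizes)
  cent$layer <- layer
  cent
}

#' Fit the degree-distribution exponent
#'
#' Estimates the exponent `gamma` of a power-law degree distribution
#' `P(k) ~ k^-gamma` from the degrees of a network (or a raw degree
#' sequence). Two estimators are offered:
#'
#' * `"ls"` (default): ordinary least squares on `log10` frequency versus
#'   `log10` degree over the raw degree histogram — the historical approach
#'   in the PPI literature (it is also the one that tends to produce the
#'   small exponents, below 2, reported for protein interaction networks).
#' * `"mle"`: discrete maximum likelihood with Kolmogorov-Smirnov selection
#'   of the lower cutoff `x_min` (Clauset-style, via
#'   [igraph::fit_power_law()]), the statistically preferred estimator.
#'
#' @param net an igraph network, or a numeric vector of degrees.
#' @param method `"ls"` or `"mle"`.
#' @param x_min lower degree cutoff for the MLE; `NULL` (default) selects it
#'   by KS minimization. Ignored by `"ls"`.
#' @return list of class `"degree_fit"` with elements `exponent`,
#'   `fit_method`, `x_min`, and for `"ls"` the underlying `lm` fit.
#' @export
fit_degree_exponent <- function(net, method = c("ls", "mle"), x_min = NULL) {
  method <- match.arg(method)
  k <- if (igraph::is_igraph(net)) as.numeric(igraph::degree(net)) else as.numeric(net)
  k <- k[k >= 1]
  if (length(unique(k)) < 2L)
    stop("degenerate degree sequence (fewer than two distinct positive degrees)")
  if (length(k) < 20L)
    warning("fewer than 20 nodes with degree >= 1; exponent estimate is unstable")
  if (method == "ls") {
    tab <- table(k)
    kk <- as.numeric(names(tab))
    fit <- stats::lm(log10(as.numeric(tab)) ~ log10(kk))
    structure(list(exponent = -unname(stats::coef(fit)[2L]),
                   fit_method = "ls", x_min = min(kk), lm_fit = fit),
              class = "degree_fit")
  } else {
    pl <- igraph::fit_power_law(k, xmin = x_min, implementation = "plfit")
    structure(list(exponent = pl$alpha, fit_method = "mle", x_min = pl$xmin,
                   ks_stat = pl$KS.stat),
              class = "degree_fit")
  }
}

#' @export
print.degree_fit <- function(x, ...) {
  cat(sprintf("Power-law degree fit (%s): exponent = %.3f, x_min = %s\n",
              x$fit_method, x$exponent, format(x$x_min)))
  invisible(x)
}

#' Write a centrality table as TSV
#'
#' @param cent a `"centrality_table"`.
#' @param path output file.
#' @export
write_centrality_table <- function(cent, path) {
  utils::write.table(cent[, c("gene_id", "degree", "betweenness", "layer", "is_hub")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cent)
}
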