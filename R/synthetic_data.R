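#' Parameters for the duplication-divergence growth simulator
#'
#' Bundles and validates the parameters of [grow_network()]. The simulated
#' process combines the two classical mechanisms of interaction-network
#' growth: gene duplication with divergence (a new node copies a uniformly
#' chosen extant node's edges, each retained with probability `retention_q`)
#' and attachment of novel links (each new node then draws `n_new_links`
#' additional targets, uniformly or proportionally to degree — the
#' rich-get-richer kernel).
#'
#' `p_duplication` and `n_new_links` may be scalars or per-node vectors of
#' length `n_final - seed_graph_size`, allowing staged schedules (e.g. an
#' ancestral de novo phase followed by a recent duplication cohort).
#'
#' @param n_final total number of nodes.
#' @param seed_graph_size size of the initial seed clique, >= 3.
#' @param p_duplication probability a new node is born by duplication
#'   (versus de novo); default 0.95, matching the empirical dominance of
#'   duplication among recently originated genes.
#' @param retention_q probability each parental edge is inherited.
#' @param n_new_links number of additional (novel) links per new node.
#' @param attachment_kernel `"degree_linear"` (preferential attachment) or
#'   `"uniform"`.
#' @param p_rna_duplication fraction of duplication births labelled
#'   RNA-level (retroposition-like) rather than DNA-level; bookkeeping only,
#'   default 0.2.
#' @param branch_table branch definition table (see
#'   [default_branch_table()]); nodes are mapped uniformly onto its branches
#'   in birth order, oldest branch first, so downstream age machinery is
#'   exercised end to end.
#' @param branch0_sentinel numeric age for branch 0; default 500.
#' @param young_branches young branch set; default 8:12.
#' @param rng_seed integer seed; the whole simulation is reproducible
#'   bit-for-bit from the parameter set.
#' @return list of class `"growth_params"`.
#' @export
growth_params <- function(n_final = 1000, seed_graph_size = 5,
                          p_duplication = 0.95, retention_q = 0.3,
                          n_new_links = 2,
                          attachment_kernel = c("degree_linear", "uniform"),
                          p_rna_duplication = 0.2,
                          branch_table = default_branch_table("human"),
                          branch0_sentinel = 500, young_branches = 8:12,
                          rng_seed = 1) {
  attachment_kernel <- match.arg(attachment_kernel)
  n_final <- as.integer(n_final); seed_graph_size <- as.integer(seed_graph_size)
  if (seed_graph_size < 3L) stop("seed_graph_size must be >= 3")
  if (n_final <= seed_graph_size) stop("n_final must exceed seed_graph_size")
  n_grow <- n_final - seed_graph_size
  recycle <- function(x, what) {
    if (length(x) == 1L) rep(x, n_grow)
    else if (length(x) == n_grow) x
    else stop(what, " must be a scalar or a vector of length n_final - seed_graph_size")
  }
  p_duplication <- recycle(p_duplication, "p_duplication")
  n_new_links <- as.integer(recycle(n_new_links, "n_new_links"))
  if (any(p_duplication < 0 | p_duplication > 1)) stop("p_duplication must lie in [0, 1]")
  if (retention_q < 0 || retention_q > 1) stop("retention_q must lie in [0, 1]")
  if (p_rna_duplication < 0 || p_rna_duplication > 1) stop("p_rna_duplication in [0, 1]")
  if (any(n_new_links < 0)) stop("n_new_links must be >= 0")
  structure(list(n_final = n_final, seed_graph_size = seed_graph_size,
                 p_duplication = p_duplication, retention_q = retention_q,
                 n_new_links = n_new_links, attachment_kernel = attachment_kernel,
                 p_rna_duplication = p_rna_duplication,
                 branch_table = branch_table,
                 branch0_sentinel = branch0_sentinel,
                 young_branches = as.integer(young_branches),
                 rng_seed = as.integer(rng_seed)),
            class = "growth_params")
}

#' Grow a duplication-divergence / preferential-attachment network
#'
#' Starting from a seed clique, nodes are added one at a time. With
#' probability `p_duplication` a new node duplicates a uniformly chosen
#' extant node, inheriting each of its edges independently with probability
#' `retention_q` (the parent is recorded in the duplicate-pair manifest);
#' otherwise it is born de novo with no inherited edges. The node then
#' acquires `n_new_links` novel links to distinct extant targets drawn by
#' the attachment kernel — proportional to current degree
#' (`"degree_linear"`, the rich-get-richer rule whose pure form is the
#' Barabasi-Albert model with asymptotic degree exponent 3) or uniformly.
#' Self-loops and multi-edges are never created; if a draw has no remaining
#' candidate the link is skipped with a warning.
#'
#' Nodes are mapped onto the branch table's phylogenetic branches uniformly
#' in birth order (seed clique and earliest nodes in branch 0, latest nodes
#' in the youngest branch), giving every node a branch and a birth time in
#' myr, so the simulator's outputs feed the entire pipeline unchanged.
#'
#' @param params a `"growth_params"` object.
#' @return list of class `"ggi_simulation"`: `network` (igraph), `nodes`
#'   (data.frame: `gene_id`, `node_index`, `branch`, `birth_myr`,
#'   `mechanism`, `parent_id`), `pairs` (data.frame: `parent_id`,
#'   `child_id`, `mechanism`), `params`.
#' @examples
#' sim <- grow_network(growth_params(n_final = 200, rng_seed = 7))
#' igraph::vcount(sim$network)
#' nrow(sim$pairs)  # realized duplication events
#' @export
grow_network <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$rng_seed)
  n <- params$n_final; s <- params$seed_graph_size
  ids <- sprintf("g%05d", seq_len(n))
  adj <- vector("list", n)
  deg <- integer(n)
  # seed clique
  for (i in seq_len(s)) adj[[i]] <- setdiff(seq_len(s), i)
  deg[seq_len(s)] <- s - 1L
  seed_edges <- which(upper.tri(matrix(0, s, s)), arr.ind = TRUE)
  mechanism <- rep(NA_character_, n)
  parent_of <- rep(NA_integer_, n)
  child_targets <- vector("list", n)  # edges contributed by each grown node
  skipped <- 0L
  for (i in (s + 1L):n) {
    gi <- i - s
    inherited <- integer(0)
    if (stats::runif(1) < params$p_duplication[gi]) {
      parent <- sample.int(i - 1L, 1L)
      pn <- adj[[parent]]
      if (length(pn) > 0L)
        inherited <- pn[stats::runif(length(pn)) < params$retention_q]
      parent_of[i] <- parent
      mechanism[i] <- if (stats::runif(1) < params$p_rna_duplication)
        "rna_duplication" else "dna_duplication"
    } else {
      mechanism[i] <- "de_novo"
    }
    targets <- inherited
    for (l in seq_len(params$n_new_links[gi])) {
      cand <- setdiff(seq_len(i - 1L), targets)
      if (length(cand) == 0L) { skipped <- skipped + 1L; next }
      if (params$attachment_kernel == "degree_linear" && sum(deg[cand]) > 0) {
        t <- cand[sample.int(length(cand), 1L, prob = deg[cand])]
      } else {
        t <- cand[sample.int(length(cand), 1L)]
      }
      targets <- c(targets, t)
    }
    targets <- unique(targets)
    child_targets[[i]] <- targets
    adj[[i]] <- targets
    for (t in targets) adj[[t]] <- c(adj[[t]], i)
    deg[i] <- length(targets)
    deg[targets] <- deg[targets] + 1L
  }
  if (skipped > 0L)
    warning(skipped, " novel link draw(s) skipped: no remaining candidate target")

  branch_idx <- sort(params$branch_table$branch)
  branch_of <- branch_idx[ceiling(seq_len(n) / n * length(branch_idx))]
  mids <- (params$branch_table$start_myr + params$branch_table$end_myr) / 2
  mids[params$branch_table$branch == 0L] <- params$branch0_sentinel
  birth <- mids[match(branch_of, params$branch_table$branch)]

  ef <- c(ids[seed_edges[, 1L]],
          ids[rep(seq_len(n), times = vapply(child_targets, length, 1L))])
  et <- c(ids[seed_edges[, 2L]], ids[unlist(child_targets)])
  g <- igraph::graph_from_data_frame(data.frame(from = ef, to = et,
                                                stringsAsFactors = FALSE),
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  stopifnot(igraph::is_simple(g))
  nodes <- data.frame(gene_id = ids, node_index = seq_len(n),
                      branch = branch_of, birth_myr = birth,
                      mechanism = mechanism,
                      parent_id = ifelse(is.na(parent_of), NA_character_,
                                         ids[ifelse(is.na(parent_of), 1L, parent_of)]),
                      stringsAsFactors = FALSE)
  dup <- which(!is.na(parent_of))
  pairs <- data.frame(parent_id = ids[parent_of[dup]], child_id = ids[dup],
                      mechanism = mechanism[dup], stringsAsFactors = FALSE)
  structure(list(network = g, nodes = nodes, pairs = pairs, params = params),
            class = "ggi_simulation")
}

#' @export
print.ggi_simulation <- function(x, ...) {
  cat(sprintf(paste0("Simulated GGI network: %d nodes, %d edges, %d duplication",
                     " events (%s kernel, q = %.2f)\n"),
              igraph::vcount(x$network), igraph::ecount(x$network),
              nrow(x$pairs), x$params$attachment_kernel, x$params$retention_q))
  invisible(x)
}

#' Age table of a simulated network
#'
#' @param manifest a `"ggi_simulation"`.
#' @return an `"age_table"` over the simulated genes.
#' @export
sim_age_table <- function(manifest) {
  stopifnot(inherits(manifest, "ggi_simulation"))
  age_table(data.frame(gene_id = manifest$nodes$gene_id,
                       branch = manifest$nodes$branch,
                       mechanism = manifest$nodes$mechanism,
                       stringsAsFactors = FALSE),
            manifest$params$branch_table,
            branch0_sentinel = manifest$params$branch0_sentinel,
            young_branches = manifest$params$young_branches)
}

#' Simulate a tissue expression matrix over a grown network
#'
#' Emulates the age-breadth coupling of real expression atlases: each gene
#' is expressed (value above the call threshold) in a number of tissues that
#' increases with its age at rate `breadth_slope` (tissues per myr), plus
#' Gaussian noise. Expressed values are log-normal above the threshold,
#' unexpressed ones uniform below it. `breadth_slope = 0` gives the null
#' fixture with breadth independent of age.
#'
#' @param manifest a `"ggi_simulation"`.
#' @param n_tissues number of tissues, >= 3; default 27 (an RNA-seq
#'   atlas-sized panel).
#' @param base_breadth expected breadth of a age-0 gene; default 3.
#' @param breadth_slope tissues gained per myr of age; default 0.04 (about
#'   20 extra tissues over 500 myr).
#' @param noise_sd SD of the Gaussian breadth noise; default 2.
#' @param call_threshold expression-call cutoff the values straddle;
#'   default 1.0 (FPKM-like).
#' @param seed integer seed.
#' @return numeric matrix genes x tissues with dimnames.
#' @export
simulate_expression <- function(manifest, n_tissues = 27, base_breadth = 3,
                                breadth_slope = 0.04, noise_sd = 2,
                                call_threshold = 1.0, seed = 1) {
  stopifnot(inherits(manifest, "ggi_simulation"))
  if (n_tissues < 3L) stop("n_tissues must be >= 3")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  nodes <- manifest$nodes
  n <- nrow(nodes)
  target <- base_breadth + breadth_slope * nodes$birth_myr +
    stats::rnorm(n, 0, noise_sd)
  target <- pmin(pmax(round(target), 0L), n_tissues)
  m <- matrix(stats::runif(n * n_tissues, 0, call_threshold / 2),
              nrow = n, ncol = n_tissues,
              dimnames = list(nodes$gene_id, sprintf("tissue%02d", seq_len(n_tissues))))
  for (i in seq_len(n)) {
    if (target[i] > 0L) {
      on <- sample.int(n_tissues, target[i])
      m[i, on] <- call_threshold + stats::rlnorm(target[i], meanlog = log(8), sdlog = 1)
    }
  }
  m
}

#' Simulate an essentiality annotation set over a grown network
#'
#' Assigns essentiality with probability logistic in network degree:
#' `P(essential) = plogis(intercept + coupling * degree)`. With
#' `essential_degree_coupling = 0` the essential fraction is flat across
#' degree bins (null fixture); positive coupling reproduces the empirical
#' association between connectivity and essentiality. Ground-truth
#' probabilities are attached as an attribute.
#'
#' @param manifest a `"ggi_simulation"`.
#' @param essential_degree_coupling logistic slope on degree; default 0.5.
#' @param intercept logistic intercept; default -3 (about 5% essential at
#'   degree 0 under the default coupling scale).
#' @param seed integer seed.
#' @return an `"annotation_set"` named `"essential"`, with attribute
#'   `"probabilities"` (named numeric over all genes).
#' @export
simulate_annotations <- function(manifest, essential_degree_coupling = 0.5,
                                 intercept = -3, seed = 1) {
  stopifnot(inherits(manifest, "ggi_simulation"))
  if (essential_degree_coupling < 0) stop("essential_degree_coupling must be >= 0")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  deg <- igraph::degree(manifest$network)
  p <- stats::plogis(intercept + essential_degree_coupling * as.numeric(deg))
  names(p) <- names(deg)
  ess <- names(p)[stats::runif(length(p)) < p]
  out <- structure(list(name = "essential", genes = ess,
                        source_count = stats::setNames(rep(2L, length(ess)), ess)),
                   class = "annotation_set")
  attr(out, "probabilities") <- p
  out
}

#' Write a simulation to the TSV formats the pipeline readers consume
#'
#' Emits a scored edge list (all scores 1.0, the simulator's edges being
#' ground truth), a gene-branch table, a branch-definition table, a
#' duplicate-pair table, optionally an expression matrix and an essential
#' gene list, and a JSON manifest of parameters and realized event tallies.
#' The integration test "simulate, write, read back, run the full pipeline,
#' recover the parameters" runs entirely through these files.
#'
#' @param manifest a `"ggi_simulation"`.
#' @param dir output directory (created if needed).
#' @param expr optional matrix from [simulate_expression()].
#' @param annotations optional `"annotation_set"` from
#'   [simulate_annotations()].
#' @return invisibly, the named list of written paths.
#' @export
write_simulation <- function(manifest, dir, expr = NULL, annotations = NULL) {
  stopifnot(inherits(manifest, "ggi_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  el <- igraph::as_data_frame(manifest$network, what = "edges")
  edges <- data.frame(gene_a = el$from, gene_b = el$to, score = 1.0,
                      stringsAsFactors = FALSE)
  paths$edges <- file.path(dir, "edges.tsv")
  utils::write.table(edges, paths$edges, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$gene_branch <- file.path(dir, "gene_branch.tsv")
  utils::write.table(manifest$nodes[, c("gene_id", "branch", "mechanism")],
                     paths$gene_branch, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$branch_def <- file.path(dir, "branch_def.tsv")
  utils::write.table(manifest$params$branch_table[, c("branch", "start_myr", "end_myr")],
                     paths$branch_def, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$pairs <- file.path(dir, "pairs.tsv")
  utils::write.table(manifest$pairs, paths$pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(expr)) {
    paths$expression <- file.path(dir, "expression.tsv")
    utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                  check.names = FALSE, stringsAsFactors = FALSE),
                       paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(annotations)) {
    paths$essential <- file.path(dir, "essential.tsv")
    utils::write.table(data.frame(gene_id = annotations$genes,
                                  stringsAsFactors = FALSE),
                       paths$essential, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths$manifest <- file.path(dir, "manifest.json")
  mech_tally <- table(factor(manifest$nodes$mechanism,
                             levels = c("dna_duplication", "rna_duplication", "de_novo")))
  info <- list(n_nodes = igraph::vcount(manifest$network),
               n_edges = igraph::ecount(manifest$network),
               n_duplication_events = nrow(manifest$pairs),
               mechanism_tally = as.list(mech_tally),
               params = list(
                 n_final = manifest$params$n_final,
                 seed_graph_size = manifest$params$seed_graph_size,
                 p_duplication = manifest$params$p_duplication[1L],
                 retention_q = manifest$params$retention_q,
                 n_new_links = manifest$params$n_new_links[1L],
                 attachment_kernel = manifest$params$attachment_kernel,
                 p_rna_duplication = manifest$params$p_rna_duplication,
                 rng_seed = manifest$params$rng_seed))
  jsonlite::write_json(info, paths$manifest, auto_unbox = TRUE, digits = 10)
  invisible(paths)
}

#' Estimate the edge-retention probability from a simulation
#'
#' Recovers `retention_q` from a grown network and its duplicate-pair
#' manifest. For each pair the estimator restricts both the parent's
#' partner set and the shared-partner count to genes born before the child.
#' Because every edge forms at the birth of its younger endpoint, the
#' parent's partners older than the child are exactly its partners at the
#' child's birth, each inherited independently with probability
#' `retention_q` — so the per-pair fraction is binomial and the mean over
#' informative pairs is an unbiased estimate of `q`, immune to the
#' contamination of later-born genes attaching to either copy. Pairs whose
#' parent had no partner besides the child at the child's birth carry no
#' information and are excluded.
#'
#' @param manifest a `"ggi_simulation"`.
#' @return list with `estimate` (mean fraction), `n_informative`,
#'   `per_pair` (data.frame `parent_id`, `child_id`, `fraction`).
#' @export
estimate_retention <- function(manifest) {
  stopifnot(inherits(manifest, "ggi_simulation"))
  g <- manifest$network
  idx <- stats::setNames(manifest$nodes$node_index, manifest$nodes$gene_id)
  nbr <- neighbor_sets(g)
  fr <- vapply(seq_len(nrow(manifest$pairs)), function(i) {
    p <- manifest$pairs$parent_id[i]
    ch <- manifest$pairs$child_id[i]
    np_old <- setdiff(nbr[[p]][idx[nbr[[p]]] < idx[ch]], ch)
    if (length(np_old) == 0L) return(NA_real_)
    length(intersect(np_old, nbr[[ch]])) / length(np_old)
  }, 1)
  per_pair <- data.frame(parent_id = manifest$pairs$parent_id,
                         child_id = manifest$pairs$child_id,
                         fraction = fr, stringsAsFactors = FALSE)
  list(estimate = mean(fr, na.rm = TRUE),
       n_informative = sum(!is.na(fr)),
       per_pair = per_pair)
}
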