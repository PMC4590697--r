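# Independent test oracles, kept deliberately naive: exhaustive enumeration
# and brute force, never the code paths they check.

# Betweenness by exhaustive shortest-path counting from an adjacency matrix:
# BFS from every source gives distances and path counts sigma; a pair (i,j)
# contributes sigma_i(v) * sigma_v(j) / sigma_i(j) for every interior v on a
# shortest path. Feasible for the <= 12-node graphs used in tests.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) for (v in which(A[u, ] == 1)) {
        if (is.infinite(dist[s, v])) { dist[s, v] <- d; nxt <- c(nxt, v) }
        if (dist[s, v] == d) sigma[s, v] <- sigma[s, v] + sigma[s, u]
      }
      frontier <- unique(nxt)
    }
  }
  B <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.infinite(dist[i, j])) next
    for (v in seq_len(n)) {
      if (v == i || v == j) next
      if (dist[i, v] + dist[v, j] == dist[i, j])
        B[v] <- B[v] + sigma[i, v] * sigma[v, j] / sigma[i, j]
    }
  }
  B
}

# Two-sided Fisher exact p for a 2x2 table by enumerating every table with
# the same margins; probabilities from choose(), not dhyper. Tables at most
# as probable as the observed one (with the conventional 1e-7 relative
# slack) are summed.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  p <- exp(logp)
  p0 <- p[xs == a]
  sum(p[p <= p0 * (1 + 1e-7)])
}

# Random simple undirected graph as a named adjacency matrix (>= 1 edge).
random_adjacency <- function(n, p_edge = 0.35) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < p_edge]
    if (length(on) > 0) {
      A[on] <- 1L
      A <- A + t(A)
      dimnames(A) <- list(sprintf("n%02d", seq_len(n)), sprintf("n%02d", seq_len(n)))
      return(A)
    }
  }
}

graph_from_adjacency_named <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Path and star fixtures used across test files.
make_path_graph <- function(ids) {
  igraph::graph_from_data_frame(
    data.frame(from = ids[-length(ids)], to = ids[-1]), directed = FALSE)
}

make_star_graph <- function(center, leaves) {
  igraph::graph_from_data_frame(
    data.frame(from = center, to = leaves), directed = FALSE)
}

# Minimal two-branch age fixture: genes split between an old and a young
# branch of a 13-branch table.
tiny_age_table <- function(old_genes, young_genes, old_branch = 2, young_branch = 10) {
  age_table(
    data.frame(gene_id = c(old_genes, young_genes),
               branch = c(rep(old_branch, length(old_genes)),
                          rep(young_branch, length(young_genes)))),
    default_branch_table("human"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
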