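test_that("scored edge lists parse with and without headers", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tscore", "a\tb\t0.9", "a\tc\t0.5", "c\td\t0.68"), tf)
  e <- read_scored_edges(tf)
  expect_s3_class(e, "scored_edges")
  expect_equal(nrow(e), 3L)
  expect_equal(e$score, c(0.9, 0.5, 0.68))

  writeLines(c("a\tb\t0.9", "a\tc\t0.5"), tf)  # headerless
  expect_equal(nrow(read_scored_edges(tf)), 2L)

  writeLines("gene_a\tgene_b\tscore", tf)  # header only
  expect_equal(nrow(read_scored_edges(tf)), 0L)
})

test_that("malformed edge rows are reported with their line numbers", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tscore", "a\tb\t0.9", "a\tc\tNA"), tf)
  expect_error(read_scored_edges(tf), "line\\(s\\) 3")
  writeLines(c("gene_a\tgene_b\tscore", "a\tb\t1.5"), tf)
  expect_error(read_scored_edges(tf), "\\[0, 1\\]")
  writeLines(c("gene_a\tother\tscore", "a\tb\t0.9"), tf)
  expect_error(read_scored_edges(tf), "missing configured column")
})

test_that("PPI construction thresholds, deduplicates and drops self-loops", {
  e <- scored_edges(c("a", "b", "a", "c"), c("b", "a", "a", "d"),
                    c(0.9, 0.9, 0.99, 0.5))
  g <- build_ppi_network(e, min_score = 0.68)
  expect_setequal(igraph::V(g)$name, c("a", "b"))
  expect_equal(igraph::ecount(g), 1L)
  # the stringent cutoff reuses the same operation and here gives the same net
  g77 <- build_ppi_network(e, min_score = 0.77)
  expect_setequal(igraph::V(g77)$name, c("a", "b"))
  expect_equal(igraph::ecount(g77), 1L)
})

test_that("duplicate records keep the maximum score before thresholding", {
  e <- scored_edges(c("a", "b"), c("b", "a"), c(0.5, 0.8))
  expect_equal(igraph::ecount(build_ppi_network(e, 0.68)), 1L)
  expect_equal(igraph::E(build_ppi_network(e, 0))$score, 0.8)
})

test_that("at zero threshold the network equals brute-force set construction", {
  set.seed(42)
  ids <- sprintf("g%02d", 1:15)
  e <- scored_edges(sample(ids, 100, TRUE), sample(ids, 100, TRUE), runif(100))
  g <- build_ppi_network(e, min_score = 0)
  # oracle: unique unordered non-self pairs
  keys <- unique(ifelse(e$gene_a < e$gene_b,
                        paste(e$gene_a, e$gene_b),
                        paste(e$gene_b, e$gene_a))[e$gene_a != e$gene_b])
  expect_equal(igraph::ecount(g), length(keys))
  got <- apply(igraph::as_edgelist(g), 1, function(r) paste(sort(r), collapse = " "))
  expect_setequal(got, keys)
})

test_that("raising the threshold never adds edges or nodes", {
  set.seed(7)
  ids <- sprintf("g%02d", 1:20)
  e <- scored_edges(sample(ids, 200, TRUE), sample(ids, 200, TRUE), runif(200))
  edge_keys <- function(g) apply(igraph::as_edgelist(g), 1,
                                 function(r) paste(sort(r), collapse = " "))
  prev <- build_ppi_network(e, 0)
  for (th in c(0.2, 0.5, 0.68, 0.77, 0.9)) {
    cur <- build_ppi_network(e, th)
    expect_true(all(edge_keys(cur) %in% edge_keys(prev)))
    expect_true(all(igraph::V(cur)$name %in% igraph::V(prev)$name))
    prev <- cur
  }
})

test_that("PPI construction is invariant to record order and endpoint swaps", {
  set.seed(11)
  ids <- sprintf("g%02d", 1:10)
  e <- scored_edges(sample(ids, 60, TRUE), sample(ids, 60, TRUE), runif(60))
  canon <- function(g) {
    el <- apply(igraph::as_edgelist(g), 1, function(r) paste(sort(r), collapse = " "))
    sort(el)
  }
  g1 <- build_ppi_network(e, 0.4)
  perm <- sample(nrow(e))
  g2 <- build_ppi_network(e[perm, ], 0.4)
  g3 <- build_ppi_network(scored_edges(e$gene_b, e$gene_a, e$score), 0.4)
  expect_equal(canon(g2), canon(g1))
  expect_equal(canon(g3), canon(g1))
})

test_that("co-expression edges follow the strict PCC cutoff", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),   # identical profile, r = 1
             c = c(4, 3, 2, 1),                      # negated, r = -1 vs a
             d = c(5, 5, 5, 5))                      # constant, excluded
  expect_warning(g <- build_coexpression_network(m, min_pcc = 0.4), NA)
  expect_setequal(igraph::V(g)$name, c("a", "b"))
  expect_equal(igraph::ecount(g), 1L)
  expect_error(build_coexpression_network(m[, 1:2]), "3 tissues")
  expect_warning(build_coexpression_network(rbind(x = c(1, 1, 1), y = c(2, 2, 2))),
                 "constant")
})

test_that("co-expression network equals the all-pairs brute-force comparison", {
  set.seed(3)
  for (rep in 1:3) {
    m <- matrix(rexp(10 * 8), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), NULL))
    g <- build_coexpression_network(m, min_pcc = 0.4)
    expected <- character(0)
    for (i in 1:9) for (j in (i + 1):10) {
      if (cor(m[i, ], m[j, ]) > 0.4)
        expected <- c(expected, paste(sort(rownames(m)[c(i, j)]), collapse = " "))
    }
    got <- if (igraph::ecount(g) == 0) character(0) else
      apply(igraph::as_edgelist(g), 1, function(r) paste(sort(r), collapse = " "))
    expect_setequal(got, expected)
  }
})
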