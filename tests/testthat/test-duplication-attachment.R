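test_that("shared-partner fractions follow set arithmetic", {
  g <- igraph::graph_from_data_frame(data.frame(
    from = c("p", "p", "p", "c", "c", "c"),
    to   = c("x", "y", "z", "x", "y", "w")), directed = FALSE)
  expect_equal(shared_partner_fraction(g, "p", "c"), 2 / 3)
  expect_equal(shared_partner_fraction(g, "p", "c", denominator = "parent"), 2 / 3)
  expect_equal(shared_partner_fraction(g, "p", "c", denominator = "union"), 2 / 4)
  # disjoint neighbourhoods
  g2 <- igraph::graph_from_data_frame(data.frame(
    from = c("p", "c"), to = c("x", "y")), directed = FALSE)
  expect_equal(shared_partner_fraction(g2, "p", "c"), 0)
  # child's only partner is the parent: degenerate, fraction 0
  g3 <- igraph::graph_from_data_frame(data.frame(
    from = c("p", "p"), to = c("c", "x")), directed = FALSE)
  expect_equal(shared_partner_fraction(g3, "p", "c"), 0)
  fr <- shared_partner_fractions(g3, data.frame(parent_id = "p", child_id = "c"))
  expect_true(fr$degenerate)
  expect_error(shared_partner_fraction(g3, "p", "nope"), "absent")
  expect_warning(
    shared_partner_fractions(g3, data.frame(parent_id = "p", child_id = "nope")),
    "skipped")
})

test_that("inheritance on a complete graph equals the null exactly", {
  ids <- letters[1:5]
  el <- t(combn(ids, 2))
  k5 <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]), directed = FALSE)
  pairs <- data.frame(parent_id = c("a", "b"), child_id = c("b", "c"))
  out <- inheritance_vs_random(k5, pairs, reps = 100, seed = 3)
  expect_equal(out$mean_shared_fraction, 1.0)
  expect_equal(out$null_mean_shared_fraction, 1.0)
  expect_equal(out$fold_over_null, 1.0)
})

test_that("inheritance on a star graph matches pair enumeration", {
  g <- make_star_graph("hub", sprintf("l%d", 1:6))
  pairs <- data.frame(parent_id = c("l1", "l3"), child_id = c("l2", "l4"))
  out <- inheritance_vs_random(g, pairs, reps = 400, seed = 5)
  expect_equal(out$mean_shared_fraction, 1.0)  # both leaves neighbour the hub
  # enumeration oracle over ordered random pairs: leaf-leaf pairs (probability
  # 6/7 * 5/6 = 5/7) share the hub (fraction 1); any pair involving the hub
  # contributes 0 -> null mean 5/7, fold 7/5
  expect_equal(out$null_mean_shared_fraction, 5 / 7, tolerance = 0.05)
  expect_equal(out$fold_over_null, 7 / 5, tolerance = 0.07)
  expect_error(inheritance_vs_random(g, pairs, reps = 50), ">= 100")
})

test_that("the random-pair null is bit-for-bit reproducible from its seed", {
  sim <- grow_network(growth_params(n_final = 120, rng_seed = 9))
  a <- inheritance_vs_random(sim$network, sim$pairs[1:10, ], reps = 120, seed = 42)
  b <- inheritance_vs_random(sim$network, sim$pairs[1:10, ], reps = 120, seed = 42)
  expect_identical(a$null_means, b$null_means)
  c <- inheritance_vs_random(sim$network, sim$pairs[1:10, ], reps = 120, seed = 43)
  expect_false(identical(a$null_means, c$null_means))
})

test_that("chi-square tercile preference matches hand-computed statistics", {
  # 100 genes in near-equal terciles; 36 new links with counts (3, 3, 30)
  # from low to high, checked against the hand-written sum((O - E)^2 / E)
  set.seed(6)
  cent <- data.frame(gene_id = sprintf("g%03d", 1:100), degree = 100:1)
  # tercile sizes (34, 33, 33) from the top: high = ranks 1-34
  g_ids <- cent$gene_id[order(-cent$degree)]
  high <- g_ids[1:34]; mid <- g_ids[35:67]; low <- g_ids[68:100]
  # build a network in which one child has novel links matching those counts
  partners <- c(sample(high, 30), sample(mid, 3), sample(low, 3))
  edges <- data.frame(from = c("par", rep("chi", length(partners))),
                      to = c("chi", partners))
  extra <- data.frame(from = cent$gene_id, to = "anchor")  # keep all genes in net
  g <- igraph::graph_from_data_frame(rbind(edges, extra), directed = FALSE)
  pairs <- data.frame(parent_id = "par", child_id = "chi")
  out <- new_link_centrality_preference(g, cent, pairs, metric = "degree")
  expect_equal(unname(out$observed_counts), c(3, 3, 30))
  expect_equal(out$statistic,
               sum((c(3, 3, 30) - 36 * c(33, 33, 34) / 100)^2 /
                     (36 * c(33, 33, 34) / 100)), tolerance = 1e-10)
  expect_lt(out$p_value, 1e-6)
})

test_that("observed counts at expectation give statistic 0 and p 1", {
  cent <- data.frame(gene_id = sprintf("g%03d", 1:99), degree = 99:1)
  g_ids <- cent$gene_id[order(-cent$degree)]
  partners <- c(g_ids[1:2], g_ids[34:35], g_ids[67:68])  # two per tercile
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(from = c("par", rep("chi", 6)), to = c("chi", partners)),
          data.frame(from = cent$gene_id, to = "anchor")), directed = FALSE)
  out <- suppressWarnings(new_link_centrality_preference(
    g, cent, data.frame(parent_id = "par", child_id = "chi"), "degree"))
  expect_equal(unname(out$statistic), 0)
  expect_equal(out$p_value, 1)
  expect_error(new_link_centrality_preference(
    g, cent, data.frame(parent_id = "g001", child_id = "anchor")[0, ], "degree"),
    "no new links")
})

test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  # exhaustive over all tables with every entry <= 6 (margins <= 12)
  for (a in 0:6) for (b in 0:6) for (c in 0:6) for (d in 0:6) {
    if (a + b + c + d == 0) next
    p_ref <- oracle_fisher_p(a, b, c, d)
    p_got <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(p_got, p_ref, tolerance = 1e-9)
  }
})

test_that("the age-preference test detects no association in balanced tables", {
  # young child with partners split evenly between young and old genes,
  # network large enough that the uniform draw is also near-even
  set.seed(14)
  old_ids <- sprintf("o%03d", 1:100)
  young_ids <- sprintf("y%03d", 1:100)
  partners <- c(old_ids[1:20], young_ids[1:20])
  g <- igraph::graph_from_data_frame(
    rbind(data.frame(from = c("par", rep("chi", 40)), to = c("chi", partners)),
          data.frame(from = c(old_ids, young_ids), to = "anchor")),
    directed = FALSE)
  ages <- tiny_age_table(c(old_ids, "par", "anchor"), c(young_ids, "chi"))
  out <- new_link_age_preference(g, ages,
                                 data.frame(parent_id = "par", child_id = "chi"),
                                 seed = 2)
  expect_equal(sum(out$observed_counts), 40)
  expect_gt(out$p_value, 0.05)
})

test_that("mechanism composition reproduces forced fractions", {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:25),
    branch = c(rep(10, 20), rep(2, 5)),
    mechanism = c(rep("dna_duplication", 15), rep("rna_duplication", 4),
                  "de_novo", rep(NA, 5)))
  tab <- age_table(genes, default_branch_table("human"))
  out <- mechanism_composition(tab)
  expect_equal(out$n_young, 20L)
  expect_equal(unname(out$fractions["duplication_based"]), 0.95)
  expect_equal(unname(out$fractions["de_novo"]), 0.05)
  all_dn <- age_table(data.frame(gene_id = "a", branch = 9, mechanism = "de_novo"),
                      default_branch_table("human"))
  expect_equal(unname(mechanism_composition(all_dn)$fractions["duplication_based"]), 0)
})
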