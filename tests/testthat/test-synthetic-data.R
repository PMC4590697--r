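test_that("growth is reproducible bit-for-bit and validates parameters", {
  p <- growth_params(n_final = 150, rng_seed = 31)
  a <- grow_network(p)
  b <- grow_network(p)
  expect_identical(igraph::as_edgelist(a$network), igraph::as_edgelist(b$network))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$pairs, b$pairs)
  c <- grow_network(growth_params(n_final = 150, rng_seed = 32))
  expect_false(identical(igraph::as_edgelist(a$network), igraph::as_edgelist(c$network)))
  expect_error(growth_params(seed_graph_size = 2), ">= 3")
  expect_error(growth_params(n_final = 5, seed_graph_size = 5), "exceed")
  expect_error(growth_params(retention_q = 1.2), "retention_q")
})

test_that("full retention with no novel links copies neighbourhoods exactly", {
  sim <- grow_network(growth_params(n_final = 80, p_duplication = 1,
                                    retention_q = 1, n_new_links = 0,
                                    rng_seed = 41))
  fr <- shared_partner_fractions(sim$network, sim$pairs)
  expect_true(all(fr$fraction[!fr$degenerate] == 1))
})

test_that("the manifest tallies match the realized events", {
  sim <- grow_network(growth_params(n_final = 400, p_duplication = 0.6,
                                    rng_seed = 51))
  grown <- sim$nodes[sim$nodes$node_index > sim$params$seed_graph_size, ]
  expect_equal(nrow(sim$pairs), sum(!is.na(grown$parent_id)))
  expect_setequal(sim$pairs$child_id, grown$gene_id[!is.na(grown$parent_id)])
  expect_true(all(sim$pairs$mechanism %in% c("dna_duplication", "rna_duplication")))
  expect_true(all(grown$mechanism[is.na(grown$parent_id)] == "de_novo"))
  # every non-seed node has a branch, a birth time and a mechanism
  expect_false(any(is.na(grown$branch)))
  expect_false(any(is.na(grown$birth_myr)))
  expect_false(any(is.na(grown$mechanism)))
  # realized duplication share close to the configured probability
  expect_equal(nrow(sim$pairs) / nrow(grown), 0.6, tolerance = 0.08)
  # mechanism composition downstream equals the manifest tallies
  at <- sim_age_table(sim)
  mc <- mechanism_composition(at)
  young_grown <- grown[grown$branch %in% 8:12, ]
  expect_equal(mc$n_young, nrow(young_grown))  # seed nodes are all branch 0
  expect_equal(unname(mc$fractions["de_novo"]),
               mean(young_grown$mechanism == "de_novo"))
})

test_that("degree-linear growth couples age and degree", {
  sim <- grow_network(growth_params(n_final = 1000, rng_seed = 61))
  cent <- centrality_table(sim$network)
  m <- merge(cent, sim$nodes, by = "gene_id")
  ct <- suppressWarnings(cor.test(m$birth_myr, m$degree, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # and the age profile's mean degree increases with age group
  prof <- suppressWarnings(age_centrality_profile(cent, sim_age_table(sim)))
  expect_gt(cor(prof$age_myr, prof$mean_degree, method = "spearman"), 0)
})

test_that("simulated expression couples breadth to age at the configured slope", {
  sim <- grow_network(growth_params(n_final = 300, rng_seed = 71))
  expr <- simulate_expression(sim, seed = 71)
  expect_identical(expr, simulate_expression(sim, seed = 71))
  b <- expression_breadth(expr, 1.0)
  m <- merge(data.frame(gene_id = names(b), breadth = as.integer(b)),
             sim$nodes, by = "gene_id")
  fit <- lm(breadth ~ birth_myr, data = m)
  expect_lt(abs(unname(coef(fit)[2]) - 0.04), 0.005)
  # null slope: no age signal
  expr0 <- simulate_expression(sim, breadth_slope = 0, seed = 72)
  b0 <- expression_breadth(expr0, 1.0)
  m0 <- merge(data.frame(gene_id = names(b0), breadth = as.integer(b0)),
              sim$nodes, by = "gene_id")
  fit0 <- summary(lm(breadth ~ birth_myr, data = m0))
  expect_gt(fit0$coefficients[2, 4], 0.01)  # slope not significant
})

test_that("simulated essentiality responds to the degree coupling", {
  sim <- grow_network(growth_params(n_final = 500, rng_seed = 81))
  ess0 <- simulate_annotations(sim, essential_degree_coupling = 0, seed = 81)
  p0 <- attr(ess0, "probabilities")
  expect_true(all(abs(p0 - p0[1]) < 1e-12))  # flat probabilities
  ess <- simulate_annotations(sim, essential_degree_coupling = 1, seed = 81)
  deg <- igraph::degree(sim$network)
  expect_gt(mean(deg[names(deg) %in% ess$genes]),
            mean(deg[!names(deg) %in% ess$genes]))
})

test_that("retention is recovered from the manifest estimator", {
  est <- sapply(c(0.2, 0.7), function(q) {
    sim <- grow_network(growth_params(n_final = 300, p_duplication = 1,
                                      n_new_links = 0, retention_q = q,
                                      rng_seed = 91))
    estimate_retention(sim)$estimate
  })
  expect_lt(abs(est[1] - 0.2), 0.1)
  expect_lt(abs(est[2] - 0.7), 0.1)
})

test_that("written simulations round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  sim <- grow_network(growth_params(n_final = 150, rng_seed = 101))
  expr <- simulate_expression(sim, seed = 101)
  ess <- simulate_annotations(sim, seed = 101)
  paths <- write_simulation(sim, dir, expr = expr, annotations = ess)
  edges <- read_scored_edges(paths$edges)
  g <- build_ppi_network(edges, min_score = 0.68)
  expect_equal(igraph::ecount(g), igraph::ecount(sim$network))
  at <- load_age_table(paths$gene_branch, paths$branch_def)
  expect_equal(nrow(at$genes), 150L)
  pr <- read_duplicate_pairs(paths$pairs)
  expect_equal(nrow(pr), nrow(sim$pairs))
  em <- read_expression_matrix(paths$expression)
  expect_equal(dim(em), dim(expr))
  expect_equal(unname(em["g00001", ]), unname(expr["g00001", ]), tolerance = 1e-6)
  expect_setequal(read_annotation(paths$essential), ess$genes)
  expect_true(file.exists(paths$manifest))
})
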