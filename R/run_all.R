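#' Default pipeline configuration
#'
#' The full set of tunables with their conventional defaults: PPI confidence
#' threshold 0.68 (stringent reanalysis 0.77), co-expression PCC cutoff 0.4,
#' expression call threshold 1.0, hub minimum degree 6, five core/periphery
#' layers, quadratic profile regressions, young branches 8-12, branch-0
#' sentinel age 500 myr. Input paths start empty and must be filled in (or
#' the corresponding stage is skipped where optional).
#'
#' @return a named list; see [run_all()] for the semantics of each entry.
#' @export
default_run_config <- function() {
  list(
    inputs = list(edges = NULL, gene_branch = NULL, branch_def = NULL,
                  expression = NULL, pairs = NULL,
                  essential_sources = NULL, categories = NULL),
    min_score = 0.68,
    stringent_min_score = 0.77,
    min_pcc = 0.4,
    expression_threshold = 1.0,
    hub_min_degree = 6,
    n_layers = 5,
    poly_degree = 2,
    young_branches = 8:12,
    branch0_sentinel = 500,
    inheritance_reps = 1000,
    seed = 1,
    out_dir = "netage_out")
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  base <- default_run_config()
  base[names(config)] <- config
  if (!is.null(config$inputs)) {
    inputs <- default_run_config()$inputs
    inputs[names(config$inputs)] <- config$inputs
    base$inputs <- inputs
  }
  base
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full network-integration analysis
#'
#' Executes network construction, age attachment, topology metrics,
#' age-stratified integration profiles, duplicate-pair
#' inheritance/attachment tests, and annotation analyses in order, writing
#' every table as TSV and every test as JSON into the output directory,
#' together with a run log carrying the package version, seed and an MD5
#' hash of the resolved configuration. Given the same configuration and
#' seed the output bundle is byte-identical across runs.
#'
#' @param config a configuration list (see [default_run_config()]) or the
#'   path to a YAML file with the same structure. Required inputs: `edges`
#'   (scored edge list TSV) and `gene_branch` (gene-branch TSV). Optional:
#'   `branch_def` (defaults to the packaged human table), `expression`,
#'   `pairs`, `essential_sources` (vector of gene-list TSVs), `categories`
#'   (gene_id/label TSV). A stage whose optional inputs are absent is
#'   skipped; a failure in any running stage aborts with the stage name.
#' @return invisibly, a list with the main in-memory results (`network`,
#'   `ages`, `centrality`, `profile`, `fits`, `attachment`, `annotation`,
#'   `paths`).
#' @export
run_all <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(cfg$out_dir, "config.yaml"))
  yaml::write_yaml(cfg, paths$config)
  # hash the configuration without the output location, so the same analysis
  # run into two directories is recognizably the same run
  hash_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")], hash_file)
  cfg_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  net <- stage("network_construction", {
    if (is.null(cfg$inputs$edges)) stop("no edge list configured")
    edges <- read_scored_edges(cfg$inputs$edges)
    build_ppi_network(edges, min_score = cfg$min_score)
  })
  paths$network_edges <- file.path(cfg$out_dir, "network_edges.tsv")
  paths$network_nodes <- file.path(cfg$out_dir, "network_nodes.tsv")
  write_network(net, paths$network_edges, paths$network_nodes)

  ages <- stage("gene_ages", {
    if (is.null(cfg$inputs$gene_branch)) stop("no gene-branch table configured")
    load_age_table(cfg$inputs$gene_branch, cfg$inputs$branch_def,
                   branch0_sentinel = cfg$branch0_sentinel,
                   young_branches = cfg$young_branches)
  })

  cent <- stage("topology_metrics",
                centrality_table(net, hub_min_degree = cfg$hub_min_degree,
                                 n_layers = cfg$n_layers))
  paths$centrality <- file.path(cfg$out_dir, "centrality.tsv")
  write_centrality_table(cent, paths$centrality)

  fits <- list()
  profile <- stage("integration_profiles", {
    p <- suppressWarnings(age_centrality_profile(cent, ages))
    p <- acquisition_rate(p)
    fits$degree_vs_age <- fit_profile_regression(p, "mean_degree", "polynomial",
                                                  degree = cfg$poly_degree)
    fits$betweenness_vs_age <- fit_profile_regression(p, "mean_betweenness_log",
                                                       "polynomial",
                                                       degree = cfg$poly_degree)
    fits$rate_vs_age <- fit_profile_regression(p, "acquisition_rate", "power")
    p
  })
  paths$profile <- file.path(cfg$out_dir, "age_profile.tsv")
  utils::write.table(profile, paths$profile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  occ <- stage("integration_profiles", layer_occupancy_by_age(cent, ages))
  paths$layer_occupancy <- file.path(cfg$out_dir, "layer_occupancy.tsv")
  utils::write.table(data.frame(branch = rownames(occ), occ, check.names = FALSE),
                     paths$layer_occupancy, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (!is.null(cfg$inputs$expression)) {
    stage("integration_profiles", {
      expr <- read_expression_matrix(cfg$inputs$expression)
      breadth <- expression_breadth(expr, threshold = cfg$expression_threshold)
      bc <- breadth_vs_connectivity(cent, breadth)
      fits$breadth_vs_degree <- bc$fit
      paths$breadth_profile <- file.path(cfg$out_dir, "breadth_profile.tsv")
      utils::write.table(bc$profile, paths$breadth_profile, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }
  paths$regressions <- file.path(cfg$out_dir, "regressions.json")
  jsonlite::write_json(lapply(fits, function(f)
    list(model = f$model, coefficients = f$coefficients,
         r_squared = f$r_squared, degree = f$degree)),
    paths$regressions, auto_unbox = TRUE, digits = 10)

  attachment <- NULL
  if (!is.null(cfg$inputs$pairs)) {
    attachment <- stage("duplication_attachment", {
      pairs <- read_duplicate_pairs(cfg$inputs$pairs)
      # the inheritance statistic concerns young duplicates: restrict to
      # pairs whose child falls in the young branches (when dated)
      cls <- classify_young_old(ages)
      young_children <- cls$gene_id[cls$age_class == "young"]
      young_pairs <- pairs[pairs$child_id %in% young_children, , drop = FALSE]
      if (nrow(young_pairs) > 0L) pairs <- young_pairs
      inh <- inheritance_vs_random(net, pairs, reps = cfg$inheritance_reps,
                                   seed = cfg$seed)
      res <- list(
        inheritance = list(n_pairs = inh$n_pairs,
                           mean_shared_fraction = inh$mean_shared_fraction,
                           null_mean_shared_fraction = inh$null_mean_shared_fraction,
                           fold_over_null = inh$fold_over_null,
                           p_value = inh$p_value, null_reps = inh$null_reps,
                           seed = inh$seed),
        mechanism_composition = mechanism_composition(ages))
      for (metric in c("degree", "betweenness")) {
        t <- tryCatch(new_link_centrality_preference(net, cent, pairs, metric),
                      error = function(e) NULL)
        if (!is.null(t))
          res[[paste0("centrality_preference_", metric)]] <-
            list(observed = as.list(t$observed_counts),
                 expected = as.list(t$expected_counts),
                 statistic = t$statistic, p_value = t$p_value, test = t$test)
      }
      ap <- tryCatch(new_link_age_preference(net, ages, pairs, seed = cfg$seed),
                     error = function(e) NULL)
      if (!is.null(ap))
        res$age_preference <- list(observed = as.list(ap$observed_counts),
                                   expected = as.list(ap$expected_counts),
                                   odds_ratio = ap$odds_ratio,
                                   p_value = ap$p_value, test = ap$test,
                                   seed = ap$seed)
      res
    })
    paths$attachment <- file.path(cfg$out_dir, "attachment.json")
    jsonlite::write_json(attachment, paths$attachment, auto_unbox = TRUE,
                         digits = 10)
  }

  annotation <- NULL
  if (!is.null(cfg$inputs$essential_sources)) {
    annotation <- stage("functional_annotation", {
      sources <- lapply(cfg$inputs$essential_sources, read_annotation)
      ess <- intersect_sources(sources,
                               min_sources = min(2L, length(sources)),
                               name = "essential")
      merged <- merge(cent, ages$genes, by = "gene_id")
      by_branch <- split(merged$gene_id, merged$branch)
      deg_bin <- cut(merged$degree, breaks = c(-1, 1, 2, 3, 5, 10, 20, Inf),
                     labels = c("0-1", "2", "3", "4-5", "6-10", "11-20", ">20"))
      by_degree <- split(merged$gene_id, deg_bin)
      res <- list(
        n_essential = length(ess$genes),
        essential_by_branch = suppressWarnings(fraction_by_group(by_branch, ess)),
        essential_by_degree = suppressWarnings(fraction_by_group(by_degree, ess)),
        hub_by_branch = suppressWarnings(
          fraction_by_group(by_branch, cent$gene_id[cent$is_hub])))
      if (!is.null(cfg$inputs$categories)) {
        cats <- read_annotation(cfg$inputs$categories)
        res$hub_by_category <- hub_by_category_test(cent, cats)
      }
      res
    })
    paths$annotation <- file.path(cfg$out_dir, "annotation.json")
    jsonlite::write_json(annotation, paths$annotation, auto_unbox = TRUE,
                         digits = 10)
  }

  paths$run_log <- file.path(cfg$out_dir, "run_log.txt")
  writeLines(c(
    paste0("netage ", as.character(utils::packageVersion("netage"))),
    paste0("R ", paste(R.version$major, R.version$minor, sep = ".")),
    paste0("seed ", cfg$seed),
    paste0("config_md5 ", cfg_hash)),
    paths$run_log)

  invisible(list(network = net, ages = ages, centrality = cent,
                 profile = profile, fits = fits, attachment = attachment,
                 annotation = annotation, paths = paths, config = cfg))
}
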