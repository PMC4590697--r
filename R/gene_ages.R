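#' Packaged default branch-time tables
#'
#' Phylogenetic branch indices with their origination intervals, in millions
#' of years before present (myr), for the human and mouse lineages. Thirteen
#' branches (0..12) are defined, branch 0 being the oldest (pre-vertebrate
#' radiation) and branch 12 the species-specific branch; branches 8-12 of the
#' human table are the primate-specific period. The intervals are
#' approximate transcriptions of published divergence-time trees (the source
#' figures give them graphically, not numerically), so treat them as sensible
#' defaults, not authoritative dates: supply your own branch table for any
#' analysis where the absolute times matter.
#'
#' @param lineage `"human"` or `"mouse"`.
#' @return data.frame with columns `branch`, `start_myr`, `end_myr`.
#' @export
default_branch_table <- function(lineage = c("human", "mouse")) {
  lineage <- match.arg(lineage)
  path <- system.file("extdata", paste0(lineage, "_branches.tsv"), package = "netage",
                      mustWork = TRUE)
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Construct an age table from gene-branch and branch-definition tables
#'
#' Attaches a phylogenetic branch index to each gene and a time interval
#' `[start_myr, end_myr]` to each branch. Each branch's numeric age is the
#' interval midpoint, except the oldest branch (branch 0), whose true
#' origination time is unbounded above: by display convention it is assigned
#' a fixed sentinel age (default 500 myr). Genes may optionally carry an
#' origination-mechanism label (`dna_duplication`, `rna_duplication`,
#' `de_novo`).
#'
#' @param genes data.frame with columns `gene_id`, `branch` and optionally
#'   `mechanism`.
#' @param branches data.frame with columns `branch`, `start_myr`, `end_myr`.
#' @param branch0_sentinel numeric age (myr) reported for branch 0; a
#'   regression/display convention, not biology. Default 500.
#' @param young_branches integer branch indices defining "young" genes;
#'   default `8:12` (primate-specific branches in the human tree).
#' @return an object of class `"age_table"`: a list with elements `genes`
#'   (gene_id, branch, mechanism, age_myr), `branches` (branch, start_myr,
#'   end_myr, midpoint_myr), `young_branches`, `branch0_sentinel`.
#' @export
age_table <- function(genes, branches, branch0_sentinel = 500, young_branches = 8:12) {
  stopifnot(is.data.frame(genes), is.data.frame(branches))
  if (!all(c("gene_id", "branch") %in% names(genes)))
    stop("gene table needs columns gene_id, branch")
  if (!all(c("branch", "start_myr", "end_myr") %in% names(branches)))
    stop("branch table needs columns branch, start_myr, end_myr")
  branches$branch <- as.integer(branches$branch)
  if (anyDuplicated(branches$branch)) stop("duplicated branch index in branch table")
  if (any(branches$start_myr <= branches$end_myr))
    stop("branch intervals must satisfy start_myr > end_myr (older bound first)")
  if (any(branches$end_myr < 0)) stop("branch end_myr must be >= 0")
  branches$midpoint_myr <- (branches$start_myr + branches$end_myr) / 2
  branches$midpoint_myr[branches$branch == 0L] <- branch0_sentinel
  branches <- branches[order(branches$branch),
                       c("branch", "start_myr", "end_myr", "midpoint_myr")]

  genes$gene_id <- as.character(genes$gene_id)
  genes$branch <- suppressWarnings(as.integer(genes$branch))
  unknown <- is.na(genes$branch)
  if (any(unknown)) {
    warning(sum(unknown), " gene(s) with unknown branch excluded: ",
            paste(utils::head(genes$gene_id[unknown], 5L), collapse = ", "))
    genes <- genes[!unknown, , drop = FALSE]
  }
  undef <- setdiff(unique(genes$branch), branches$branch)
  if (length(undef) > 0L)
    stop("undefined branch ", paste(sort(undef), collapse = ", "),
         " referenced in gene table")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in gene table")
  if (!"mechanism" %in% names(genes)) genes$mechanism <- NA_character_
  genes$mechanism <- as.character(genes$mechanism)
  known_mech <- c("dna_duplication", "rna_duplication", "de_novo")
  bad_mech <- !is.na(genes$mechanism) & !(genes$mechanism %in% known_mech)
  if (any(bad_mech))
    stop("unknown mechanism label(s): ",
         paste(unique(genes$mechanism[bad_mech]), collapse = ", "))
  genes$age_myr <- branches$midpoint_myr[match(genes$branch, branches$branch)]
  genes <- genes[, c("gene_id", "branch", "mechanism", "age_myr")]
  rownames(genes) <- NULL

  if (!all(young_branches %in% branches$branch))
    stop("young_branches must be a subset of defined branches")
  structure(list(genes = genes, branches = branches,
                 young_branches = as.integer(young_branches),
                 branch0_sentinel = branch0_sentinel),
            class = "age_table")
}

#' Load an age table from TSV files
#'
#' @param gene_branch_path TSV with columns `gene_id`, `branch` and optional
#'   `mechanism`.
#' @param branch_def_path TSV with columns `branch`, `start_myr`, `end_myr`;
#'   defaults to the packaged human branch table when `NULL`.
#' @inheritParams age_table
#' @return an `"age_table"` object; see [age_table()].
#' @export
load_age_table <- function(gene_branch_path, branch_def_path = NULL,
                           branch0_sentinel = 500, young_branches = 8:12) {
  genes <- utils::read.delim(gene_branch_path, header = TRUE,
                             stringsAsFactors = FALSE)
  branches <- if (is.null(branch_def_path)) default_branch_table("human")
              else utils::read.delim(branch_def_path, header = TRUE,
                                     stringsAsFactors = FALSE)
  age_table(genes, branches, branch0_sentinel = branch0_sentinel,
            young_branches = young_branches)
}

#' @export
print.age_table <- function(x, ...) {
  cat("Gene age table: ", nrow(x$genes), " genes across ",
      nrow(x$branches), " branches (young = ",
      paste(range(x$young_branches), collapse = "-"), ")\n", sep = "")
  invisible(x)
}

#' Numeric age (myr) of genes
#'
#' Returns each gene's branch-midpoint divergence time; branch 0 returns the
#' configured sentinel age (see [age_table()]).
#'
#' @param table an `"age_table"`.
#' @param gene character vector of gene ids.
#' @return named numeric vector of ages in myr.
#' @export
assign_age_myr <- function(table, gene) {
  stopifnot(inherits(table, "age_table"))
  idx <- match(as.character(gene), table$genes$gene_id)
  if (anyNA(idx))
    stop("gene(s) not in age table: ",
         paste(utils::head(gene[is.na(idx)], 5L), collapse = ", "))
  stats::setNames(table$genes$age_myr[idx], as.character(gene))
}

#' Partition aged genes into young and old
#'
#' Young genes are those dated to the configured young branches (default
#' 8-12, the primate-specific period of the human tree); all other aged genes
#' are old. The two classes partition the aged genes exactly.
#'
#' @param table an `"age_table"`.
#' @param young_branches integer branch set; defaults to the table's own.
#' @return data.frame with columns `gene_id`, `branch`, `age_class`
#'   (factor, levels `young`, `old`).
#' @export
classify_young_old <- function(table, young_branches = NULL) {
  stopifnot(inherits(table, "age_table"))
  if (is.null(young_branches)) young_branches <- table$young_branches
  if (!all(young_branches %in% table$branches$branch))
    stop("young_branches must be a subset of defined branches")
  g <- table$genes
  cls <- ifelse(g$branch %in% young_branches, "young", "old")
  data.frame(gene_id = g$gene_id, branch = g$branch,
             age_class = factor(cls, levels = c("young", "old")),
             stringsAsFactors = FALSE)
}
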