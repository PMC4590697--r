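#' Age-stratified centrality profile
#'
#' Summarizes network centralities per phylogenetic branch, over the genes
#' that are both network members and dated: gene counts, mean degree with its
#' standard error, mean betweenness on a log scale, hub fraction, and the
#' branch's numeric age. Branches with no network genes are omitted with a
#' warning. Betweenness is summarized as `log10(mean(B) + 1)` by default
#' (log of the group average); `betweenness_log = "mean-of-log"` averages
#' `log10(B + 1)` instead — the two conventions differ for skewed
#' distributions and the choice is exposed because published "average
#' betweenness (log10)" axes rarely state which was used.
#'
#' @param cent a `"centrality_table"` (see [centrality_table()]).
#' @param ages an `"age_table"`.
#' @param betweenness_log `"log-of-mean"` (default) or `"mean-of-log"`.
#' @return data.frame of class `"age_profile"`: one row per represented
#'   branch with columns `branch`, `n_genes`, `age_myr`, `mean_degree`,
#'   `sem_degree`, `mean_betweenness_log`, `hub_fraction`.
#' @export
age_centrality_profile <- function(cent, ages,
                                   betweenness_log = c("log-of-mean", "mean-of-log")) {
  betweenness_log <- match.arg(betweenness_log)
  stopifnot(is.data.frame(cent), inherits(ages, "age_table"))
  m <- merge(cent, ages$genes, by = "gene_id")
  if (nrow(m) == 0L) stop("no network gene has an age record")
  absent <- setdiff(ages$branches$branch, unique(m$branch))
  if (length(absent) > 0L)
    warning("branch(es) with no network genes omitted: ",
            paste(absent, collapse = ", "))
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  rows <- lapply(split(m, m$branch), function(g) {
    data.frame(branch = g$branch[1L],
               n_genes = nrow(g),
               age_myr = g$age_myr[1L],
               mean_degree = mean(g$degree),
               sem_degree = sem(g$degree),
               mean_betweenness_log = if (betweenness_log == "log-of-mean")
                 log10(mean(g$betweenness) + 1) else mean(log10(g$betweenness + 1)),
               hub_fraction = if ("is_hub" %in% names(g)) mean(g$is_hub) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$branch), ]
  rownames(out) <- NULL
  if (length(unique(out$branch)) < 2L)
    warning("only one branch represented; profile regressions are not meaningful")
  class(out) <- c("age_profile", "data.frame")
  out
}

#' Fit a regression of a profile column against divergence time
#'
#' Least-squares fit of a profile quantity (e.g. `mean_degree`) against
#' `age_myr`. Models: `"polynomial"` (default degree 2 — published
#' age-centrality trends are curvilinear and a quadratic is the lowest-order
#' curve that captures the saturation), `"linear"`, and `"power"`
#' (`log10(y) ~ log10(x)`, i.e. `y = a * x^b`; requires positive values).
#'
#' @param profile an `"age_profile"` data.frame (or any data.frame with an
#'   `age_myr` column).
#' @param y name of the response column.
#' @param model `"polynomial"`, `"linear"` or `"power"`.
#' @param degree polynomial degree (default 2); ignored otherwise.
#' @return list of class `"profile_fit"`: `model`, `coefficients`,
#'   `r_squared`, `degree`, `lm_fit`.
#' @export
fit_profile_regression <- function(profile, y = "mean_degree",
                                   model = c("polynomial", "linear", "power"),
                                   degree = 2) {
  model <- match.arg(model)
  stopifnot(is.data.frame(profile), "age_myr" %in% names(profile))
  if (!y %in% names(profile)) stop("no column '", y, "' in profile")
  x <- profile$age_myr
  yy <- profile[[y]]
  ok <- stats::complete.cases(x, yy)
  x <- x[ok]; yy <- yy[ok]
  n_par <- switch(model, polynomial = degree + 1L, linear = 2L, power = 2L)
  if (length(x) < n_par + 1L)
    stop("underdetermined fit: ", length(x), " points for ", n_par, " parameters")
  if (model == "power") {
    if (any(x <= 0) || any(yy <= 0)) stop("power model requires positive x and y")
    fit <- stats::lm(log10(yy) ~ log10(x))
  } else if (model == "linear") {
    fit <- stats::lm(yy ~ x)
  } else {
    fit <- stats::lm(yy ~ stats::poly(x, degree, raw = TRUE))
  }
  r2 <- if (stats::var(yy) == 0) 0 else summary(fit)$r.squared
  structure(list(model = model, coefficients = unname(stats::coef(fit)),
                 r_squared = r2,
                 degree = if (model == "polynomial") as.integer(degree) else NA_integer_,
                 lm_fit = fit),
            class = "profile_fit")
}

#' @export
print.profile_fit <- function(x, ...) {
  cat(sprintf("%s regression: R^2 = %.4f\n", x$model, x$r_squared))
  invisible(x)
}

#' Interaction-acquisition rate per branch
#'
#' The average rate at which genes of each branch have acquired interaction
#' partners, in interactions per million years. The default `"cumulative"`
#' definition amortizes a branch's present-day mean degree over its age:
#' `rate = mean_degree / age_myr` — the interpretation behind
#' "interactions acquired per myr" axes. The `"incremental"` alternative
#' differences mean degree between adjacent branches and divides by the time
#' gap, estimating the marginal rate in each age interval (its first branch
#' falls back to the cumulative value).
#'
#' @param profile an `"age_profile"` with positive `age_myr`.
#' @param method `"cumulative"` (default) or `"incremental"`.
#' @return the profile with an added `acquisition_rate` column.
#' @export
acquisition_rate <- function(profile, method = c("cumulative", "incremental")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(profile),
            all(c("age_myr", "mean_degree") %in% names(profile)))
  if (any(profile$age_myr <= 0))
    stop("acquisition rate undefined for branch with age_myr <= 0")
  if (method == "cumulative") {
    profile$acquisition_rate <- profile$mean_degree / profile$age_myr
  } else {
    p <- profile[order(-profile$age_myr), ]
    d_deg <- c(NA, diff(p$mean_degree))
    d_age <- c(NA, -diff(p$age_myr))
    rate <- d_deg / d_age
    rate[1L] <- p$mean_degree[1L] / p$age_myr[1L]
    profile$acquisition_rate <- rate[match(profile$branch, p$branch)]
  }
  profile
}

#' Layer occupancy by age group
#'
#' For each phylogenetic branch, the percentage of its network genes falling
#' in each core/periphery layer. Rows sum to 100.
#'
#' @param cent a `"centrality_table"` with a `layer` column.
#' @param ages an `"age_table"`.
#' @return numeric matrix, branches in rows (dimnames set), layers in
#'   columns, entries in percent.
#' @export
layer_occupancy_by_age <- function(cent, ages) {
  stopifnot(is.data.frame(cent), "layer" %in% names(cent),
            inherits(ages, "age_table"))
  m <- merge(cent, ages$genes, by = "gene_id")
  if (nrow(m) == 0L) stop("no network gene has an age record")
  layers <- sort(unique(cent$layer))
  tab <- table(factor(m$branch), factor(m$layer, levels = layers))
  pct <- sweep(unclass(tab), 1L, rowSums(tab), "/") * 100
  dimnames(pct) <- list(branch = rownames(tab), layer = layers)
  pct
}

#' Expression breadth per gene
#'
#' Number of tissues in which each gene is called expressed, i.e. has a value
#' strictly greater than `threshold` (the conventional RNA-seq call being
#' FPKM > 1). For a binary expressed/not matrix (e.g. western-blot protein
#' calls coded 0/1) pass `threshold = 0`: the strict comparison then counts
#' exactly the 1 entries.
#'
#' @param expr numeric matrix, genes in rows (rownames = ids), tissues in
#'   columns.
#' @param threshold expression-call cutoff, strict comparison; default 1.0.
#' @return named integer vector, tissues expressed per gene.
#' @export
expression_breadth <- function(expr, threshold = 1.0) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix must have gene ids as rownames")
  if (threshold < 0) stop("threshold must be >= 0")
  stats::setNames(as.integer(rowSums(expr > threshold, na.rm = TRUE)), rownames(expr))
}

#' Expression breadth versus network connectivity
#'
#' Bins genes by degree, averages expression breadth per bin, and fits a
#' linear regression of mean breadth on bin degree. Default binning is one
#' bin per distinct degree value; `binning = "quantile"` uses `n_bins`
#' near-equal-occupancy degree bins instead (useful for heavy-tailed degree
#' distributions).
#'
#' @param cent a `"centrality_table"`.
#' @param breadth named integer vector from [expression_breadth()].
#' @param binning `"degree"` (default) or `"quantile"`.
#' @param n_bins number of quantile bins; default 20.
#' @return list with `profile` (data.frame: `degree`, `n_genes`,
#'   `mean_breadth`, `sem_breadth`) and `fit` (a `"profile_fit"`-like list
#'   with `coefficients`, `r_squared`, `lm_fit`).
#' @export
breadth_vs_connectivity <- function(cent, breadth, binning = c("degree", "quantile"),
                                    n_bins = 20) {
  binning <- match.arg(binning)
  stopifnot(is.data.frame(cent), "degree" %in% names(cent))
  shared <- intersect(cent$gene_id, names(breadth))
  if (length(shared) == 0L) stop("no genes shared between centrality table and breadth")
  d <- cent$degree[match(shared, cent$gene_id)]
  b <- as.numeric(breadth[shared])
  bin <- if (binning == "degree") d else {
    qs <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_bins + 1L)))
    mids <- (utils::head(qs, -1L) + utils::tail(qs, -1L)) / 2
    mids[findInterval(d, qs, rightmost.closed = TRUE, all.inside = TRUE)]
  }
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  sp <- split(b, bin)
  profile <- data.frame(degree = as.numeric(names(sp)),
                        n_genes = vapply(sp, length, 1L),
                        mean_breadth = vapply(sp, mean, 1),
                        sem_breadth = vapply(sp, sem, 1))
  rownames(profile) <- NULL
  fit <- stats::lm(mean_breadth ~ degree, data = profile)
  r2 <- if (stats::var(profile$mean_breadth) == 0) 0 else summary(fit)$r.squared
  list(profile = profile,
       fit = structure(list(model = "linear",
                            coefficients = unname(stats::coef(fit)),
                            r_squared = r2, degree = NA_integer_, lm_fit = fit),
                       class = "profile_fit"))
}
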