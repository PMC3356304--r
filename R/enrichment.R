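#' Observed MutGene overlap with a pathway
#'
#' @param sample A [sample_mutations()] object.
#' @param pathway Character vector of pathway member gene ids.
#' @return Integer count k = |MutGenes ∩ pathway|.
#' @export
observed_overlap <- function(sample, pathway) {
  stopifnot(inherits(sample, "sample_mutations"))
  sum(sample$mut_genes %in% pathway)
}

#' Empirical P value from a resampling null
#'
#' Add-one exceedance estimator `(#\{K >= k\} + 1) / (B + 1)`: the observed
#' labelling counts as one more realization of the null, so the estimate is
#' never zero and Bonferroni correction stays meaningful. `adjust = "raw"`
#' gives the plain exceedance fraction `#\{K >= k\} / B` for comparison.
#'
#' @param k Observed overlap count.
#' @param null_counts Integer vector of per-resample overlap counts K.
#' @param adjust `"add_one"` (default) or `"raw"`.
#' @return Upper-tail empirical probability.
#' @export
empirical_p <- function(k, null_counts, adjust = c("add_one", "raw")) {
  adjust <- match.arg(adjust)
  if (length(null_counts) == 0L) stop("empty null: no resample counts")
  b <- sum(null_counts >= k)
  B <- length(null_counts)
  if (adjust == "add_one") (b + 1) / (B + 1) else b / B
}

#' Upper-tail hypergeometric enrichment P value
#'
#' P(X >= k) for X ~ Hypergeometric drawing N genes from a universe of n of
#' which `pathway_size` belong to the pathway — the classical urn test that
#' assumes every gene is equally likely to be mutated.
#'
#' @param k Observed overlap.
#' @param pathway_size Universe-resident pathway size.
#' @param N Number of mutated genes in the sample.
#' @param n Universe size.
#' @return Probability in (0, 1].
#' @export
hypergeom_p <- function(k, pathway_size, N, n) {
  if (any(c(k, pathway_size, N, n) < 0)) stop("counts must be non-negative")
  if (pathway_size > n || N > n) stop("pathway_size and N must be <= n")
  if (k > min(pathway_size, N)) {
    stop("inconsistent counts: k > min(pathway_size, N)")
  }
  phyper(k - 1, pathway_size, n - pathway_size, N, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p_raw Raw P value(s) in (0, 1].
#' @param n_tests Number of tests in the family (>= 1).
#' @return `min(1, p_raw * n_tests)`, vectorised.
#' @export
bonferroni <- function(p_raw, n_tests) {
  if (any(p_raw <= 0 | p_raw > 1)) stop("p_raw must be in (0, 1]")
  if (n_tests < 1) stop("n_tests must be >= 1")
  pmin(1, p_raw * n_tests)
}

#' Per-sample pathway enrichment by three methods
#'
#' For one sample, tests every pathway for enrichment with MutGenes by (i)
#' the weighted resampling null (gene-wise mutation rates as weights), (ii)
#' the regular unweighted resampling null, and (iii) the analytic
#' hypergeometric test. Each method's raw P values are Bonferroni-corrected
#' over the pathways tested; a pathway is called significant when
#' `p_bonferroni < alpha`.
#'
#' @param sample A [sample_mutations()] object.
#' @param universe A [gene_universe()] with mutation rates set.
#' @param pathways A `pathway_collection`.
#' @param plan A [resample_plan()]; its scheme field is ignored here (both
#'   resampling schemes are always run), its `n_resamples` and `seed` apply.
#' @param methods Subset of `c("weighted", "regular", "hypergeometric")`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param adjust Empirical-P estimator, see [empirical_p()].
#' @return A data.frame with one row per (pathway, method): columns
#'   `sample`, `pathway_id`, `pathway_name`, `method`, `k`, `pathway_size`,
#'   `N`, `n`, `p_raw`, `p_bonferroni`, `significant`.
#' @export
enrich_sample <- function(sample, universe, pathways, plan,
                          methods = c("weighted", "regular", "hypergeometric"),
                          alpha = 0.05, adjust = c("add_one", "raw")) {
  stopifnot(inherits(sample, "sample_mutations"),
            inherits(universe, "gene_universe"),
            inherits(pathways, "pathway_collection"),
            inherits(plan, "resample_plan"))
  methods <- match.arg(methods, several.ok = TRUE)
  adjust <- match.arg(adjust)
  n <- length(universe$gene_ids)
  N <- sample$N
  ids <- names(pathways$sets)
  n_tests <- length(ids)
  if (n_tests == 0L) stop("no pathways to test")
  sizes <- lengths(pathways$sets)
  k <- vapply(pathways$sets, function(g) observed_overlap(sample, g), 0L)

  one_method <- function(method, p_raw) {
    data.frame(
      sample = sample$sample_id, pathway_id = ids,
      pathway_name = unname(pathways$names[ids]), method = method,
      k = unname(k), pathway_size = unname(sizes), N = N, n = n,
      p_raw = unname(p_raw),
      p_bonferroni = unname(bonferroni(p_raw, n_tests)),
      significant = unname(bonferroni(p_raw, n_tests) < alpha),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }

  res <- list()
  for (scheme in intersect(methods, c("weighted", "regular"))) {
    pl <- resample_plan(plan$n_resamples, plan$seed, scheme)
    K <- null_pathway_counts(pl, universe, pathways, N, sample$sample_id)
    p <- vapply(seq_along(ids),
                function(j) empirical_p(k[j], K[, j], adjust), 0)
    res[[scheme]] <- one_method(scheme, p)
  }
  if ("hypergeometric" %in% methods) {
    p <- vapply(seq_along(ids),
                function(j) hypergeom_p(k[j], sizes[j], N, n), 0)
    res$hypergeometric <- one_method("hypergeometric", p)
  }
  out <- do.call(rbind, res[intersect(methods, names(res))])
  row.names(out) <- NULL
  out
}

#' Cohort-wide enrichment
#'
#' Applies [enrich_sample()] to every sample and binds the results.
#'
#' @param samples Named list of [sample_mutations()] (as returned by
#'   [read_mutations()]).
#' @inheritParams enrich_sample
#' @return A data.frame, rows stacked over samples.
#' @export
enrich_cohort <- function(samples, universe, pathways, plan,
                          methods = c("weighted", "regular", "hypergeometric"),
                          alpha = 0.05, adjust = c("add_one", "raw")) {
  res <- lapply(samples, enrich_sample, universe = universe,
                pathways = pathways, plan = plan, methods = methods,
                alpha = alpha, adjust = adjust)
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}
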