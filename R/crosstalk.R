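#' Jaccard coefficient of two gene sets
#'
#' `|U ∩ V| / |U ∪ V|`; defined as 0 (with a warning) when both sets are
#' empty, which can arise in degenerate resamples.
#'
#' @param U,V Character vectors of gene ids.
#' @return Coefficient in `[0, 1]`.
#' @export
jaccard <- function(U, V) {
  U <- unique(U); V <- unique(V)
  un <- length(union(U, V))
  if (un == 0L) {
    warning("jaccard of two empty sets: defined as 0", call. = FALSE)
    return(0)
  }
  length(intersect(U, V)) / un
}

#' Per-sample pathway crosstalk between enriched pathways
#'
#' For every unordered pair of pathways significant in the sample, scores
#' the overlap of their mutated members by the Jaccard coefficient
#' `JC = |U ∩ V| / |U ∪ V|` with U, V the per-pathway MutGene sets, and
#' computes an empirical P value against the weighted resampling null:
#' `p_emp = (#\{π : JC(π) >= JC_obs\} + 1) / (B + 1)`, where JC(π) is the
#' coefficient recomputed on the π-th weighted resample. The same draws used
#' for enrichment (same seed sub-stream) are reused. Edges with
#' `p_emp < alpha` are flagged; the threshold is nominal — in practice
#' Bonferroni-corrected crosstalk P values are rarely significant, so
#' nominal selection is the default reporting rule.
#'
#' With `jc_on = "full"` the coefficient is instead computed on the full
#' pathway memberships (a static quantity, reported without a null).
#'
#' @param sample A [sample_mutations()] object.
#' @param significant_pathways Character vector of pathway ids significant
#'   in this sample (typically from [enrich_sample()], weighted method).
#' @param universe A [gene_universe()] with mutation rates set.
#' @param pathways A `pathway_collection`.
#' @param plan A [resample_plan()] (the weighted scheme is used).
#' @param alpha Nominal significance level for edge flagging (default 0.05).
#' @param jc_on `"mutated"` (default) or `"full"`.
#' @return A data.frame with one row per pathway pair: `sample`,
#'   `pathway_a`, `pathway_b`, `n_shared_mut_genes`, `jc`, `p_emp`,
#'   `significant`. Zero rows (with a message) if fewer than two pathways
#'   are supplied.
#' @export
crosstalk_sample <- function(sample, significant_pathways, universe,
                             pathways, plan, alpha = 0.05,
                             jc_on = c("mutated", "full")) {
  stopifnot(inherits(sample, "sample_mutations"),
            inherits(universe, "gene_universe"),
            inherits(pathways, "pathway_collection"),
            inherits(plan, "resample_plan"))
  jc_on <- match.arg(jc_on)
  ids <- intersect(significant_pathways, names(pathways$sets))
  empty <- data.frame(
    sample = character(), pathway_a = character(), pathway_b = character(),
    n_shared_mut_genes = integer(), jc = numeric(), p_emp = numeric(),
    significant = logical(), stringsAsFactors = FALSE
  )
  if (length(ids) < 2L) {
    message("sample ", sample$sample_id,
            ": fewer than 2 significant pathways, no crosstalk computed")
    return(empty)
  }
  pairs <- combn(ids, 2L)

  if (jc_on == "full") {
    rows <- apply(pairs, 2L, function(pr) {
      A <- pathways$sets[[pr[1]]]; B <- pathways$sets[[pr[2]]]
      data.frame(sample = sample$sample_id, pathway_a = pr[1],
                 pathway_b = pr[2],
                 n_shared_mut_genes = length(intersect(
                   intersect(sample$mut_genes, A),
                   intersect(sample$mut_genes, B))),
                 jc = jaccard(A, B), p_emp = NA_real_, significant = NA,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    row.names(out) <- NULL
    return(out)
  }

  # Weighted resamples shared with enrichment (same sub-stream).
  wplan <- resample_plan(plan$n_resamples, plan$seed, "weighted")
  draws <- resample_draws(universe, sample$N, wplan, sample$sample_id)
  B <- nrow(draws)

  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    A <- pathways$sets[[a]]; Bset <- pathways$sets[[b]]
    mutA <- intersect(sample$mut_genes, A)
    mutB <- intersect(sample$mut_genes, Bset)
    shared <- intersect(mutA, mutB)
    jc_obs <- if (length(mutA) + length(mutB) == 0L) 0 else jaccard(mutA, mutB)
    # For resample MutGene sets D: U = D ∩ A, V = D ∩ B, so
    # |U ∩ V| = |D ∩ (A ∩ B)| and |U ∪ V| = |D ∩ (A ∪ B)|: two overlap
    # counts per draw suffice.
    cts <- counts_from_draws(draws, universe,
                             list(both = intersect(A, Bset),
                                  either = union(A, Bset)))
    jc_null <- ifelse(cts[, "either"] == 0L, 0, cts[, "both"] / cts[, "either"])
    p_emp <- (sum(jc_null >= jc_obs) + 1) / (B + 1)
    rows[[j]] <- data.frame(
      sample = sample$sample_id, pathway_a = a, pathway_b = b,
      n_shared_mut_genes = length(shared), jc = jc_obs, p_emp = p_emp,
      significant = p_emp < alpha, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Cohort-wide crosstalk
#'
#' Runs [crosstalk_sample()] for every sample using that sample's
#' significant pathways under the weighted method.
#'
#' @param samples Named list of [sample_mutations()].
#' @param enrichment Data.frame from [enrich_cohort()].
#' @inheritParams crosstalk_sample
#' @param method Enrichment method whose significant calls define the nodes
#'   (default `"weighted"`).
#' @return Stacked edge data.frame.
#' @export
crosstalk_cohort <- function(samples, enrichment, universe, pathways, plan,
                             alpha = 0.05, method = "weighted",
                             jc_on = c("mutated", "full")) {
  jc_on <- match.arg(jc_on)
  res <- lapply(samples, function(s) {
    sig <- enrichment$pathway_id[enrichment$sample == s$sample_id &
                                   enrichment$method == method &
                                   enrichment$significant]
    crosstalk_sample(s, sig, universe, pathways, plan, alpha, jc_on)
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}
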