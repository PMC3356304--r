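#' Binary pathway-by-sample significance profile
#'
#' Each pathway's mutation status per sample is a binary indicator: 1 if the
#' pathway is significantly enriched (weighted method, Bonferroni < alpha)
#' in that sample, else 0. Only pathways significant in at least one sample
#' are kept as rows, and only samples with at least one significant pathway
#' are kept as columns — indicator patterns in never-significant pathways
#' could arise by chance and would dilute the map.
#'
#' @param enrichment Data.frame from [enrich_cohort()].
#' @param method Method whose significance calls are used (default
#'   `"weighted"`).
#' @param keep_all_samples Keep samples without any significant pathway as
#'   all-zero columns (default FALSE).
#' @return Binary integer matrix, pathways x samples. Zero rows (with a
#'   message) when nothing is significant anywhere.
#' @export
build_profile <- function(enrichment, method = "weighted",
                          keep_all_samples = FALSE) {
  e <- enrichment[enrichment$method == method, , drop = FALSE]
  if (nrow(e) == 0L) stop("no enrichment rows for method '", method, "'")
  samples <- unique(e$sample)
  pw <- unique(e$pathway_id[e$significant])
  if (length(pw) == 0L) {
    message("no pathway significant in any sample: empty profile")
    return(matrix(0L, nrow = 0L, ncol = length(samples),
                  dimnames = list(NULL, samples)))
  }
  prof <- matrix(0L, nrow = length(pw), ncol = length(samples),
                 dimnames = list(pw, samples))
  sig <- e[e$significant & e$pathway_id %in% pw, c("pathway_id", "sample")]
  prof[cbind(sig$pathway_id, sig$sample)] <- 1L
  if (!keep_all_samples) {
    prof <- prof[, colSums(prof) > 0L, drop = FALSE]
  }
  prof
}

#' Fisher's exact test on a pathway co-occurrence table
#'
#' Two-sided exact test on the 2x2 table (a: both pathways significant in a
#' sample, b: A only, c: B only, d: neither), summing the hypergeometric
#' probabilities of all tables with fixed margins that are as or less
#' probable than the observed one. Degenerate margins (an all-zero row or
#' column) admit a single table, so P = 1 by convention (with a warning).
#'
#' @param table 2x2 matrix or length-4 vector `c(a, b, c, d)` of
#'   non-negative integer counts.
#' @param alternative Passed to [stats::fisher.test()]; `"two.sided"`
#'   (default) or `"greater"` for pure co-occurrence.
#' @return Exact P value.
#' @export
fisher_cooccurrence <- function(table, alternative = "two.sided") {
  if (is.matrix(table)) table <- as.vector(t(table))
  if (length(table) != 4L || any(table < 0) || any(table != round(table))) {
    stop("'table' must be 4 non-negative integer counts (a, b, c, d)")
  }
  m <- matrix(as.integer(table), 2L, 2L, byrow = TRUE)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    warning("degenerate margin in 2x2 table: P = 1 by convention",
            call. = FALSE)
    return(1)
  }
  fisher.test(m, alternative = alternative)$p.value
}

#' Cross-sample co-mutation pathway map
#'
#' Evaluates every unordered pair of profile pathways: counts the four
#' co-occurrence categories over samples, tests association by Fisher's
#' exact test, and retains an edge when the pair is co-significant in at
#' least `min_cooccur` samples and `p_fisher < alpha` (nominal).
#'
#' @param profile Binary matrix from [build_profile()].
#' @param min_cooccur Minimum number of samples in which both pathways are
#'   significant (default 2).
#' @param alpha Significance level on the Fisher P (default 0.05).
#' @param alternative Sidedness of the Fisher test (default two-sided; use
#'   `"greater"` to test co-occurrence only).
#' @return Data.frame with one row per pair: `pathway_a`, `pathway_b`, `a`,
#'   `b`, `c`, `d`, `n_cooccur`, `p_fisher`, `retained`.
#' @export
comutation_map <- function(profile, min_cooccur = 2L, alpha = 0.05,
                           alternative = "two.sided") {
  if (nrow(profile) < 2L) {
    message("fewer than 2 profile pathways: no co-mutation pairs")
    return(data.frame(pathway_a = character(), pathway_b = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), n_cooccur = integer(),
                      p_fisher = numeric(), retained = logical(),
                      stringsAsFactors = FALSE))
  }
  pairs <- combn(rownames(profile), 2L)
  n_samples <- ncol(profile)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    pa <- pairs[1, j]; pb <- pairs[2, j]
    x <- profile[pa, ]; y <- profile[pb, ]
    a <- sum(x == 1L & y == 1L)
    b <- sum(x == 1L & y == 0L)
    cc <- sum(x == 0L & y == 1L)
    d <- sum(x == 0L & y == 0L)
    p <- suppressWarnings(fisher_cooccurrence(c(a, b, cc, d), alternative))
    rows[[j]] <- data.frame(
      pathway_a = pa, pathway_b = pb, a = a, b = b, c = cc, d = d,
      n_cooccur = a, p_fisher = p,
      retained = (a >= min_cooccur && p < alpha),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  stopifnot(all(out$a + out$b + out$c + out$d == n_samples))
  row.names(out) <- NULL
  out
}
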