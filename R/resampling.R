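#' Describe a resampling null
#'
#' @param n_resamples Number of label randomizations B (default 10000).
#' @param seed Base RNG seed; per-sample sub-streams are derived
#'   deterministically from `(seed, sample_id)`.
#' @param scheme `"weighted"` (gene-wise mutation rates as selection
#'   weights) or `"regular"` (every gene equally likely).
#' @return A `resample_plan` list.
#' @export
resample_plan <- function(n_resamples = 10000L, seed = 1L,
                          scheme = c("weighted", "regular")) {
  scheme <- match.arg(scheme)
  n_resamples <- as.integer(n_resamples)
  if (is.na(n_resamples) || n_resamples < 1L) stop("n_resamples must be >= 1")
  structure(list(n_resamples = n_resamples, seed = as.integer(seed),
                 scheme = scheme),
            class = "resample_plan")
}

#' One uniform (regular) resample of N MutGene labels
#'
#' Every gene has the same chance of selection: the null shared by the
#' hypergeometric test.
#'
#' @param universe A [gene_universe()].
#' @param N Number of labels to place, `1 <= N <= n`.
#' @return Character vector of N gene ids.
#' @export
draw_regular <- function(universe, N) {
  stopifnot(inherits(universe, "gene_universe"))
  n <- length(universe$gene_ids)
  N <- as.integer(N)
  if (is.na(N) || N < 1L || N > n) stop("N must be in [1, ", n, "]")
  universe$gene_ids[as.integer(cpp_regular_draws(n, N, 1L))]
}

#' One weighted resample of N MutGene labels
#'
#' Weighted sampling without replacement with the gene-wise mutation rates
#' m_i as weights: per gene draw u_i ~ Uniform(0,1), form the key
#' u_i^(1/m_i), and assign the N largest keys as MutGenes. Genes with larger
#' m_i (longer genes) have keys stochastically closer to 1, so each resample
#' reproduces the gene-length pattern of real mutated-gene sets. For a
#' two-gene universe and N = 1, P(gene a selected) = m_a / (m_a + m_b).
#'
#' @param universe A [gene_universe()] with mutation rates set (see
#'   [set_mu()]); all m_i must be strictly positive.
#' @param N Number of labels to place, `1 <= N <= n`.
#' @return Character vector of N gene ids.
#' @export
draw_weighted <- function(universe, N) {
  stopifnot(inherits(universe, "gene_universe"))
  if (is.null(universe$mutation_rates)) {
    stop("universe has no mutation rates; call set_mu() first")
  }
  n <- length(universe$gene_ids)
  N <- as.integer(N)
  if (is.na(N) || N < 1L || N > n) stop("N must be in [1, ", n, "]")
  universe$gene_ids[as.integer(cpp_weighted_draws(universe$mutation_rates, N, 1L))]
}

# Bulk draw matrix (B x N, 1-based gene indices) under a plan, seeded by the
# per-sample sub-stream. Shared by enrichment and crosstalk so both stages
# see the same randomizations for a given sample.
resample_draws <- function(universe, N, plan, sample_id = "global") {
  stopifnot(inherits(universe, "gene_universe"),
            inherits(plan, "resample_plan"))
  n <- length(universe$gene_ids)
  N <- as.integer(N)
  if (is.na(N) || N < 1L || N > n) stop("N must be in [1, ", n, "]")
  sub <- derive_seed(plan$seed, paste0(sample_id, ":", plan$scheme))
  with_seed(sub, {
    if (plan$scheme == "weighted") {
      if (is.null(universe$mutation_rates)) {
        stop("universe has no mutation rates; call set_mu() first")
      }
      cpp_weighted_draws(universe$mutation_rates, N, plan$n_resamples)
    } else {
      cpp_regular_draws(n, N, plan$n_resamples)
    }
  })
}

#' Null pathway-overlap counts across resamples
#'
#' Runs the resampling plan once and, for each pathway, records the number
#' K of resampled MutGenes falling in the pathway in each randomization —
#' the background distribution against which observed overlaps are scored.
#'
#' @param plan A [resample_plan()].
#' @param universe A [gene_universe()].
#' @param pathways A `pathway_collection` (see [read_gmt()]).
#' @param N Number of MutGene labels per resample.
#' @param sample_id Identifier selecting the RNG sub-stream (default
#'   `"global"`).
#' @return Integer matrix, `n_resamples` rows x one column per pathway.
#' @export
null_pathway_counts <- function(plan, universe, pathways, N,
                                sample_id = "global") {
  stopifnot(inherits(pathways, "pathway_collection"))
  draws <- resample_draws(universe, N, plan, sample_id)
  counts_from_draws(draws, universe, pathways$sets)
}

# Overlap counts of each draw with each member set (list of gene ids).
counts_from_draws <- function(draws, universe, sets) {
  out <- vapply(sets, function(g) {
    member <- universe$gene_ids %in% g
    as.integer(cpp_overlap_counts(draws, member))
  }, integer(nrow(draws)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(draws))
  colnames(out) <- names(sets)
  out
}
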