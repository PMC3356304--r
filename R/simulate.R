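#' Simulation configuration
#'
#' Describes a synthetic cohort generated under the uniform per-nucleotide
#' mutation model: each gene mutates independently with probability
#' `m_i = 1 - exp(-mu * l_i)`. Driver pathways multiply their member genes'
#' mutation probabilities in the samples where they are planted; a decoy
#' pathway is drawn from the longest length decile with no boost, so any
#' apparent enrichment it shows is pure length bias.
#'
#' @param n_genes Universe size (default 1000).
#' @param length_range Log-uniform gene-length range in nt (default
#'   `c(500, 50000)`, median ~5 kb — typical of exome-scale gene spans).
#' @param mu Background mutation rate per nucleotide (default 2.7e-6, a
#'   rate reported for lung adenocarcinoma panels).
#' @param n_samples Number of samples (default 30).
#' @param drivers List of driver specs, each a list with `id`, `n_genes`
#'   (members), `multiplier` (>= 1, applied to m_i), and optional
#'   `sample_idx` (integer vector of samples where the driver is active;
#'   default all).
#' @param decoy Either NULL or a list with `id` and `n_genes`: a pathway of
#'   genes sampled from the longest length decile, never boosted.
#' @param n_random_pathways,random_pathway_size Background pathways of
#'   uniformly sampled genes (defaults 30 pathways of 30 genes) so that
#'   multiple-testing correction operates at a realistic family size.
#' @param seed RNG seed for cohort generation.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000L,
                              length_range = c(500, 50000),
                              mu = 2.7e-6,
                              n_samples = 30L,
                              drivers = list(),
                              decoy = NULL,
                              n_random_pathways = 30L,
                              random_pathway_size = 30L,
                              seed = 1L) {
  stopifnot(n_genes >= 10L, length(length_range) == 2L,
            length_range[1] > 0, length_range[2] > length_range[1],
            mu > 0, n_samples >= 1L)
  for (d in drivers) {
    if (is.null(d$id) || is.null(d$n_genes) || is.null(d$multiplier)) {
      stop("each driver needs 'id', 'n_genes' and 'multiplier'")
    }
    if (d$multiplier < 1) stop("driver multipliers must be >= 1")
  }
  structure(
    list(n_genes = as.integer(n_genes), length_range = length_range,
         mu = mu, n_samples = as.integer(n_samples), drivers = drivers,
         decoy = decoy, n_random_pathways = as.integer(n_random_pathways),
         random_pathway_size = as.integer(random_pathway_size),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate one sample under the null mutation model
#'
#' Every gene mutates independently with its gene-wise probability
#' `m_i = 1 - exp(-mu * l_i)` (the Bernoulli-per-gene form of a uniform
#' per-nucleotide process; see also `per_nucleotide` for the direct
#' position-wise simulation, equivalent by construction of m_i). Samples
#' with zero mutated genes are redrawn (and the redraw count recorded), so
#' N >= 1 always holds.
#'
#' @param universe A [gene_universe()] with mutation rates set.
#' @param sample_id Identifier for the resulting sample.
#' @param boost Optional named numeric vector of per-gene probability
#'   multipliers (names are gene ids); resulting probabilities must stay
#'   below 1.
#' @param per_nucleotide If TRUE, simulate each gene as `l_i` independent
#'   per-position Bernoulli(mu) trials via a Binomial draw instead of the
#'   collapsed per-gene Bernoulli (slower; used to cross-validate the
#'   equivalence).
#' @return A [sample_mutations()] object with attribute `redraws`.
#' @export
simulate_null_sample <- function(universe, sample_id = "sim",
                                 boost = NULL, per_nucleotide = FALSE) {
  stopifnot(inherits(universe, "gene_universe"))
  if (is.null(universe$mutation_rates) || all(universe$mutation_rates == 0)) {
    stop("universe has no positive mutation rates (mu = 0?)")
  }
  m <- universe$mutation_rates
  if (!is.null(boost)) {
    idx <- match(names(boost), universe$gene_ids)
    if (anyNA(idx)) stop("boost names must be universe gene ids")
    m[idx] <- m[idx] * boost
    if (any(m >= 1)) {
      stop("boost pushes a gene's mutation probability to >= 1")
    }
  }
  n <- length(m)
  redraws <- 0L
  repeat {
    if (per_nucleotide) {
      hits <- rbinom(n, size = round(universe$lengths), prob = universe$mu)
      if (!is.null(boost)) {
        # boosted genes keep the collapsed form; the per-position mode is a
        # null-model cross-check
        hits[idx] <- rbinom(length(idx), 1L, m[idx])
      }
      mut <- hits > 0L
    } else {
      mut <- runif(n) < m
    }
    if (any(mut)) break
    redraws <- redraws + 1L
  }
  out <- sample_mutations(sample_id, universe$gene_ids[mut], universe)
  attr(out, "redraws") <- redraws
  out
}

#' Simulate a full cohort with planted signal
#'
#' Generates a gene universe with log-uniformly distributed lengths, a
#' pathway collection (driver pathways from mid-length genes, an optional
#' long-gene decoy, and random background pathways), and per-sample mutated
#' gene lists. Driver members' mutation probabilities are multiplied in the
#' samples where the driver is planted; the decoy is never boosted.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, writes `lengths.tsv`,
#'   `pathways.gmt`, `mutations.tsv` and `provenance.yaml` there.
#' @return List with `universe`, `pathways` (a `pathway_collection`),
#'   `samples` (named list of [sample_mutations()]), `truth` (driver/decoy
#'   membership and planting), and `files` (paths, if written).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    lr <- log(config$length_range)
    lens <- round(exp(runif(config$n_genes, lr[1], lr[2])))
    ids <- sprintf("g%04d", seq_len(config$n_genes))
    universe <- gene_universe(ids, lens, mu = config$mu)

    # drivers drawn from the middle length deciles so their detection is not
    # a length artefact; decoy from the top decile
    ord <- order(lens)
    n <- config$n_genes
    mid_pool <- ids[ord[ceiling(0.3 * n):floor(0.7 * n)]]
    long_pool <- ids[ord[(floor(0.9 * n) + 1):n]]

    sets <- list()
    truth <- list(drivers = list(), decoy = NULL)
    used <- character()
    for (d in config$drivers) {
      pool <- setdiff(mid_pool, used)
      if (length(pool) < d$n_genes) stop("not enough mid-length genes for drivers")
      memb <- sample(pool, d$n_genes)
      used <- c(used, memb)
      sets[[d$id]] <- memb
      sample_idx <- if (is.null(d$sample_idx)) seq_len(config$n_samples)
                    else as.integer(d$sample_idx)
      truth$drivers[[d$id]] <- list(members = memb,
                                    multiplier = d$multiplier,
                                    sample_idx = sample_idx)
    }
    if (!is.null(config$decoy)) {
      if (length(long_pool) < config$decoy$n_genes) {
        stop("not enough long genes for the decoy pathway")
      }
      memb <- sample(long_pool, config$decoy$n_genes)
      sets[[config$decoy$id]] <- memb
      truth$decoy <- list(id = config$decoy$id, members = memb)
    }
    for (j in seq_len(config$n_random_pathways)) {
      sets[[sprintf("rand%03d", j)]] <- sample(ids, config$random_pathway_size)
    }
    pathways <- pathway_collection(
      sets, universe = universe,
      min_size = min(lengths(sets)), max_size = max(lengths(sets))
    )

    samples <- vector("list", config$n_samples)
    sample_ids <- sprintf("s%03d", seq_len(config$n_samples))
    for (s in seq_len(config$n_samples)) {
      boost <- numeric()
      for (d in truth$drivers) {
        if (s %in% d$sample_idx) {
          boost <- c(boost, setNames(rep(d$multiplier, length(d$members)),
                                     d$members))
        }
      }
      samples[[s]] <- suppressWarnings(simulate_null_sample(
        universe, sample_ids[s],
        boost = if (length(boost)) boost else NULL
      ))
    }
    names(samples) <- sample_ids

    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(
        lengths = file.path(out_dir, "lengths.tsv"),
        gmt = file.path(out_dir, "pathways.gmt"),
        mutations = file.path(out_dir, "mutations.tsv"),
        provenance = file.path(out_dir, "provenance.yaml")
      )
      write_gene_lengths(universe, files$lengths)
      write_gmt(pathways, files$gmt)
      mut <- do.call(rbind, lapply(samples, function(sm) {
        data.frame(sample = sm$sample_id, gene = sm$mut_genes,
                   stringsAsFactors = FALSE)
      }))
      write.table(mut, files$mutations, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      yaml::write_yaml(
        list(generator = "pathweigh::simulate_cohort",
             seed = config$seed, mu = config$mu,
             n_genes = config$n_genes, n_samples = config$n_samples,
             length_range = as.numeric(config$length_range),
             drivers = lapply(truth$drivers, function(d) {
               list(multiplier = d$multiplier,
                    n_genes = length(d$members),
                    sample_idx = as.integer(d$sample_idx))
             }),
             decoy = if (is.null(truth$decoy)) NULL else
               list(id = truth$decoy$id, n_genes = length(truth$decoy$members))),
        files$provenance
      )
    }
    list(universe = universe, pathways = pathways, samples = samples,
         truth = truth, files = files)
  })
}
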