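#' Run the full analysis pipeline
#'
#' Reads the three standard inputs, runs per-sample enrichment by all three
#' methods, per-sample crosstalk among weighted-significant pathways, and
#' the cross-sample co-mutation map, and writes plain-text result tables
#' plus a machine-readable run manifest.
#'
#' @param lengths Path to the gene-length TSV (gene, length).
#' @param gmt Path to the GMT pathway file.
#' @param mutations Path to the mutation TSV (sample, gene).
#' @param out_dir Output directory (created if needed).
#' @param mu Background mutation rate per nucleotide: a single number, or a
#'   named vector keyed by sample id (per-sample rates; a name `".default"`
#'   supplies the fallback).
#' @param min_mut_genes Minimum universe-resident MutGenes per sample
#'   (default 10).
#' @param min_size,max_size Pathway size bounds (defaults 10 and 500).
#' @param n_resamples Number of resamples B (default 10000).
#' @param seed Base RNG seed (default 1).
#' @param alpha Significance level (default 0.05).
#' @param methods Enrichment methods to run.
#' @param adjust Empirical-P estimator, see [empirical_p()].
#' @return Invisibly, a list with `enrichment`, `crosstalk`, `profile`,
#'   `comutation`, `manifest` and the output file paths.
#' @export
run_all <- function(lengths, gmt, mutations, out_dir,
                    mu, min_mut_genes = 10L,
                    min_size = 10L, max_size = 500L,
                    n_resamples = 10000L, seed = 1L, alpha = 0.05,
                    methods = c("weighted", "regular", "hypergeometric"),
                    adjust = c("add_one", "raw")) {
  adjust <- match.arg(adjust)
  for (p in c(lengths, gmt, mutations)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  universe0 <- read_gene_lengths(lengths)
  # sample and pathway filtering depend only on universe membership, not mu
  samples <- read_mutations(mutations, universe0, min_mut_genes = min_mut_genes)
  pathways <- read_gmt(gmt, universe0, min_size = min_size, max_size = max_size)
  mu_for <- function(sample_id) {
    if (is.null(names(mu))) return(unname(mu[1]))
    if (sample_id %in% names(mu)) return(unname(mu[[sample_id]]))
    if (".default" %in% names(mu)) return(unname(mu[[".default"]]))
    stop("no mu for sample ", sample_id, " and no '.default' entry")
  }
  universe_for <- function(sample_id) set_mu(universe0, mu_for(sample_id))
  plan <- resample_plan(n_resamples, seed, "weighted")

  enr <- do.call(rbind, lapply(samples, function(s) {
    enrich_sample(s, universe_for(s$sample_id), pathways, plan,
                  methods = methods, alpha = alpha, adjust = adjust)
  }))
  row.names(enr) <- NULL

  ct <- do.call(rbind, lapply(samples, function(s) {
    sig <- enr$pathway_id[enr$sample == s$sample_id &
                            enr$method == "weighted" & enr$significant]
    crosstalk_sample(s, sig, universe_for(s$sample_id), pathways, plan,
                     alpha = alpha)
  }))
  row.names(ct) <- NULL

  prof <- build_profile(enr, method = "weighted")
  cm <- comutation_map(prof, min_cooccur = 2L, alpha = alpha)

  files <- list(
    enrichment = file.path(out_dir, "enrichment.tsv"),
    crosstalk = file.path(out_dir, "crosstalk.tsv"),
    crosstalk_sif = file.path(out_dir, "crosstalk.sif"),
    profile = file.path(out_dir, "comutation_profile.tsv"),
    comutation = file.path(out_dir, "comutation_edges.tsv"),
    comutation_sif = file.path(out_dir, "comutation.sif"),
    incidence = file.path(out_dir, "gene_pathway_incidence.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(enr, files$enrichment)
  write_tsv(ct, files$crosstalk)
  writeLines(if (nrow(ct)) {
    sig <- ct[ct$significant %in% TRUE, , drop = FALSE]
    sprintf("%s\tcrosstalk(%s)\t%s", sig$pathway_a, sig$sample, sig$pathway_b)
  } else character(), files$crosstalk_sif)
  write_tsv(data.frame(pathway_id = rownames(prof), prof,
                       check.names = FALSE, stringsAsFactors = FALSE),
            files$profile)
  write_tsv(cm, files$comutation)
  writeLines(if (nrow(cm)) {
    ret <- cm[cm$retained, , drop = FALSE]
    sprintf("%s\tcomutation\t%s", ret$pathway_a, ret$pathway_b)
  } else character(), files$comutation_sif)
  write_tsv(gene_pathway_incidence(samples, pathways), files$incidence)

  manifest <- list(
    inputs = list(lengths = normalizePath(lengths), gmt = normalizePath(gmt),
                  mutations = normalizePath(mutations),
                  md5 = list(lengths = unname(tools::md5sum(lengths)),
                             gmt = unname(tools::md5sum(gmt)),
                             mutations = unname(tools::md5sum(mutations)))),
    parameters = list(mu = as.list(mu), min_mut_genes = min_mut_genes,
                      min_size = min_size, max_size = max_size,
                      n_resamples = as.integer(n_resamples),
                      seed = as.integer(seed), alpha = alpha,
                      methods = methods, adjust = adjust),
    counts = list(
      universe_genes = length(universe0$gene_ids),
      pathways_tested = length(pathways$sets),
      pathways_dropped = nrow(pathways$dropped),
      samples_retained = length(samples),
      samples_dropped = length(attr(samples, "dropped_samples")),
      off_universe_mutations = attr(samples, "n_off_universe"),
      significant_calls = sum(enr$significant),
      crosstalk_edges = if (nrow(ct)) sum(ct$significant) else 0L,
      comutation_edges_retained = if (nrow(cm)) sum(cm$retained) else 0L
    ),
    versions = list(pathweigh = as.character(utils::packageVersion("pathweigh")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  yaml::write_yaml(manifest, files$manifest)

  invisible(list(enrichment = enr, crosstalk = ct, profile = prof,
                 comutation = cm, manifest = manifest, files = files))
}

#' Mutated-gene by pathway incidence table
#'
#' One row per (sample, gene, pathway) triple where the gene is mutated in
#' the sample and belongs to the pathway — the flat form of the
#' gene-by-pathway membership panel used to inspect crosstalk drivers
#' ("hot" genes shared by many pathways).
#'
#' @param samples Named list of [sample_mutations()].
#' @param pathways A `pathway_collection`.
#' @return Data.frame with columns `sample`, `gene`, `pathway_id`.
#' @export
gene_pathway_incidence <- function(samples, pathways) {
  rows <- list()
  for (sm in samples) {
    for (pid in names(pathways$sets)) {
      hit <- intersect(sm$mut_genes, pathways$sets[[pid]])
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sm$sample_id, gene = hit, pathway_id = pid,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(sample = character(), gene = character(),
                      pathway_id = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
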