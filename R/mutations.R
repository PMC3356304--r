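#' Construct per-sample mutated-gene sets
#'
#' A sample's MutGenes are the genes carrying at least one (non-silent)
#' somatic mutation. Labels y_i over the universe are implied: 1 for
#' MutGenes, 0 otherwise; N = |MutGenes|.
#'
#' @param sample_id Sample identifier.
#' @param mut_genes Character vector of mutated gene ids (deduplicated).
#' @param universe A [gene_universe()]; genes outside it are dropped with a
#'   warning (a gene without a length has no resampling weight).
#' @return A `sample_mutations` object: list with `sample_id`, `mut_genes`,
#'   `N`, `n_dropped` (off-universe genes removed).
#' @export
sample_mutations <- function(sample_id, mut_genes, universe) {
  stopifnot(inherits(universe, "gene_universe"))
  mut_genes <- unique(as.character(mut_genes))
  off <- setdiff(mut_genes, universe$gene_ids)
  if (length(off)) {
    warning("sample ", sample_id, ": dropping ", length(off),
            " mutated gene(s) absent from the universe", call. = FALSE)
    mut_genes <- setdiff(mut_genes, off)
  }
  if (length(mut_genes) == 0L) {
    stop("sample ", sample_id, " has no universe-resident mutated genes")
  }
  structure(
    list(sample_id = as.character(sample_id), mut_genes = mut_genes,
         N = length(mut_genes), n_dropped = length(off)),
    class = "sample_mutations"
  )
}

#' @export
print.sample_mutations <- function(x, ...) {
  cat("sample_mutations:", x$sample_id, "- N =", x$N, "MutGenes\n")
  invisible(x)
}

#' Read per-sample mutated-gene lists from a two-column table
#'
#' Expects a tab-separated file with columns sample id and gene id (a header
#' line is detected automatically). Duplicate (sample, gene) rows collapse
#' to one MutGene. Samples with fewer than `min_mut_genes` universe-resident
#' MutGenes are dropped: small mutated-gene lists give the enrichment test
#' no power (the lung cohort used a cutoff of 10, the glioblastoma cohort 5).
#'
#' @param path Path to the mutation TSV.
#' @param universe A [gene_universe()].
#' @param min_mut_genes Minimum number of distinct universe-resident mutated
#'   genes for a sample to be retained (default 10).
#' @return Named list of [sample_mutations()] objects, with attributes
#'   `dropped_samples` (character vector) and `n_off_universe` (count of
#'   discarded off-universe gene occurrences).
#' @export
read_mutations <- function(path, universe, min_mut_genes = 10L) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!file.exists(path)) stop("mutation file not found: ", path)
  tab <- tryCatch(
    read.delim(path, header = FALSE, colClasses = "character",
               stringsAsFactors = FALSE, comment.char = "#",
               blank.lines.skip = TRUE),
    error = function(e) stop("no rows in mutation file ", path)
  )
  if (nrow(tab) == 0L) stop("no rows in mutation file ", path)
  if (ncol(tab) < 2L) stop("mutation file needs >= 2 columns (sample, gene)")
  if (identical(tolower(tab[1, 1]), "sample") ||
      identical(tolower(tab[1, 2]), "gene")) {
    tab <- tab[-1, , drop = FALSE]
  }
  mutations_from_pairs(tab[[1]], tab[[2]], universe, min_mut_genes)
}

#' Read (sample, gene) pairs from a MAF-like table
#'
#' Uses the columns `Tumor_Sample_Barcode`, `Hugo_Symbol` and (if present)
#' `Variant_Classification`; variants whose classification is in
#' `silent_classes` are excluded before collapsing to (sample, gene) pairs.
#'
#' @param path Path to a tab-separated MAF-like file with a header.
#' @param universe A [gene_universe()].
#' @param min_mut_genes Minimum retained MutGenes per sample (default 10).
#' @param silent_classes Variant classes treated as silent (default
#'   `c("Silent", "Intron", "3'UTR", "5'UTR", "IGR", "RNA", "5'Flank", "3'Flank")`).
#' @return As [read_mutations()].
#' @export
read_maf <- function(path, universe, min_mut_genes = 10L,
                     silent_classes = c("Silent", "Intron", "3'UTR", "5'UTR",
                                        "IGR", "RNA", "5'Flank", "3'Flank")) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!file.exists(path)) stop("MAF file not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("MAF file missing column(s): ", paste(miss, collapse = ", "))
  if ("Variant_Classification" %in% names(tab)) {
    tab <- tab[!(tab$Variant_Classification %in% silent_classes), , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no non-silent variants in ", path)
  mutations_from_pairs(tab$Tumor_Sample_Barcode, tab$Hugo_Symbol,
                       universe, min_mut_genes)
}

# Shared core: collapse (sample, gene) pairs, drop off-universe genes,
# apply the per-sample MutGene count filter.
mutations_from_pairs <- function(samples, genes, universe, min_mut_genes) {
  samples <- as.character(samples)
  genes <- as.character(genes)
  in_uni <- genes %in% universe$gene_ids
  n_off <- sum(!in_uni)
  if (n_off) {
    warning("dropping ", n_off, " mutation record(s) for genes absent from ",
            "the universe", call. = FALSE)
  }
  by_sample <- split(genes[in_uni], samples[in_uni])
  by_sample <- lapply(by_sample, unique)
  keep <- lengths(by_sample) >= min_mut_genes
  dropped <- union(names(by_sample)[!keep],
                   setdiff(unique(samples), names(by_sample)))
  if (length(dropped)) {
    message(length(dropped), " sample(s) dropped (< ", min_mut_genes,
            " universe-resident mutated genes)")
  }
  by_sample <- by_sample[keep]
  if (length(by_sample) == 0L) {
    stop("zero samples survive the min_mut_genes = ", min_mut_genes, " filter")
  }
  out <- lapply(names(by_sample), function(s) {
    structure(
      list(sample_id = s, mut_genes = by_sample[[s]],
           N = length(by_sample[[s]]), n_dropped = NA_integer_),
      class = "sample_mutations"
    )
  })
  names(out) <- names(by_sample)
  attr(out, "dropped_samples") <- dropped
  attr(out, "n_off_universe") <- n_off
  out
}
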