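#' Per-gene probability of harbouring at least one mutation
#'
#' Under a uniform per-nucleotide mutation process at rate `mu`, a gene of
#' length `l` nucleotides escapes mutation with probability `exp(-mu * l)`
#' (independent Bernoulli trials per position, in the Poisson limit), so its
#' gene-wise mutation rate is `m = 1 - exp(-mu * l)`.
#'
#' @param mu Background mutation rate per nucleotide (>= 0, typically of
#'   order 1e-6).
#' @param length Gene length in nucleotides (>= 0). Recycled against `mu`.
#' @return Probability in `[0, 1)`, vectorised over the inputs.
#' @examples
#' gene_mutation_prob(2.7e-6, 5000)
#' @export
gene_mutation_prob <- function(mu, length) {
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("'mu' must be finite and >= 0")
  }
  if (any(!is.finite(length)) || any(length < 0)) {
    stop("'length' must be finite and >= 0")
  }
  -expm1(-mu * length)
}

#' Construct a gene universe
#'
#' The universe is the set of assayed genes over which mutated-gene labels
#' are resampled: ordered gene identifiers with lengths and, once `mu` is
#' set, gene-wise mutation rates `m_i = 1 - exp(-mu * l_i)`. The universe is
#' always user-supplied (e.g. a targeted sequencing panel); resampling over
#' genes that were never assayed would be invalid.
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param lengths Positive gene lengths in nucleotides, one per gene. Any
#'   consistent length convention (genomic span, coding length) may be used.
#' @param mu Optional background mutation rate per nucleotide; when supplied,
#'   per-gene mutation rates are attached.
#' @return An object of class `gene_universe`: a list with `gene_ids`,
#'   `lengths`, `mu` and `mutation_rates` (NULL until `mu` is set).
#' @seealso [read_gene_lengths()], [set_mu()]
#' @export
gene_universe <- function(gene_ids, lengths, mu = NULL) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) == 0L) stop("empty universe")
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids in universe: ", paste(head(dups, 5), collapse = ", "))
  }
  lengths <- as.numeric(lengths)
  if (length(lengths) != length(gene_ids)) {
    stop("'lengths' must match 'gene_ids' in length")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    bad <- which(!is.finite(lengths) | lengths <= 0)[1]
    stop("non-positive or non-numeric length for gene '", gene_ids[bad], "'")
  }
  uni <- structure(
    list(gene_ids = gene_ids, lengths = unname(lengths),
         mu = NULL, mutation_rates = NULL),
    class = "gene_universe"
  )
  if (!is.null(mu)) uni <- set_mu(uni, mu)
  uni
}

#' Attach a background mutation rate to a universe
#'
#' @param universe A [gene_universe()].
#' @param mu Background mutation rate per nucleotide, > 0. May also be a
#'   named vector keyed by gene id for per-gene rates (e.g. when samples in
#'   different treatment groups use different rates, rebuild the universe per
#'   group instead).
#' @return The universe with `mu` and `mutation_rates` filled in.
#' @export
set_mu <- function(universe, mu) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("'mu' must be a single finite rate > 0")
  }
  universe$mu <- mu
  universe$mutation_rates <- gene_mutation_prob(mu, universe$lengths)
  universe
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("gene_universe:", length(x$gene_ids), "genes; length range [",
      min(x$lengths), ",", max(x$lengths), "] nt;",
      if (is.null(x$mu)) "mu unset" else paste0("mu = ", format(x$mu)), "\n")
  invisible(x)
}

#' Read a gene universe from a two-column length table
#'
#' Expects a tab-separated file with at least two columns: gene id and gene
#' length in nucleotides. A header line is detected automatically (a
#' non-numeric second field on line 1 is treated as a header).
#'
#' @param path Path to the TSV file.
#' @param duplicates How to resolve duplicated gene ids: `"error"` (default)
#'   or `"keep-max"` (keep the largest length). Silent resolution can hide
#'   annotation bugs, hence the strict default.
#' @param mu Optional background mutation rate to attach (see [set_mu()]).
#' @return A [gene_universe()] (mutation rates unset unless `mu` is given).
#' @export
read_gene_lengths <- function(path, duplicates = c("error", "keep-max"),
                              mu = NULL) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stop("gene length file not found: ", path)
  tab <- tryCatch(
    read.delim(path, header = FALSE, colClasses = "character",
               stringsAsFactors = FALSE, comment.char = "#",
               blank.lines.skip = TRUE),
    error = function(e) stop("empty universe: no rows in ", path)
  )
  if (nrow(tab) == 0L) stop("empty universe: no rows in ", path)
  if (ncol(tab) < 2L) stop("gene length file needs >= 2 columns (gene, length)")
  if (is.na(suppressWarnings(as.numeric(tab[1, 2])))) tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("empty universe: no data rows in ", path)
  ids <- tab[[1]]
  len <- suppressWarnings(as.numeric(tab[[2]]))
  bad <- which(is.na(len) | len <= 0)
  if (length(bad)) {
    stop("non-positive or non-numeric length at row ", bad[1],
         " (gene '", ids[bad[1]], "')")
  }
  if (anyDuplicated(ids)) {
    if (duplicates == "error") {
      dups <- unique(ids[duplicated(ids)])
      stop("duplicate gene ids in ", path, ": ",
           paste(head(dups, 5), collapse = ", "),
           " (use duplicates = \"keep-max\" to keep the largest length)")
    }
    ord <- order(ids, -len)
    keep <- !duplicated(ids[ord])
    ids <- ids[ord][keep]
    len <- len[ord][keep]
  }
  gene_universe(ids, len, mu = mu)
}

#' Write a gene universe back to a length TSV
#'
#' @param universe A [gene_universe()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_lengths <- function(universe, path) {
  stopifnot(inherits(universe, "gene_universe"))
  write.table(
    data.frame(gene = universe$gene_ids, length = universe$lengths),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
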