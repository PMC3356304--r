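#' Read gene sets from a GMT file
#'
#' GMT lines are `id TAB description TAB gene1 TAB gene2 ...`. Members are
#' first intersected with the universe, then the size filter is applied to
#' the intersected size, so a pathway whose nominal size exceeds `max_size`
#' is retained if enough of its members fall outside the assayed universe.
#'
#' @param path Path to the GMT file.
#' @param universe A [gene_universe()]; members outside it are dropped.
#' @param min_size,max_size Inclusive size bounds applied to the
#'   universe-resident membership (defaults 10 and 500, the conventional
#'   band that excludes overly specific and overly general gene sets).
#' @return A `pathway_collection`: list with `sets` (named list of member
#'   gene-id vectors), `names` (named character vector of descriptions),
#'   `min_size`, `max_size`, and `dropped` (data.frame of excluded pathways
#'   with reasons).
#' @export
read_gmt <- function(path, universe, min_size = 10L, max_size = 500L) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed GMT line ", which(nf < 3L)[1],
         ": fewer than 3 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descs <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  pathway_collection(setNames(members, ids), setNames(descs, ids),
                     universe, min_size, max_size)
}

#' Build a size-filtered pathway collection
#'
#' @param sets Named list of member gene-id character vectors.
#' @param names Named character vector of pathway descriptions (optional;
#'   defaults to the ids).
#' @param universe A [gene_universe()].
#' @param min_size,max_size Inclusive bounds on universe-resident size.
#' @return A `pathway_collection` (see [read_gmt()]).
#' @export
pathway_collection <- function(sets, names = NULL, universe,
                               min_size = 10L, max_size = 500L) {
  stopifnot(inherits(universe, "gene_universe"))
  if (is.null(base::names(sets)) || anyDuplicated(base::names(sets))) {
    stop("'sets' must be a uniquely named list")
  }
  if (is.null(names)) names <- setNames(base::names(sets), base::names(sets))
  resident <- lapply(sets, function(g) {
    g <- unique(as.character(g))
    g[g %in% universe$gene_ids]
  })
  sz <- lengths(resident)
  keep <- sz >= min_size & sz <= max_size
  dropped <- data.frame(
    pathway_id = base::names(sets)[!keep],
    size = sz[!keep],
    reason = ifelse(sz[!keep] < min_size, "below min_size", "above max_size"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (nrow(dropped)) {
    message(nrow(dropped), " pathway(s) dropped by size filter [",
            min_size, ", ", max_size, "]")
  }
  structure(
    list(sets = resident[keep],
         names = names[base::names(sets)[keep]],
         min_size = min_size, max_size = max_size, dropped = dropped),
    class = "pathway_collection"
  )
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat("pathway_collection:", length(x$sets), "pathways (size filter [",
      x$min_size, ",", x$max_size, "]);", nrow(x$dropped), "dropped\n")
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$sets)

#' Write a pathway collection to GMT
#'
#' @param pathways A `pathway_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  stopifnot(inherits(pathways, "pathway_collection"))
  ids <- names(pathways$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, unname(pathways$names[id]), pathways$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
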