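# Gene-set enrichment of skewed gene lists: GMT I/O and one-sided Fisher
# (hypergeometric upper-tail) over-representation tests with BH correction.

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Empty lines are
#' skipped; duplicate members within a line are stored once.
#'
#' @param path Path to a GMT file.
#' @return Object of class `geneset_collection`: a named list of character
#'   vectors, with attributes `descriptions` (named) and `source`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  desc <- character(0)
  for (i in keep) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, ": fewer than 3 tab-separated fields",
           call. = FALSE)
    nm <- f[1]
    if (nm %in% names(sets))
      stop("GMT line ", i, ": duplicate set name '", nm, "'", call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("GMT line ", i, ": set '", nm, "' has no members", call. = FALSE)
    sets[[nm]] <- members
    desc[nm] <- f[2]
  }
  structure(sets, descriptions = desc, source = path,
            class = "geneset_collection")
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors (or a `geneset_collection`).
#' @param path Output path.
#' @param descriptions Optional named character descriptions; defaults to the
#'   collection's stored descriptions or `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all gene sets must be named", call. = FALSE)
  d <- if (is.null(descriptions)) stats::setNames(rep("na", length(nm)), nm)
       else descriptions
  lines <- vapply(nm, function(s) {
    paste(c(s, if (is.na(d[s])) "na" else d[s], unique(sets[[s]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided Fisher over-representation test against a gene-set collection
#'
#' For each gene set (intersected with the universe first), tests whether the
#' query list over-represents the set's members: the one-sided Fisher exact
#' p-value of the 2x2 (in/out of query x in/out of set) table, which equals
#' the hypergeometric upper tail `P[X >= overlap]`. q-values are
#' Benjamini-Hochberg across the tested sets of this query. Sets with an
#' empty universe intersection are skipped and reported in the `"skipped"`
#' attribute.
#'
#' @param query Character vector of genes of interest (e.g. the male-skewed
#'   list); must be a subset of `universe`.
#' @param universe Character vector of all genes that entered the selection
#'   (the association universe); duplicates removed.
#' @param sets A `geneset_collection` from [read_gmt()] or a named list of
#'   character vectors.
#'
#' @return Data.frame with one row per tested set: `set`, `query_size`,
#'   `set_size` (after universe intersection), `overlap`, `p`, `q`, ordered
#'   as in the collection. Attribute `"skipped"` lists sets with no universe
#'   overlap.
#' @export
#' @examples
#' sets <- list(S1 = paste0("G", 1:10), S2 = paste0("G", 40:59))
#' fisher_enrichment(paste0("G", 1:20), paste0("G", 1:100), sets)
fisher_enrichment <- function(query, universe, sets) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  bad <- setdiff(query, universe)
  if (length(bad) > 0)
    stop("query genes outside the universe: ", paste(bad, collapse = ", "),
         call. = FALSE)
  n_u <- length(universe)
  n_q <- length(query)
  rows <- list()
  skipped <- character(0)
  for (nm in names(sets)) {
    s <- intersect(sets[[nm]], universe)
    if (length(s) == 0) {
      skipped <- c(skipped, nm)
      next
    }
    k <- length(intersect(query, s))
    p <- stats::phyper(k - 1, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    rows[[nm]] <- data.frame(set = nm, query_size = n_q,
                             set_size = length(s), overlap = k, p = p,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    stop("no gene set overlaps the universe", call. = FALSE)
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
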