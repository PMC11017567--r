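# File I/O for the tab-separated formats the pipeline reads and writes.

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and one row per gene, first column
#' gene ids. Empty cells (or literal `NA`) are missing values handled by the
#' chosen policy; infinite values are an error.
#'
#' @param path Path to a TSV file.
#' @param missing Missing-value policy: `"drop"` (default) removes any gene
#'   row with a missing value, `"impute"` replaces missing cells with the
#'   gene's row mean.
#' @param dedup Duplicate gene-id policy: `"error"` (default) or `"first"`
#'   (keep the first occurrence).
#' @param transpose If `TRUE`, the file is samples x genes and is transposed
#'   after parsing.
#' @param exclude_genes Optional character vector of gene ids to remove
#'   (e.g. a sex-chromosome gene list, so distances ignore canonical
#'   XY-linked expression).
#'
#' @return Numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression <- function(path, missing = c("drop", "impute"),
                            dedup = c("error", "first"),
                            transpose = FALSE, exclude_genes = NULL) {
  missing <- match.arg(missing)
  dedup <- match.arg(dedup)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2)
    stop("expression file needs a header and at least one gene row",
         call. = FALSE)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row at line ", bad, ": ", nf[bad], " fields, expected ",
         nf[1], call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE,
                           colClasses = "character")
  ids <- tab[[1]]
  vals <- suppressWarnings(
    vapply(tab[-1], as.numeric, numeric(nrow(tab))))
  if (nrow(tab) == 1) vals <- matrix(vals, nrow = 1)
  m <- matrix(as.numeric(vals), nrow = nrow(tab),
              dimnames = list(ids, names(tab)[-1]))
  if (transpose) m <- t(m)
  if (any(is.infinite(m)))
    stop("expression file contains non-finite values", call. = FALSE)
  if (anyDuplicated(rownames(m))) {
    if (dedup == "error") {
      stop("duplicate gene id(s): ",
           paste(unique(rownames(m)[duplicated(rownames(m))]),
                 collapse = ", "),
           " (use dedup = \"first\" to keep first occurrences)",
           call. = FALSE)
    }
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
  }
  if (!is.null(exclude_genes))
    m <- m[!(rownames(m) %in% exclude_genes), , drop = FALSE]
  if (anyNA(m)) {
    if (missing == "drop") {
      m <- m[!apply(is.na(m), 1L, any), , drop = FALSE]
    } else {
      rm <- rowMeans(m, na.rm = TRUE)
      idx <- which(is.na(m), arr.ind = TRUE)
      m[idx] <- rm[idx[, 1L]]
    }
  }
  m
}

#' Write an expression matrix as TSV
#'
#' Values are printed with 17 significant digits so a write-read round trip
#' reproduces the matrix exactly.
#'
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  body <- matrix(sprintf("%.17g", expr), nrow = nrow(expr))
  lines <- c(paste(c("gene", colnames(expr)), collapse = "\t"),
             paste(rownames(expr),
                   apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' TSV with a header; requires columns `sample`, `sex`, `cancer_type`
#' (optional `weight`). Sex labels are normalized case-insensitively from
#' male/m/female/f; any other value is an error.
#'
#' @param path Path to a TSV file.
#' @return Validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  validate_annotations(ann)
}

#' Write a sample annotation table
#'
#' @param ann Annotation data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  write_tsv(validate_annotations(ann), path)
}

#' Write a TI result table
#'
#' Columns `sample`, `cancer_type`, `sex`, `ti`, `support`, sorted by sample
#' id, full numeric precision (the table is an intermediate consumed by the
#' association and contrast steps).
#'
#' @param ti_results Data.frame from [compute_ti()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ti <- function(ti_results, path) {
  write_tsv(ti_results[order(ti_results$sample), ], path)
}

#' Read a TI result table written by [write_ti()]
#'
#' @param path Path to the TSV.
#' @return Data.frame with `sample`, `cancer_type`, `sex`, `ti`, `support`.
#' @export
read_ti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ti <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample", "cancer_type", "sex", "ti")
  miss <- setdiff(need, names(ti))
  if (length(miss) > 0)
    stop("TI table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ti$sample <- as.character(ti$sample)
  ti
}
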