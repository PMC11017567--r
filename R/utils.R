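# Internal helpers shared across modules.

# Canonicalize sex labels: {male, m} / {female, f}, case-insensitive.
# Anything else is an error -- the binary encoding is a model assumption
# that must be explicit, never silently dropped.
normalize_sex <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(v))
  out[v %in% c("male", "m")] <- "male"
  out[v %in% c("female", "f")] <- "female"
  if (anyNA(out)) {
    stop("unrecognized sex label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected male/m/female/f)", call. = FALSE)
  }
  out
}

# Validate and canonicalize a sample annotation table.
validate_annotations <- function(ann) {
  if (!is.data.frame(ann))
    stop("annotations must be a data.frame", call. = FALSE)
  need <- c("sample", "sex", "cancer_type")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0)
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ann$sample <- as.character(ann$sample)
  if (anyDuplicated(ann$sample))
    stop("duplicate sample id(s): ",
         paste(unique(ann$sample[duplicated(ann$sample)]), collapse = ", "),
         call. = FALSE)
  ann$sex <- normalize_sex(ann$sex)
  ann$cancer_type <- as.character(ann$cancer_type)
  if ("weight" %in% names(ann)) {
    w <- as.numeric(ann$weight)
    if (anyNA(w) || any(!is.finite(w)) || any(w <= 0))
      stop("annotation weights must be positive and finite", call. = FALSE)
    ann$weight <- w
  }
  ann
}

# Tab-separated writer with a header and deterministic content. Numeric
# columns are printed at full double precision by default, or rounded to
# `digits` significant digits for human-facing report tables.
write_tsv <- function(df, path, digits = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- if (is.null(digits)) sprintf("%.17g", out[[j]])
                  else as.character(signif(out[[j]], digits))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score for separating positives from
#' negatives; ties share ranks. Used to quantify how well association
#' statistics rank planted genes above null genes in recovery experiments.
#'
#' @param score Numeric scores, larger = more positive-like.
#' @param positive Logical vector, `TRUE` for positives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, positive) {
  positive <- as.logical(positive)
  stopifnot(length(score) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    stop("need at least one positive and one negative", call. = FALSE)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
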