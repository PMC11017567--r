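# Per-gene association of expression with TI, skew calling, list overlap
# testing, and midrange-versus-pole contrasts.

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment. Input order is preserved.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`, same order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Per-gene association of expression with TI
#'
#' Fits, for every gene, an ordinary least squares regression of expression
#' on the TI vector and tests the slope with a two-sided t-test; q-values are
#' Benjamini-Hochberg across all genes of the cohort. Genes significantly
#' positively associated with TI (`slope > 0`, `q < threshold`) are called
#' male-skewed, negative ones female-skewed. A constant gene gets slope 0,
#' p = 1, skew "none" by convention (its t statistic is undefined).
#'
#' Association is intended to be fit within one cancer type (TI values are
#' only comparable within the cohort they were estimated in); cross-cohort
#' claims should be made at the gene-list or pathway level.
#'
#' @param expr Numeric matrix, genes x samples; column names must cover the
#'   samples the TI vector refers to.
#' @param ti Numeric TI vector, either aligned with `expr` columns or named
#'   by sample id.
#' @param threshold FDR level for skew calls (default 0.05).
#'
#' @return Data.frame with one row per gene (input gene order preserved):
#'   `gene`, `slope`, `p`, `q`, `skew` in `{male, female, none}`.
#' @export
associate_genes <- function(expr, ti, threshold = 0.05) {
  expr <- as.matrix(expr)
  if (!is.null(names(ti))) {
    miss <- setdiff(colnames(expr), names(ti))
    if (length(miss) > 0)
      stop("TI missing for sample(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    ti <- ti[colnames(expr)]
  }
  n <- ncol(expr)
  if (length(ti) != n)
    stop("need one TI value per expression column", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::var(ti) == 0)
    stop("TI values are all identical; association undefined", call. = FALSE)

  xc <- ti - mean(ti)
  sxx <- sum(xc^2)
  yc <- expr - rowMeans(expr)
  slope <- as.vector(yc %*% xc) / sxx
  res <- yc - outer(slope, xc)
  rss <- rowSums(res^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  const <- rowSums(yc^2) == 0
  slope[const] <- 0
  p[const] <- 1
  # perfect non-constant fit: se = 0, |t| = Inf -> p = 0 (pt handles Inf)
  p[is.nan(p)] <- 1
  q <- bh_fdr(p)
  skew <- rep("none", nrow(expr))
  skew[slope > 0 & q < threshold] <- "male"
  skew[slope < 0 & q < threshold] <- "female"
  genes <- rownames(expr)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(expr)))
  data.frame(gene = genes, slope = slope, p = p, q = q, skew = skew,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split association records into pole gene lists
#'
#' @param records Data.frame from [associate_genes()].
#' @param threshold FDR level; genes with `q < threshold` are classified by
#'   slope sign.
#' @return List with character vectors `male` and `female` (disjoint).
#' @export
classify_poles <- function(records, threshold = 0.05) {
  need <- c("gene", "slope", "q")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0)
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  list(
    male = records$gene[records$slope > 0 & records$q < threshold],
    female = records$gene[records$slope < 0 & records$q < threshold]
  )
}

#' Hypergeometric overlap test for two gene lists
#'
#' Upper-tail probability of observing at least the realized overlap between
#' two gene lists drawn from a common universe (duplicates are removed).
#'
#' @param a,b Character vectors of gene ids, subsets of the universe.
#' @param universe_size Number of genes in the universe.
#' @return List with `overlap` (count) and `p` (one-sided upper-tail
#'   hypergeometric probability).
#' @export
overlap_test <- function(a, b, universe_size) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) > universe_size || length(b) > universe_size)
    stop("lists cannot exceed the universe size", call. = FALSE)
  k <- length(intersect(a, b))
  p <- stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                     lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Midrange-versus-pole expression contrast
#'
#' Within one sex stratum of each cancer type, compares midrange-TI samples
#' (`low <= ti <= high`) against the sex's own pole (females with
#' `ti < low`, males with `ti > high`) gene by gene with a two-sided Welch
#' t-test, followed by Benjamini-Hochberg correction across genes. The
#' default bounds `(0.25, 0.75)` mark the observed all-female / all-male
#' tails of the pan-cancer TI distribution.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param ti_results Data.frame from [compute_ti()] (`sample`,
#'   `cancer_type`, `sex`, `ti`).
#' @param sex Stratum to contrast, `"male"` or `"female"`.
#' @param bounds Numeric `(low, high)` with `0 <= low < high <= 1`.
#' @param threshold FDR level for calling a direction (default 0.05).
#'
#' @return Data.frame with one row per gene and cancer type: `gene`,
#'   `cancer_type`, `sex`, `mean_pole`, `mean_midrange`, `difference`
#'   (midrange minus pole), `p`, `q`, and `direction` in
#'   `{gained, lost, none}` (`gained` = higher in midrange at `q <
#'   threshold`).
#' @export
midrange_contrast <- function(expr, ti_results, sex = c("female", "male"),
                              bounds = c(0.25, 0.75), threshold = 0.05) {
  sex <- match.arg(sex)
  if (length(bounds) != 2 || !all(is.finite(bounds)) ||
      bounds[1] >= bounds[2] || bounds[1] < 0 || bounds[2] > 1)
    stop("`bounds` must be (low, high) with 0 <= low < high <= 1",
         call. = FALSE)
  expr <- as.matrix(expr)
  sub <- ti_results[ti_results$sex == sex, ]
  out <- list()
  for (ct in unique(sub$cancer_type)) {
    s <- sub[sub$cancer_type == ct, ]
    pole_ids <- if (sex == "female") s$sample[s$ti < bounds[1]]
                else s$sample[s$ti > bounds[2]]
    mid_ids <- s$sample[s$ti >= bounds[1] & s$ti <= bounds[2]]
    if (length(pole_ids) < 2 || length(mid_ids) < 2) {
      stop("cancer type '", ct, "', ", sex, " stratum: ",
           if (length(pole_ids) < 2) "pole" else "midrange",
           " group has fewer than 2 samples (pole n=", length(pole_ids),
           ", midrange n=", length(mid_ids), ")", call. = FALSE)
    }
    out[[ct]] <- welch_by_gene(expr[, pole_ids, drop = FALSE],
                               expr[, mid_ids, drop = FALSE],
                               ct, sex, threshold)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Vectorized two-sided Welch t-test per gene (pole vs midrange).
welch_by_gene <- function(pole, mid, cancer_type, sex, threshold) {
  n1 <- ncol(pole)
  n2 <- ncol(mid)
  m1 <- rowMeans(pole)
  m2 <- rowMeans(mid)
  v1 <- rowSums((pole - m1)^2) / (n1 - 1)
  v2 <- rowSums((mid - m2)^2) / (n2 - 1)
  sesq <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(sesq)
  df <- sesq^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  diff <- m2 - m1
  # degenerate zero-variance genes: identical constants -> no evidence;
  # separated constants -> unbounded statistic
  p[sesq == 0 & diff == 0] <- 1
  p[sesq == 0 & diff != 0] <- 0
  q <- bh_fdr(p)
  direction <- rep("none", length(p))
  direction[diff > 0 & q < threshold] <- "gained"
  direction[diff < 0 & q < threshold] <- "lost"
  genes <- rownames(pole)
  if (is.null(genes)) genes <- as.character(seq_along(p))
  data.frame(gene = genes, cancer_type = cancer_type, sex = sex,
             mean_pole = m1, mean_midrange = m2, difference = diff,
             p = p, q = q, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}
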