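# Cohort-level Transcriptomic Index: leave-one-out BNN within each cancer
# type, balanced weighting, quantile summaries, and IRR regression.

#' Sex-balancing observation weights
#'
#' Within each cancer type of `N` samples with `N_m` males and `N_f` females,
#' assigns `w_male = N / (2 N_m)` and `w_female = N / (2 N_f)`, so the total
#' male and female weight both equal `N / 2`. This is the weighting used to
#' keep the BNN label evidence balanced in cohorts with skewed male:female
#' ratios.
#'
#' @param ann Sample annotation data.frame with columns `sample`, `sex`,
#'   `cancer_type`.
#' @return Named numeric vector of weights, one per sample, in `ann` order.
#' @export
balanced_weights <- function(ann) {
  ann <- validate_annotations(ann)
  w <- numeric(nrow(ann))
  for (ct in unique(ann$cancer_type)) {
    idx <- ann$cancer_type == ct
    nm <- sum(ann$sex[idx] == "male")
    nf <- sum(ann$sex[idx] == "female")
    if (nm == 0 || nf == 0) {
      stop("balanced weighting undefined for cancer type '", ct,
           "': needs both sexes present", call. = FALSE)
    }
    n <- nm + nf
    w[idx] <- ifelse(ann$sex[idx] == "male", n / (2 * nm), n / (2 * nf))
  }
  stats::setNames(w, ann$sample)
}

#' Leave-one-out Transcriptomic Index for a cohort
#'
#' Computes, separately within each cancer type, the TI of every sample: the
#' sample's training set is all *other* samples of the same cancer type,
#' ordered by Euclidean distance (farthest first, ties broken by sample id),
#' and the posterior male probability comes from [bnn_posterior()]. With
#' `weighting = "balanced"` in the configuration, [balanced_weights()] are
#' applied to the label evidence; an explicit `weight` column in `ann` is
#' used when the configuration is unweighted.
#'
#' A cancer type with a single sample gets the prior mean
#' `alpha / (alpha + beta)` with a warning (no neighbors to learn from).
#'
#' @param expr Numeric expression matrix, genes in rows, samples in columns
#'   (column names are sample ids). All values must be finite.
#' @param ann Annotation data.frame with columns `sample`, `sex`
#'   (male/female), `cancer_type`, optional `weight`.
#' @param config A [bnn_config()].
#'
#' @return A data.frame with one row per sample (in `ann` order):
#'   `sample`, `cancer_type`, `sex`, `ti`, and `support` (the expected size
#'   `E[k_tau]` of the target's partition, i.e. how many nearest neighbors
#'   effectively back the prediction).
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_samples = 30, n_genes = 50,
#'                                    module_size_male = 5,
#'                                    module_size_female = 5), seed = 1)
#' ti <- compute_ti(sim$expression, sim$annotations)
#' head(ti)
compute_ti <- function(expr, ann, config = bnn_config()) {
  if (!inherits(config, "bnn_config"))
    stop("`config` must be a bnn_config object", call. = FALSE)
  ann <- validate_annotations(ann)
  expr <- as.matrix(expr)
  if (is.null(colnames(expr)))
    stop("expression matrix must have sample ids as column names",
         call. = FALSE)
  un <- setdiff(colnames(expr), ann$sample)
  if (length(un) > 0)
    stop("samples missing annotation: ", paste(un, collapse = ", "),
         call. = FALSE)
  un <- setdiff(ann$sample, colnames(expr))
  if (length(un) > 0)
    stop("annotated samples absent from expression matrix: ",
         paste(un, collapse = ", "), call. = FALSE)
  if (any(!is.finite(expr)))
    stop("expression matrix contains non-finite values", call. = FALSE)

  w <- if (config$weighting == "balanced") {
    balanced_weights(ann)
  } else if ("weight" %in% names(ann)) {
    stats::setNames(ann$weight, ann$sample)
  } else {
    stats::setNames(rep(1, nrow(ann)), ann$sample)
  }
  x <- stats::setNames(as.numeric(ann$sex == "male"), ann$sample)

  ti <- support <- stats::setNames(numeric(nrow(ann)), ann$sample)
  for (ct in unique(ann$cancer_type)) {
    sid <- ann$sample[ann$cancer_type == ct]
    if (length(sid) < 2L) {
      warning("cancer type '", ct, "' has fewer than 2 samples; ",
              "TI set to the prior mean", call. = FALSE)
      ti[sid] <- config$alpha / (config$alpha + config$beta)
      support[sid] <- 0
      next
    }
    D <- as.matrix(stats::dist(t(expr[, sid, drop = FALSE])))
    for (s in sid) {
      others <- setdiff(sid, s)
      d <- D[s, others]
      ord <- order(-d, others)  # farthest first, ties by ascending id
      nb <- neighbor_sequence(x[others][ord], w[others][ord], others[ord])
      post <- bnn_posterior(nb, config)
      ti[s] <- post$ti
      support[s] <- post$expected_k
    }
  }
  data.frame(sample = ann$sample, cancer_type = ann$cancer_type,
             sex = ann$sex, ti = unname(ti[ann$sample]),
             support = unname(support[ann$sample]),
             stringsAsFactors = FALSE)
}

#' Per-cancer-type TI summaries
#'
#' Counts, male:female ratio, and the median plus 5/25/75/95% quantiles of
#' the TI distribution per cancer type. Quantiles use linear interpolation
#' between order statistics (R's default type 7), a convention fixed for
#' reproducibility. The male:female ratio is computed from cohort counts
#' `N_m / N_f`; an externally determined incidence rate ratio can be
#' supplied instead via `irr` (e.g. registry-based rates) and overrides the
#' count ratio for matching cancer types.
#'
#' @param ti_results Data.frame from [compute_ti()] (columns `sample`,
#'   `cancer_type`, `sex`, `ti`).
#' @param irr Optional data.frame with columns `cancer_type` and `irr`
#'   supplying external male:female incidence rate ratios.
#'
#' @return A data.frame with one row per cancer type: `cancer_type`,
#'   `n_male`, `n_female`, `irr`, `median_ti`, `q05`, `q25`, `q75`, `q95`,
#'   sorted by cancer type.
#' @export
summarize_cohorts <- function(ti_results, irr = NULL) {
  need <- c("cancer_type", "sex", "ti")
  miss <- setdiff(need, names(ti_results))
  if (length(miss) > 0)
    stop("ti_results lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(ti_results) == 0) stop("empty TI table", call. = FALSE)
  types <- sort(unique(ti_results$cancer_type))
  rows <- lapply(types, function(ct) {
    sub <- ti_results[ti_results$cancer_type == ct, ]
    nm <- sum(sub$sex == "male")
    nf <- sum(sub$sex == "female")
    q <- stats::quantile(sub$ti, c(0.05, 0.25, 0.5, 0.75, 0.95),
                         type = 7, names = FALSE)
    data.frame(cancer_type = ct, n_male = nm, n_female = nf,
               irr = if (nm > 0 && nf > 0) nm / nf else NA_real_,
               median_ti = q[3], q05 = q[1], q25 = q[2], q75 = q[4],
               q95 = q[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(irr)) {
    if (!all(c("cancer_type", "irr") %in% names(irr)))
      stop("external `irr` needs columns cancer_type and irr", call. = FALSE)
    m <- match(out$cancer_type, irr$cancer_type)
    out$irr[!is.na(m)] <- irr$irr[m[!is.na(m)]]
  }
  rownames(out) <- NULL
  out
}

#' Regression of median TI on the male:female ratio
#'
#' Ordinary least squares of per-cancer-type median TI on the male:female
#' incidence rate ratio (or its log2), with a two-sided t-test for zero
#' slope. Cancer types with undefined IRR are dropped.
#'
#' @param summaries Data.frame from [summarize_cohorts()].
#' @param scale `"linear"` to regress on IRR, `"log2"` on `log2(IRR)`.
#'
#' @return A list with `slope`, `intercept`, `r` (Pearson correlation),
#'   `p_value` (two-sided, for zero slope), `n` (cohorts used), and `scale`.
#' @export
irr_ti_regression <- function(summaries, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  keep <- is.finite(summaries$irr) & is.finite(summaries$median_ti)
  x <- summaries$irr[keep]
  y <- summaries$median_ti[keep]
  if (scale == "log2") x <- log2(x)
  n <- length(x)
  if (n < 3) stop("need at least 3 cohorts with defined IRR", call. = FALSE)
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1], r = 0, p_value = 1,
                n = n, scale = scale))
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- stats::cor(x, y)
  # a perfect fit makes summary.lm warn; the NaN p is patched just below
  p <- suppressWarnings(summary(fit)$coefficients[2, 4])
  if (is.nan(p)) p <- if (abs(abs(r) - 1) < 1e-12) 0 else 1
  list(slope = slope, intercept = intercept, r = r, p_value = p,
       n = n, scale = scale)
}
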