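# Synthetic cohort generator: samples carry a latent sex continuum z that
# overlaps between the binary sex labels; planted gene modules track z in
# opposite directions against a majority of null genes. Full ground truth is
# returned for parameter-recovery tests.

#' Specification of a synthetic cohort
#'
#' The generator draws a latent continuum `z` per sample (`z | male ~
#' N(mu_male, sigma_z)`, `z | female ~ N(mu_female, sigma_z)`, with
#' `mu_male > mu_female` and overlapping supports), then builds expression
#' as `baseline_g + effect * z + noise` for male-module genes,
#' `baseline_g - effect * z + noise` for female-module genes, and
#' `baseline_g + noise` for null genes. Baselines are drawn once per gene
#' from N(0, 1). The default separation `mu_male - mu_female = 2 sigma_z`
#' makes the sexes clearly overlapping yet distinguishable, the regime the
#' TI model is designed for.
#'
#' @param n_samples Number of samples (default 300).
#' @param male_fraction Fraction of male samples, strictly in (0, 1).
#' @param n_genes Total genes (default 2000).
#' @param module_size_male,module_size_female Planted module sizes (default
#'   100 each); their sum must not exceed `n_genes`.
#' @param mu_male,mu_female Latent means per sex (defaults +1 / -1).
#' @param sigma_z Latent standard deviation within sex (> 0, default 1).
#' @param effect Expression shift per unit of `z`, in residual SD units
#'   (default 1); 0 makes the planted genes statistically null.
#' @param noise_sd Residual expression noise SD (>= 0, default 1).
#' @param mode `"continuum"` (default) for the overlapping latent model, or
#'   `"poles"` for two tight clusters (`sigma_z / 5` within sex).
#' @param cancer_type Cohort label used in the annotations.
#'
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 300, male_fraction = 0.5, n_genes = 2000,
                        module_size_male = 100, module_size_female = 100,
                        mu_male = 1, mu_female = -1, sigma_z = 1,
                        effect = 1, noise_sd = 1,
                        mode = c("continuum", "poles"),
                        cancer_type = "SYNTH") {
  mode <- match.arg(mode)
  if (n_samples < 2) stop("need at least 2 samples", call. = FALSE)
  if (male_fraction <= 0 || male_fraction >= 1)
    stop("male_fraction must be strictly in (0, 1)", call. = FALSE)
  if (module_size_male + module_size_female > n_genes)
    stop("planted modules cannot exceed the number of genes", call. = FALSE)
  if (sigma_z <= 0) stop("sigma_z must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (mu_male <= mu_female)
    stop("mu_male must exceed mu_female", call. = FALSE)
  structure(
    list(n_samples = n_samples, male_fraction = male_fraction,
         n_genes = n_genes, module_size_male = module_size_male,
         module_size_female = module_size_female, mu_male = mu_male,
         mu_female = mu_female, sigma_z = sigma_z, effect = effect,
         noise_sd = noise_sd, mode = mode, cancer_type = cancer_type),
    class = "cohort_spec")
}

#' Simulate a synthetic cohort with ground truth
#'
#' Deterministic given `seed`: two calls with the same spec and seed produce
#' identical matrices. See [cohort_spec()] for the generative model.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed (sets the R RNG).
#'
#' @return A list with
#'   \describe{
#'     \item{expression}{numeric matrix, genes x samples;}
#'     \item{annotations}{data.frame `sample`, `sex`, `cancer_type`;}
#'     \item{truth}{list with per-sample latent `z` (named), `sex`, per-gene
#'       `gene_skew` factor-like character (`male`/`female`/`null`, named),
#'       and `modules` (list of planted gene-id vectors).}
#'   }
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  if (!inherits(spec, "cohort_spec"))
    stop("`spec` must be a cohort_spec object", call. = FALSE)
  set.seed(as.integer(seed))
  n <- spec$n_samples
  n_m <- max(1L, min(n - 1L, round(n * spec$male_fraction)))
  sex <- sample(c(rep("male", n_m), rep("female", n - n_m)))
  ids <- sprintf("S%04d", seq_len(n))
  sd_z <- if (spec$mode == "poles") spec$sigma_z / 5 else spec$sigma_z
  z <- stats::rnorm(n,
                    mean = ifelse(sex == "male", spec$mu_male,
                                  spec$mu_female),
                    sd = sd_z)
  g_m <- spec$module_size_male
  g_f <- spec$module_size_female
  g_n <- spec$n_genes - g_m - g_f
  genes <- c(if (g_m > 0) sprintf("MG%04d", seq_len(g_m)),
             if (g_f > 0) sprintf("FG%04d", seq_len(g_f)),
             if (g_n > 0) sprintf("NG%04d", seq_len(g_n)))
  direction <- c(rep(1, g_m), rep(-1, g_f), rep(0, g_n))
  baseline <- stats::rnorm(spec$n_genes)
  expr <- baseline + outer(direction * spec$effect, z) +
    matrix(stats::rnorm(spec$n_genes * n, sd = spec$noise_sd),
           nrow = spec$n_genes, ncol = n)
  dimnames(expr) <- list(genes, ids)
  ann <- data.frame(sample = ids, sex = sex,
                    cancer_type = spec$cancer_type,
                    stringsAsFactors = FALSE)
  skew <- stats::setNames(
    c(rep("male", g_m), rep("female", g_f), rep("null", g_n)), genes)
  truth <- list(z = stats::setNames(z, ids),
                sex = stats::setNames(sex, ids),
                gene_skew = skew,
                modules = list(
                  male_module = genes[direction == 1],
                  female_module = genes[direction == -1]))
  list(expression = expr, annotations = ann, truth = truth)
}

#' Register planted modules (plus decoys) as a gene-set collection
#'
#' Emits one gene set per planted module plus `n_decoys` random decoy sets of
#' matched size drawn without replacement from the null genes, so the planted
#' sets never intersect the decoys. The result feeds straight into
#' [fisher_enrichment()] for recovery tests.
#'
#' @param truth Ground-truth list from [simulate_cohort()].
#' @param n_decoys Number of decoy sets (default 8).
#' @param seed Integer RNG seed for the decoy draw.
#' @return A `geneset_collection` (named list of gene-id vectors).
#' @export
register_genesets <- function(truth, n_decoys = 8, seed = 1L) {
  set.seed(as.integer(seed))
  modules <- Filter(function(x) length(x) > 0, truth$modules)
  if (length(modules) == 0)
    stop("no planted modules to register", call. = FALSE)
  null_genes <- names(truth$gene_skew)[truth$gene_skew == "null"]
  sizes <- vapply(modules, length, integer(1))
  sets <- modules
  if (n_decoys > 0) {
    for (i in seq_len(n_decoys)) {
      sz <- sizes[((i - 1L) %% length(sizes)) + 1L]
      if (sz > length(null_genes))
        stop("not enough null genes to draw a decoy of size ", sz,
             call. = FALSE)
      sets[[sprintf("decoy_%02d", i)]] <- sample(null_genes, sz)
    }
  }
  desc <- stats::setNames(
    c(rep("planted module", length(modules)),
      rep("random decoy", n_decoys)), names(sets))
  structure(sets, descriptions = desc, source = "synthetic",
            class = "geneset_collection")
}
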