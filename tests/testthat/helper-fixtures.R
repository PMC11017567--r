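# Shared fixtures and independent oracles used across the suite.

# Random neighbor sequence (labels and optional weights) for property tests.
rand_seq <- function(tau, weighted = FALSE) {
  neighbor_sequence(sample(0:1, tau, replace = TRUE),
                    if (weighted) stats::runif(tau, 0.2, 3))
}

# Upper-tail hypergeometric oracle by direct summation of point masses:
# P[X >= k] with X ~ Hypergeometric(N total, K in set, n drawn).
hyper_tail <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(stats::dhyper(max(k, 0):hi, K, N - K, n))
}

# Closed-form OLS oracle from raw sums (slope, intercept, two-sided p).
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(t), n - 2))
}

# Two well-separated sex clusters in gene space: 2*n_per samples, the male
# cluster centered at +center, female at -center, spherical noise `sd`.
two_cluster_cohort <- function(n_per = 20, n_genes = 10, center = 50,
                               sd = 1, seed = 11) {
  set.seed(seed)
  n <- 2 * n_per
  ids <- sprintf("S%03d", seq_len(n))
  sex <- rep(c("male", "female"), each = n_per)
  mu <- ifelse(sex == "male", center, -center)
  expr <- matrix(stats::rnorm(n_genes * n, sd = sd), n_genes, n) +
    matrix(mu, n_genes, n, byrow = TRUE)
  dimnames(expr) <- list(sprintf("G%03d", seq_len(n_genes)), ids)
  list(expression = expr,
       annotations = data.frame(sample = ids, sex = sex,
                                cancer_type = "TC",
                                stringsAsFactors = FALSE))
}
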