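# Bayesian nearest-neighbor (BNN) posterior with a changepoint partition
# prior over the distance-ordered neighbor sequence.

#' Configuration of the Bayesian nearest-neighbor model
#'
#' Collects the hyperparameters of the changepoint BNN model behind the
#' Transcriptomic Index. Within each partition of the distance-ordered
#' neighbor sequence, labels (1 = male, 0 = female) are i.i.d. Bernoulli with
#' a conjugate `Beta(alpha, beta)` prior on the male probability; moving from
#' the farthest neighbor towards the target, a new partition starts at each
#' step with prior probability `p_gamma`.
#'
#' @param alpha,beta Positive pseudo-counts of the Beta prior on the
#'   within-partition male probability. The symmetric default
#'   `alpha = beta = 10` pulls the index towards 0.5 unless the local
#'   neighborhood carries substantial evidence.
#' @param p_gamma Prior breakpoint probability in `[0, 1]`: the chance that a
#'   new partition begins at each step moving towards the target. Default
#'   0.05.
#' @param distance Distance metric identifier; only `"euclidean"` is
#'   supported.
#' @param weighting Either `"unweighted"` (all observations count 1) or
#'   `"balanced"` (per-cohort weights that equalize the total male and female
#'   mass, see [balanced_weights()]).
#'
#' @return An object of class `bnn_config`.
#' @seealso [bnn_posterior()], [compute_ti()]
#' @export
#' @examples
#' bnn_config()
#' bnn_config(p_gamma = 0.1, weighting = "balanced")
bnn_config <- function(alpha = 10, beta = 10, p_gamma = 0.05,
                       distance = "euclidean",
                       weighting = c("unweighted", "balanced")) {
  weighting <- match.arg(weighting)
  distance <- match.arg(distance, "euclidean")
  for (nm in c("alpha", "beta", "p_gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (alpha <= 0 || beta <= 0)
    stop("`alpha` and `beta` must be positive", call. = FALSE)
  if (p_gamma < 0 || p_gamma > 1)
    stop("`p_gamma` must lie in [0, 1]", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, p_gamma = p_gamma,
         distance = distance, weighting = weighting),
    class = "bnn_config"
  )
}

#' @export
print.bnn_config <- function(x, ...) {
  cat("BNN configuration: Beta(", x$alpha, ", ", x$beta, ") prior, p_gamma = ",
      x$p_gamma, ", ", x$distance, " distance, ", x$weighting, "\n", sep = "")
  invisible(x)
}

#' Ordered neighbor label sequence
#'
#' A sequence of binary sex labels (1 = male, 0 = female) with positive
#' observation weights, ordered from the training point *farthest* from the
#' target (index 1) to the nearest (last index). This is the sufficient input
#' to [bnn_posterior()].
#'
#' @param labels Numeric or logical vector with values in `{0, 1}`.
#' @param weights Positive observation weights, recycled scalar or one per
#'   label; defaults to 1 (unweighted).
#' @param ids Optional character identifiers, one per label.
#'
#' @return An object of class `neighbor_sequence`.
#' @export
neighbor_sequence <- function(labels, weights = NULL, ids = NULL) {
  labels <- as.numeric(labels)
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must all be 0 (female) or 1 (male)", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(labels))
  if (length(weights) == 1L) weights <- rep(weights, length(labels))
  weights <- as.numeric(weights)
  if (length(weights) != length(labels))
    stop("labels and weights must have equal length", call. = FALSE)
  if (anyNA(weights) || any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  if (!is.null(ids) && length(ids) != length(labels))
    stop("ids must have one entry per label", call. = FALSE)
  structure(list(labels = labels, weights = weights, ids = ids),
            class = "neighbor_sequence")
}

#' Order training samples by distance to a target
#'
#' Computes Euclidean distances from the target profile to every training
#' profile and returns the label/weight sequence sorted farthest-first (the
#' ordering convention of the changepoint model). Ties in distance are broken
#' by ascending sample id so the ordering is reproducible.
#'
#' @param target Numeric expression profile of the target sample.
#' @param profiles Numeric matrix of training profiles, one row per sample,
#'   columns matching `target`.
#' @param labels Binary labels (1 = male, 0 = female), one per row.
#' @param weights Optional positive weights, one per row (default 1).
#' @param ids Sample identifiers; defaults to `rownames(profiles)`.
#'
#' @return A [neighbor_sequence()] whose last element is the nearest
#'   neighbor. Distances are attached as attribute `"distances"` (same
#'   order).
#' @export
#' @examples
#' p <- rbind(A = c(3, 4), B = c(1, 0), C = c(0, 2))
#' s <- order_neighbors(c(0, 0), p, labels = c(1, 0, 0))
#' s$labels  # farthest first: A (d=5), C (d=2), B (d=1)
order_neighbors <- function(target, profiles, labels, weights = NULL,
                            ids = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(ids)) ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(profiles)))
  if (length(target) != ncol(profiles)) {
    stop("profile dimension mismatch: target has ", length(target),
         " features, training profiles have ", ncol(profiles), call. = FALSE)
  }
  if (any(!is.finite(target)))
    stop("target profile contains non-finite values", call. = FALSE)
  bad <- !apply(is.finite(profiles), 1L, all)
  if (any(bad)) {
    stop("non-finite values in training profile(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  if (length(labels) != nrow(profiles))
    stop("need one label per training profile", call. = FALSE)
  if (nrow(profiles) == 0L)
    return(neighbor_sequence(numeric(0), numeric(0), character(0)))
  d <- sqrt(rowSums(sweep(profiles, 2L, target)^2))
  ord <- order(-d, ids)
  w <- if (is.null(weights)) rep(1, nrow(profiles)) else weights
  out <- neighbor_sequence(labels[ord], w[ord], ids[ord])
  attr(out, "distances") <- unname(d[ord])
  out
}

#' Beta-Bernoulli posterior predictive for one block
#'
#' Probability that the next observation in a partition is male, given the
#' (possibly weighted) male mass and total mass observed in that partition:
#' `(alpha + male_mass) / (alpha + beta + total_mass)`.
#'
#' @param male_mass Non-negative male evidence mass (weighted count).
#' @param total_mass Non-negative total evidence mass, at least `male_mass`.
#' @param config A [bnn_config()].
#'
#' @return A probability strictly inside (0, 1).
#' @export
#' @examples
#' block_predictive(8, 10, bnn_config())  # (10 + 8) / (20 + 10) = 0.6
block_predictive <- function(male_mass, total_mass, config = bnn_config()) {
  if (any(male_mass < 0) || any(total_mass < 0))
    stop("masses must be non-negative", call. = FALSE)
  if (any(male_mass > total_mass))
    stop("male_mass cannot exceed total_mass", call. = FALSE)
  (config$alpha + male_mass) / (config$alpha + config$beta + total_mass)
}

as_neighbor_sequence <- function(seq) {
  if (inherits(seq, "neighbor_sequence")) return(seq)
  if (is.numeric(seq) || is.logical(seq)) return(neighbor_sequence(seq))
  stop("`seq` must be a neighbor_sequence or a binary label vector",
       call. = FALSE)
}

#' BNN posterior predictive by forward recursion
#'
#' Exact posterior probability that the target is male, marginalized over the
#' changepoint partition of its distance-ordered neighbor sequence. The
#' forward pass tracks `p(k_i | x_0..x_i)` where `k_i` is the size of the
#' partition preceding observation `i`: a breakpoint (`k_i = 0`) occurs with
#' prior probability `p_gamma`, extension with `1 - p_gamma`, and each step
#' multiplies in the Beta-Bernoulli predictive of the observed label given
#' the current block. The state vector is renormalized every step and the
#' log normalization constant accumulated, so the recursion is numerically
#' exact for sequences of tens of thousands of neighbors. The target's own
#' transition follows the same law; the returned index averages the block
#' predictive over the posterior of the target partition size `k_tau`.
#'
#' @param seq A [neighbor_sequence()] (or bare binary label vector), ordered
#'   farthest-first.
#' @param config A [bnn_config()].
#'
#' @return A list of class `bnn_posterior` with elements
#'   \describe{
#'     \item{ti}{posterior probability the target is male, in `[0, 1]`;}
#'     \item{k}{integer support `0..tau` of the target partition size;}
#'     \item{prob}{posterior probabilities over `k` (sum to 1);}
#'     \item{expected_k}{`E[k_tau | data]`, the neighborhood support behind
#'       the prediction;}
#'     \item{log_marginal}{log marginal likelihood of the label sequence.}
#'   }
#'   An empty sequence returns the prior mean `alpha / (alpha + beta)` with
#'   all partition mass on `k = 0`.
#' @seealso [bnn_posterior_bruteforce()] for the enumeration cross-check.
#' @export
#' @examples
#' bnn_posterior(c(1, 1, 0, 0, 1, 1))$ti
#' bnn_posterior(rep(1, 10), bnn_config(p_gamma = 0))$ti  # single block
bnn_posterior <- function(seq, config = bnn_config()) {
  if (!inherits(config, "bnn_config"))
    stop("`config` must be a bnn_config object", call. = FALSE)
  seq <- as_neighbor_sequence(seq)
  l <- seq$labels
  w <- seq$weights
  tau <- length(l)
  a <- config$alpha
  b <- config$beta
  pg <- config$p_gamma
  if (tau == 0L) {
    return(structure(
      list(ti = a / (a + b), k = 0L, prob = 1, expected_k = 0,
           log_marginal = 0),
      class = "bnn_posterior"))
  }
  # cumulative weighted masses; cm[j + 1] = male mass of labels 1..j
  cm <- c(0, cumsum(w * l))
  ct <- c(0, cumsum(w))
  # after observing x_0: k_0 = 0 with probability 1
  p0 <- a / (a + b)
  logz <- log(if (l[1L] == 1) p0 else 1 - p0)
  g <- 1  # p(k_{i-1} | x_0..x_{i-1}) over k = 0..(i-1), normalized
  if (tau >= 2L) {
    for (i in 2:tau) {
      f <- c(pg, (1 - pg) * g)          # prior over k_i = 0..(i-1)
      kk <- 0:(i - 1L)
      m <- cm[i] - cm[i - kk]           # male mass of the k nearest before i
      t <- ct[i] - ct[i - kk]
      pm <- (a + m) / (a + b + t)
      lik <- if (l[i] == 1) pm else 1 - pm
      g <- f * lik
      s <- sum(g)
      logz <- logz + log(s)
      g <- g / s
    }
  }
  # target transition: same changepoint law, no label observed
  f <- c(pg, (1 - pg) * g)
  h <- f / sum(f)
  kk <- 0:tau
  m <- cm[tau + 1L] - cm[tau + 1L - kk]
  t <- ct[tau + 1L] - ct[tau + 1L - kk]
  ti <- sum(h * (a + m) / (a + b + t))
  structure(
    list(ti = ti, k = kk, prob = h, expected_k = sum(kk * h),
         log_marginal = logz),
    class = "bnn_posterior")
}

#' @export
print.bnn_posterior <- function(x, ...) {
  cat("BNN posterior: TI =", format(x$ti, digits = 6),
      "| support E[k] =", format(x$expected_k, digits = 4), "\n")
  invisible(x)
}

#' BNN posterior by exhaustive breakpoint enumeration
#'
#' Independent reference computation of [bnn_posterior()]: enumerates all
#' `2^tau` breakpoint indicator vectors `(b_1, ..., b_tau)` (where `b_i = 1`
#' starts a new partition before observation `i`, and the last indicator
#' governs the target's block), weighs each by its
#' `p_gamma^sum(b) (1-p_gamma)^(tau-sum(b))` prior and the sequential
#' Beta-Bernoulli likelihood of the labels within its blocks, and returns the
#' posterior-weighted average of the final block's male predictive. Only
#' feasible for short sequences; refuses `tau > 20`.
#'
#' @inheritParams bnn_posterior
#' @return The posterior male probability (a single number).
#' @export
bnn_posterior_bruteforce <- function(seq, config = bnn_config()) {
  if (!inherits(config, "bnn_config"))
    stop("`config` must be a bnn_config object", call. = FALSE)
  seq <- as_neighbor_sequence(seq)
  l <- seq$labels
  w <- seq$weights
  tau <- length(l)
  a <- config$alpha
  b <- config$beta
  pg <- config$p_gamma
  if (tau == 0L) return(a / (a + b))
  if (tau > 20L)
    stop("enumeration over 2^tau configurations refused for tau > 20",
         call. = FALSE)
  B <- as.matrix(expand.grid(rep(list(c(0L, 1L)), tau)))
  nb <- nrow(B)
  nbrk <- rowSums(B)
  # prior of each breakpoint configuration (0^0 := 1 at the boundaries)
  prior <- rep(1, nb)
  if (pg > 0) prior <- prior * pg^nbrk else prior[nbrk > 0] <- 0
  if (pg < 1) prior <- prior * (1 - pg)^(tau - nbrk) else prior[nbrk < tau] <- 0
  bm <- numeric(nb)  # running male mass of the open block, per configuration
  bt <- numeric(nb)
  loglik <- numeric(nb)
  p0 <- a / (a + b)
  loglik <- loglik + log(if (l[1L] == 1) p0 else 1 - p0)
  bm <- bm + w[1L] * l[1L]
  bt <- bt + w[1L]
  if (tau >= 2L) {
    for (i in 2:tau) {
      reset <- B[, i - 1L] == 1L
      bm[reset] <- 0
      bt[reset] <- 0
      pm <- (a + bm) / (a + b + bt)
      loglik <- loglik + log(if (l[i] == 1) pm else 1 - pm)
      bm <- bm + w[i] * l[i]
      bt <- bt + w[i]
    }
  }
  reset <- B[, tau] == 1L
  bm[reset] <- 0
  bt[reset] <- 0
  pred <- (a + bm) / (a + b + bt)
  wt <- prior * exp(loglik)
  sum(wt * pred) / sum(wt)
}
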