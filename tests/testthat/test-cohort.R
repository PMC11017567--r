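# Cohort-level TI: balanced weights, leave-one-out computation, summaries,
# and IRR regression.

test_that("balanced weights equalize the total mass of each sex", {
  ann <- data.frame(sample = sprintf("S%02d", 1:4),
                    sex = c("male", "female", "male", "female"),
                    cancer_type = "A")
  expect_equal(unname(balanced_weights(ann)), rep(1, 4))  # already balanced

  ann2 <- data.frame(sample = sprintf("S%02d", 1:40),
                     sex = rep(c("male", "female"), c(30, 10)),
                     cancer_type = "A")
  w <- balanced_weights(ann2)
  expect_equal(unname(w[1:30]), rep(2 / 3, 30))
  expect_equal(unname(w[31:40]), rep(2, 10))
  expect_equal(sum(w[1:30]), sum(w[31:40]))

  # random compositions: weights positive, per-type sex totals equal
  set.seed(21)
  for (i in 1:20) {
    nm <- sample(1:50, 1)
    nf <- sample(1:50, 1)
    ann3 <- data.frame(sample = sprintf("S%03d", seq_len(nm + nf)),
                       sex = sample(rep(c("male", "female"), c(nm, nf))),
                       cancer_type = sample(c("A", "B"), nm + nf,
                                            replace = TRUE))
    ok <- all(vapply(split(ann3$sex, ann3$cancer_type),
                     function(s) all(c("male", "female") %in% s),
                     logical(1)))
    if (!ok) next
    w3 <- balanced_weights(ann3)
    expect_true(all(w3 > 0))
    for (ct in unique(ann3$cancer_type)) {
      idx <- ann3$cancer_type == ct
      expect_equal(sum(w3[idx][ann3$sex[idx] == "male"]),
                   sum(w3[idx][ann3$sex[idx] == "female"]),
                   tolerance = 1e-12)
    }
  }

  ann4 <- data.frame(sample = c("a", "b"), sex = c("male", "male"),
                     cancer_type = "A")
  expect_error(balanced_weights(ann4), "both sexes")
})

test_that("leave-one-out TI matches a hand-constructed posterior per sample", {
  cc <- two_cluster_cohort(n_per = 20, center = 50)
  ti <- compute_ti(cc$expression, cc$annotations)

  # two well-separated pure clusters: every male TI above every female TI
  expect_gt(min(ti$ti[ti$sex == "male"]), max(ti$ti[ti$sex == "female"]))

  # oracle: build each sample's neighbor sequence from raw distances and
  # call the posterior directly
  x <- setNames(as.numeric(cc$annotations$sex == "male"),
                cc$annotations$sample)
  for (s in sample(cc$annotations$sample, 8)) {
    others <- setdiff(cc$annotations$sample, s)
    d <- sqrt(colSums((cc$expression[, others, drop = FALSE] -
                         cc$expression[, s])^2))
    ord <- order(-d, others)
    want <- bnn_posterior(neighbor_sequence(x[others][ord]), bnn_config())
    expect_equal(ti$ti[ti$sample == s], want$ti)
    expect_equal(ti$support[ti$sample == s], want$expected_k)
  }
})

test_that("a single-sample cancer type falls back to the prior mean", {
  cc <- two_cluster_cohort(n_per = 3, n_genes = 5)
  cc$annotations$cancer_type[1] <- "LONE"
  expect_warning(ti <- compute_ti(cc$expression, cc$annotations),
                 "fewer than 2")
  expect_identical(ti$ti[1], 0.5)
  expect_identical(ti$support[1], 0)
})

test_that("relabeling every sex flips TI about one half", {
  cc <- two_cluster_cohort(n_per = 8, n_genes = 6, center = 3, seed = 4)
  ti1 <- compute_ti(cc$expression, cc$annotations)
  flipped <- cc$annotations
  flipped$sex <- ifelse(flipped$sex == "male", "female", "male")
  ti2 <- compute_ti(cc$expression, flipped)
  expect_equal(ti1$ti + ti2$ti, rep(1, nrow(ti1)), tolerance = 1e-12)
})

test_that("TI is invariant to sample order in the input", {
  cc <- two_cluster_cohort(n_per = 10, n_genes = 8, center = 2, seed = 9)
  ti1 <- compute_ti(cc$expression, cc$annotations)
  set.seed(1)
  perm <- sample(nrow(cc$annotations))
  ti2 <- compute_ti(cc$expression[, perm], cc$annotations[perm, ])
  m <- match(ti1$sample, ti2$sample)
  expect_equal(ti1$ti, ti2$ti[m], tolerance = 1e-14)
  expect_equal(ti1$support, ti2$support[m], tolerance = 1e-14)
})

test_that("annotation problems are reported by sample id", {
  cc <- two_cluster_cohort(n_per = 3, n_genes = 4)
  expect_error(compute_ti(cc$expression, cc$annotations[-1, ]),
               cc$annotations$sample[1])
  bad <- cc$expression
  bad[1, 1] <- Inf
  expect_error(compute_ti(bad, cc$annotations), "non-finite")
})

test_that("cohort summaries report counts, IRR and named quantiles", {
  ti <- data.frame(sample = sprintf("S%d", 1:3),
                   cancer_type = "A",
                   sex = c("male", "male", "female"),
                   ti = c(0.2, 0.4, 0.6))
  s <- summarize_cohorts(ti)
  expect_equal(s$median_ti, 0.4)
  expect_equal(s$irr, 2)
  expect_equal(s$n_male, 2L)

  # quantiles are non-decreasing and follow the linear-interpolation rule
  set.seed(5)
  ti2 <- data.frame(sample = sprintf("S%03d", 1:40), cancer_type = "B",
                    sex = sample(c("male", "female"), 40, replace = TRUE),
                    ti = stats::runif(40))
  s2 <- summarize_cohorts(ti2)
  qs <- unlist(s2[, c("q05", "q25", "median_ti", "q75", "q95")])
  expect_true(all(diff(qs) >= 0))
  expect_equal(s2$q25, unname(stats::quantile(ti2$ti, 0.25, type = 7)))

  # an external IRR table overrides the count ratio
  ext <- data.frame(cancer_type = "B", irr = 4.22)
  s3 <- summarize_cohorts(ti2, irr = ext)
  expect_equal(s3$irr, 4.22)
})

test_that("IRR regression matches the closed-form OLS oracle", {
  # collinear points: r = 1 exactly, p on the degenerate branch
  s <- data.frame(cancer_type = c("A", "B", "C"), irr = c(1, 2, 3),
                  median_ti = c(0.4, 0.5, 0.6))
  r <- irr_ti_regression(s)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.1, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-6)

  # constant response: zero slope, zero correlation
  s2 <- transform(s, median_ti = 0.5)
  r2 <- irr_ti_regression(s2)
  expect_identical(r2$slope, 0)
  expect_identical(r2$r, 0)

  # randomized cohorts against the sums-based oracle, both scales
  set.seed(14)
  s3 <- data.frame(cancer_type = sprintf("T%02d", 1:12),
                   irr = stats::runif(12, 0.3, 4),
                   median_ti = stats::runif(12, 0.3, 0.7))
  for (sc in c("linear", "log2")) {
    x <- if (sc == "log2") log2(s3$irr) else s3$irr
    want <- ols_oracle(x, s3$median_ti)
    got <- irr_ti_regression(s3, scale = sc)
    expect_equal(got$slope, want$slope, tolerance = 1e-12)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }

  expect_error(irr_ti_regression(s[1:2, ]), "at least 3")
})

test_that("neighborhood support grows with cluster tightness", {
  supports <- vapply(c(0.5, 2, 8), function(ns) {
    sim <- simulate_cohort(cohort_spec(n_samples = 80, n_genes = 300,
                                       module_size_male = 30,
                                       module_size_female = 30,
                                       mode = "poles", noise_sd = ns),
                           seed = 3)
    mean(compute_ti(sim$expression, sim$annotations)$support)
  }, numeric(1))
  expect_true(all(diff(supports) < 0))
})

test_that("a sexless-signal cohort with balanced weights centers at 0.5", {
  sim <- simulate_cohort(cohort_spec(n_samples = 200, n_genes = 500,
                                     module_size_male = 50,
                                     module_size_female = 50, effect = 0),
                         seed = 5)
  ti <- compute_ti(sim$expression, sim$annotations,
                   bnn_config(weighting = "balanced"))
  expect_lt(abs(mean(ti$ti) - 0.5), 0.05)
})
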