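# Discrimination coefficient, logistic IRLS, ROC/AUC, Youden cut-off.

test_that("discrimination coefficient: worked values, edge cases", {
  # printed-summary arithmetic (dominant frequency, P2, PD vs ET)
  expect_equal(alpha_from_summary(5.2, 1.6, 8.1, 2.0)$alpha, 2.9 / 3.6)

  set.seed(1)
  a <- rnorm(40, 5, 1)
  expect_equal(discrimination_coefficient(a, a)$alpha, 0)

  expect_equal(alpha_from_summary(1, 0.5, 0, 0.5)$alpha, 1.0)
  expect_equal(alpha_from_summary(2, 0, 2, 0)$alpha, 0)
  expect_true(alpha_from_summary(2, 0, 3, 0)$undefined)

  expect_error(discrimination_coefficient(1, c(1, 2)), "at least 2")
})

test_that("alpha is symmetric and affine-invariant", {
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1), rnorm(1), runif(1, 0.5, 2))
    b <- rnorm(sample(5:30, 1), rnorm(1), runif(1, 0.5, 2))
    d_ab <- discrimination_coefficient(a, b)$alpha
    d_ba <- discrimination_coefficient(b, a)$alpha
    expect_equal(d_ab, d_ba)
    sc <- runif(1, 0.1, 5); off <- rnorm(1)
    d_tr <- discrimination_coefficient(sc * a + off, sc * b + off)$alpha
    expect_equal(d_tr, d_ab, tolerance = 1e-10)
  }
})

test_that("logistic IRLS: symmetry, null slope, separation flag", {
  x <- rep(c(-1, 1), each = 20)
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$beta0), 1e-6)
  expect_gt(fit$beta1, 0)
  expect_true(fit$separation_detected)

  set.seed(3)
  xn <- rnorm(400)
  yn <- sample(rep(0:1, each = 200))
  fn <- fit_logistic(xn, yn)
  expect_true(fn$converged)
  expect_lt(abs(fn$beta1), 3 * fn$se_beta1)

  expect_error(fit_logistic(rnorm(10), rep(1, 10)), "both classes")
})

test_that("IRLS beats a coarse grid on a non-separable toy", {
  x <- c(-2, -1.5, -0.6, 0.4, -0.3, 0.8, 1.7, 2.2)
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  ll_fit <- logistic_ll(fit$beta0, fit$beta1, x, y)
  expect_gte(ll_fit + 1e-8, grid_best_ll(x, y, step = 0.05))
})

test_that("ROC: perfect, degenerate and hand-enumerated cases", {
  r1 <- roc_curve(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
  expect_equal(r1$auc, 1.0)
  r2 <- roc_curve(rep(2, 8), rep(0:1, 4))
  expect_equal(r2$auc, 0.5)
  r3 <- roc_curve(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(r3$auc, 0.75)
  # curve anchored at (0,0) and (1,1), monotone
  pts <- r3$points
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(1:6, n, replace = TRUE) + rnorm(n, sd = 0.2) * rbinom(n, 1, 0.5)
    expect_equal(roc_curve(s, y)$auc, mw_auc(s, y), tolerance = 1e-12)
  }
})

test_that("Youden optimiser equals the exhaustive scan, tie-break rule", {
  sep <- youden_optimal_cutoff(c(1, 2, 3, 7, 8, 9), c(0, 0, 0, 1, 1, 1))
  expect_equal(c(sep$tpr, sep$fpr, sep$acc), c(1, 0, 1))
  expect_true(sep$cutoff > 3 && sep$cutoff < 7)

  # hand-enumerated tie: PD {5,6}, ET {6,7} -> cut above 6 (lower FPR)
  tie <- youden_optimal_cutoff(c(5, 6, 6, 7), c(0, 0, 1, 1))
  expect_equal(tie$youden, 0.5)
  expect_equal(c(tie$tpr, tie$fpr), c(0.5, 0))
  expect_gt(tie$cutoff, 6)

  set.seed(5)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.3) * rbinom(n, 1, 0.5)
    got <- youden_optimal_cutoff(s, y)
    want <- brute_youden(s, y)
    expect_equal(got[c("cutoff", "tpr", "fpr", "acc", "youden")],
                 want[c("cutoff", "tpr", "fpr", "acc", "youden")])
  }
})

test_that("AUC and Youden are invariant under monotone score transforms", {
  set.seed(6)
  for (i in 1:15) {
    n <- 30
    y <- rbinom(n, 1, 0.5); y[1:2] <- 0:1
    s <- rnorm(n)
    mono <- list(function(z) exp(z), function(z) rank(z, ties.method = "min"),
                 function(z) z^3 + 2 * z)
    base_auc <- roc_curve(s, y)$auc
    base_yo <- youden_optimal_cutoff(s, y)
    for (f in mono) {
      expect_equal(roc_curve(f(s), y)$auc, base_auc, tolerance = 1e-12)
      yo <- youden_optimal_cutoff(f(s), y)
      expect_equal(c(yo$tpr, yo$fpr, yo$acc),
                   c(base_yo$tpr, base_yo$fpr, base_yo$acc))
    }
  }
})

test_that("analyze_pair: instance counts, subgroups, separation path", {
  # synthetic feature table: 50 subjects x 10 segments, posture P2
  set.seed(7)
  subj <- function(id, group, stage, mu, sd) {
    data.frame(subject_id = id, group = group, stage = stage, posture = "P2",
               segment_index = 1:10, segment_length_s = 30,
               mav = 1, ln_mav = rnorm(10, mu, sd),
               domfreq_psd = rnorm(10, mu + 5, sd),
               domfreq_bispec = rnorm(10, mu + 5, sd))
  }
  tabs <- list()
  for (i in 1:13) tabs <- c(tabs, list(subj(paste0("PD1-", i), "PD", "S1", -0.3, 1.8)))
  for (i in 1:13) tabs <- c(tabs, list(subj(paste0("PD2-", i), "PD", "S2", -0.3, 1.8)))
  for (i in 1:12) tabs <- c(tabs, list(subj(paste0("ET1-", i), "ET", "S1", -2.1, 0.6)))
  for (i in 1:12) tabs <- c(tabs, list(subj(paste0("ET2-", i), "ET", "S2", -2.1, 0.6)))
  ft <- do.call(rbind, tabs)
  res <- analyze_pair(ft, "ln_mav", c("PD", "ET"), "P2")
  expect_identical(res$roc$n_instances, 500L)
  expect_identical(res$roc$positive_class, "ET")

  sub <- analyze_pair(ft, "ln_mav", c("PD1", "ET1"), "P2")
  expect_identical(sub$roc$n_instances, 250L)

  ft2 <- ft; ft2$stage <- NA_character_
  expect_error(analyze_pair(ft2, "ln_mav", c("PD1", "ET1"), "P2"), "stage")
  expect_error(analyze_pair(ft, "ln_mav", c("PD", "ET"), "P1"), "empty selection")

  # complete separation still yields a sane ROC (AUC 1, Youden perfect)
  ftc <- ft
  ftc$ln_mav <- ifelse(ftc$group == "ET", ftc$ln_mav - 50, ftc$ln_mav + 50)
  resc <- analyze_pair(ftc, "ln_mav", c("PD", "ET"), "P2")
  expect_true(resc$roc$separation_detected)
  expect_equal(resc$roc$auc, 1.0)
  expect_equal(c(resc$roc$tpr, resc$roc$fpr), c(1, 0))
})

test_that("logistic ranking and raw-feature ranking give the same ROC", {
  set.seed(8)
  x <- c(rnorm(40, 0), rnorm(40, 1.2))
  y <- rep(0:1, each = 40)
  fit <- fit_logistic(x, y)
  p <- stats::plogis(fit$beta0 + fit$beta1 * x)
  expect_equal(roc_curve(p, y)$auc, roc_curve(x, y)$auc, tolerance = 1e-12)
})
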