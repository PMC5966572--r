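#' Discrimination coefficient between two groups
#'
#' `alpha = |mean_A - mean_B| / (sd_A + sd_B)` with sample (n-1) standard
#' deviations.  Values above the differentiation level (0.7 by
#' convention) mark a feature/condition that separates the groups well.
#' The statistic is symmetric in the two groups and invariant under a
#' common affine rescaling of the feature.
#'
#' @param values_a,values_b Feature values of the two groups (>= 2 each).
#' @param level Differentiation level (default 0.7).
#' @param feature_name,group_a,group_b Labels carried on the result.
#' @return An object of class `discrimination_result` with fields
#'   `mean_a, sd_a, mean_b, sd_b, alpha, passes_level, undefined`.
#' @export
discrimination_coefficient <- function(values_a, values_b, level = 0.7,
                                       feature_name = "feature",
                                       group_a = "A", group_b = "B") {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 finite values")
  m_a <- mean(values_a); s_a <- stats::sd(values_a)
  m_b <- mean(values_b); s_b <- stats::sd(values_b)
  res <- alpha_from_summary(m_a, s_a, m_b, s_b)
  structure(list(feature_name = feature_name,
                 group_a = group_a, group_b = group_b,
                 n_a = length(values_a), n_b = length(values_b),
                 mean_a = m_a, sd_a = s_a, mean_b = m_b, sd_b = s_b,
                 alpha = res$alpha, undefined = res$undefined,
                 level = level,
                 passes_level = is.finite(res$alpha) && res$alpha > level),
            class = "discrimination_result")
}

#' Discrimination coefficient from printed summary statistics
#'
#' The same statistic computed directly from group means and SDs, e.g.
#' from a published summary table.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group summaries.
#' @return List with `alpha` and an `undefined` flag (`TRUE` when both
#'   SDs are zero but the means differ).
#' @export
alpha_from_summary <- function(mean_a, sd_a, mean_b, sd_b) {
  denom <- sd_a + sd_b
  num <- abs(mean_a - mean_b)
  if (denom == 0) {
    if (num == 0) return(list(alpha = 0, undefined = FALSE))
    return(list(alpha = Inf, undefined = TRUE))
  }
  list(alpha = num / denom, undefined = FALSE)
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "<discrimination> %s, %s (%.3g +/- %.3g) vs %s (%.3g +/- %.3g): alpha = %.3f %s\n",
    x$feature_name, x$group_a, x$mean_a, x$sd_a, x$group_b, x$mean_b, x$sd_b,
    x$alpha, if (x$passes_level) sprintf("(> %.2f)", x$level) else ""))
  invisible(x)
}

#' Binary logistic regression on a single feature (IRLS)
#'
#' Maximum-likelihood fit of `P(positive | x) = plogis(b0 + b1 x)` by
#' iteratively reweighted least squares, with a deviance-change tolerance
#' of 1e-8 and at most 100 iterations.  Complete separation (a feature
#' threshold perfectly splitting the classes) makes the MLE diverge; it
#' is detected and flagged, the coefficients are reported at the capped
#' magnitude reached, and downstream ROC analysis should rank by the raw
#' feature (which gives the identical curve by monotonicity).
#'
#' @param features Numeric predictor values.
#' @param labels 0/1 vector (1 = positive class) or a factor/character
#'   vector combined with `positive`.
#' @param positive Label treated as the positive class when `labels` is
#'   not numeric.
#' @param max_iter,tol IRLS controls.
#' @return List with `beta0`, `beta1`, their standard errors, `deviance`,
#'   `converged`, `separation_detected`, `n_iter`, `fitted`.
#' @export
fit_logistic <- function(features, labels, positive = NULL,
                         max_iter = 100, tol = 1e-8) {
  y <- as_binary_labels(labels, positive)
  x <- as.numeric(features)
  stopifnot(length(x) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 instances per class")
  separation <- is_separable(x, y)
  scale_x <- stats::sd(x); if (scale_x == 0) scale_x <- 1
  beta <- c(stats::qlogis(mean(y)), 0)
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  X <- cbind(1, x)
  for (iter in seq_len(max_iter)) {
    eta <- X %*% beta
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * as.vector(w))
    beta <- solve(XtW %*% X, XtW %*% z)
    mu <- stats::plogis(X %*% beta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(dev_old - dev) < tol) { converged <- TRUE; break }
    dev_old <- dev
    # under separation the deviance decreases monotonically while the
    # slope diverges; stop once the standardised slope is clearly capped
    if (abs(beta[2]) * scale_x > 30) break
  }
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- t(X * w) %*% X
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) c(NA, NA))
  list(beta0 = beta[1], beta1 = beta[2],
       se_beta0 = se[1], se_beta1 = se[2],
       deviance = dev, converged = converged && !separation,
       separation_detected = separation, n_iter = iter,
       fitted = mu)
}

as_binary_labels <- function(labels, positive = NULL) {
  if (is.numeric(labels) && all(labels %in% c(0, 1)) && is.null(positive)) {
    return(as.integer(labels))
  }
  if (is.null(positive)) stop("positive class label required")
  as.integer(labels == positive)
}

is_separable <- function(x, y) {
  r0 <- range(x[y == 0]); r1 <- range(x[y == 1])
  r0[2] < r1[1] || r1[2] < r0[1]
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct score values (plus
#' sentinels), classifying an instance positive when its score is at or
#' above the threshold.  TPR/FPR per point, AUC by trapezoidal
#' integration; with ties grouped at one threshold this equals the
#' Mann-Whitney rank statistic (ties counted 1/2) exactly.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Class labels; see [fit_logistic()].
#' @param positive Positive-class label.
#' @return List of class `roc_analysis` with `points` (data.frame
#'   `threshold, fpr, tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  np <- sum(y == 1); nn <- sum(y == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1), 0) / np
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0), 0) / nn
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, positive_class = positive),
            class = "roc_analysis")
}

#' Youden-index optimal cut-off
#'
#' Evaluates TPR - FPR at every candidate threshold (midpoints between
#' adjacent distinct sorted scores, plus the two infinite sentinels) and
#' returns the maximiser, with ties broken by higher accuracy, then lower
#' FPR, then lower cut-off.  An instance is classified positive when its
#' score is at or above the cut-off.
#'
#' @inheritParams roc_curve
#' @return List with `cutoff` (score units), `tpr`, `fpr`, `acc`,
#'   `youden`.
#' @export
youden_optimal_cutoff <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  np <- sum(y == 1); nn <- sum(y == 0)
  n <- length(y)
  best <- NULL
  for (cc in cand) {
    pred <- scores >= cc
    tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
    tpr <- tp / np; fpr <- fp / nn
    acc <- (tp + (nn - fp)) / n
    j <- tpr - fpr
    cur <- list(cutoff = cc, tpr = tpr, fpr = fpr, acc = acc, youden = j)
    if (is.null(best) ||
        j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 &&
         (acc > best$acc + 1e-12 ||
          (abs(acc - best$acc) <= 1e-12 &&
           (fpr < best$fpr - 1e-12 ||
            (abs(fpr - best$fpr) <= 1e-12 && cc < best$cutoff)))))) {
      best <- cur
    }
  }
  best
}

#' Run the full differentiation analysis for one feature / pair / posture
#'
#' Selects the segment rows of the requested group pair and posture from
#' a feature table (each segment is one instance), computes the
#' discrimination coefficient, fits the single-feature binary logistic
#' model (positive class: ET), and derives the ROC curve, AUC and the
#' Youden-optimal cut-off mapped back to feature units.  ROC ranking uses
#' the raw feature oriented by the sign of the fitted slope, which is
#' identical to ranking by the fitted probability (strictly monotone
#' map) and stays well-defined under complete separation.
#'
#' @param feature_table Output of [extract_features()].
#' @param feature_name Column to analyse (`"ln_mav"`, `"domfreq_psd"` or
#'   `"domfreq_bispec"`).
#' @param group_pair Two labels among `PD, ET, PD1, PD2, ET1, ET2`
#'   (subgroup labels require the `stage` column).
#' @param posture `"P1"` or `"P2"`.
#' @param positive Positive class (default `"ET"`: the diagnosis
#'   targeted).
#' @param level Differentiation level for the discrimination coefficient.
#' @return List with `discrimination` (a `discrimination_result`) and
#'   `roc` (logistic fit, ROC points, AUC, cut-off with TPR/FPR/ACC).
#' @export
analyze_pair <- function(feature_table, feature_name,
                         group_pair = c("PD", "ET"), posture = "P2",
                         positive = "ET", level = 0.7) {
  stopifnot(length(group_pair) == 2)
  sel <- lapply(group_pair, function(g) select_group(feature_table, g, posture))
  n_sel <- vapply(sel, nrow, 0L)
  if (any(n_sel == 0)) {
    stop(sprintf("empty selection for group %s, posture %s",
                 group_pair[which(n_sel == 0)[1]], posture))
  }
  va <- sel[[1]][[feature_name]]
  vb <- sel[[2]][[feature_name]]
  if (is.null(va)) stop("unknown feature column: ", feature_name)
  disc <- discrimination_coefficient(va, vb, level = level,
                                     feature_name = feature_name,
                                     group_a = group_pair[1],
                                     group_b = group_pair[2])
  pos_side <- if (startsWith(positive, group_pair[1])) 1L else 2L
  x <- c(va, vb)
  ylab <- rep(group_pair, times = c(length(va), length(vb)))
  keep <- is.finite(x)
  x <- x[keep]; ylab <- ylab[keep]
  y <- as.integer(seq_along(ylab) %in% which(ylab == group_pair[pos_side]))
  fit <- fit_logistic(x, y)
  dir <- if (fit$beta1 >= 0) 1 else -1
  scores <- dir * x
  roc <- roc_curve(scores, y, positive = NULL)
  yo <- youden_optimal_cutoff(scores, y)
  cutoff_feature <- dir * yo$cutoff
  cutoff_prob <- if (is.finite(cutoff_feature)) {
    stats::plogis(fit$beta0 + fit$beta1 * cutoff_feature)
  } else NA_real_
  structure(list(
    discrimination = disc,
    roc = list(beta0 = fit$beta0, beta1 = fit$beta1,
               converged = fit$converged,
               separation_detected = fit$separation_detected,
               roc_points = roc$points, auc = roc$auc,
               youden_cutoff_feature = cutoff_feature,
               youden_cutoff_prob = cutoff_prob,
               direction = if (dir > 0) "positive above cutoff" else "positive below cutoff",
               tpr = yo$tpr, fpr = yo$fpr, acc = yo$acc,
               positive_class = positive,
               n_instances = length(x))),
    class = "pair_analysis")
}

select_group <- function(feature_table, group, posture) {
  ft <- feature_table[feature_table$posture == posture, , drop = FALSE]
  if (group %in% c("PD", "ET")) {
    return(ft[ft$group == group, , drop = FALSE])
  }
  base <- substr(group, 1, 2)
  stage <- paste0("S", substr(group, 3, 3))
  if (is.null(ft$stage) || all(is.na(ft$stage))) {
    stop("feature table lacks stage labels needed for subgroup ", group)
  }
  ft[ft$group == base & ft$stage == stage, , drop = FALSE]
}
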