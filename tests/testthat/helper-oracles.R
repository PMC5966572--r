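# Independent oracles and tiny signal builders shared across tests.

# Brute-force triple-sum third-order cumulant (reference implementation,
# O(L^2 M) with explicit index checks).
brute_cumulant <- function(x, L) {
  M <- length(x)
  C <- matrix(0, 2 * L + 1, 2 * L + 1)
  for (k in -L:L) for (l in -L:L) {
    s <- 0
    for (n in 1:M) {
      if (n + k >= 1 && n + k <= M && n + l >= 1 && n + l <= M) {
        s <- s + x[n] * x[n + k] * x[n + l]
      }
    }
    C[k + L + 1, l + L + 1] <- s / M
  }
  C
}

# Mann-Whitney AUC with ties counted 1/2.
mw_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every threshold position (including
# between equal values), with the package's tie-break rule.
brute_youden <- function(scores, y) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  np <- sum(y == 1); nn <- sum(y == 0)
  best <- NULL
  for (cc in cand) {
    pred <- scores >= cc
    tpr <- sum(pred & y == 1) / np
    fpr <- sum(pred & y == 0) / nn
    acc <- (sum(pred & y == 1) + sum(!pred & y == 0)) / length(y)
    j <- tpr - fpr
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 &&
         (acc > best$acc + 1e-12 ||
          (abs(acc - best$acc) <= 1e-12 &&
           (fpr < best$fpr - 1e-12 ||
            (abs(fpr - best$fpr) <= 1e-12 && cc < best$cutoff)))))) {
      best <- list(cutoff = cc, tpr = tpr, fpr = fpr, acc = acc, youden = j)
    }
  }
  best
}

# Log-likelihood of the single-feature logistic model.
logistic_ll <- function(beta0, beta1, x, y) {
  eta <- beta0 + beta1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Best log-likelihood over a (beta0, beta1) grid (brute-force oracle).
grid_best_ll <- function(x, y, lim = 5, step = 0.05) {
  g <- seq(-lim, lim, by = step)
  best <- -Inf
  for (b0 in g) {
    eta <- outer(g, x) + b0                       # |g| x n
    ll <- rowSums(sweep(eta, 2, y, "*") - log1p(exp(eta)))
    best <- max(best, max(ll))
  }
  best
}

# Noise-free phase-coupled harmonic stack at fundamental f0 (unit
# fundamental amplitude, default harmonic ratios).
coupled_stack <- function(f0, t, amps = c(1, 0.4, 0.15), phi0 = 0) {
  s <- numeric(length(t))
  for (h in seq_along(amps)) s <- s + amps[h] * cos(h * (2 * pi * f0 * t + phi0))
  s
}

# A quiet deterministic group model for fast end-to-end tests.
clean_model <- function(f0 = 5, ln = 0) {
  group_signal_model(f0, 0, ln, 0, freq_jitter_sd = 0, amp_mod_depth = 0,
                     drift_amp = 0, mains_amp = 0, noise_sd = 0)
}
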