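# Independent brute-force oracles, written from the defining formulas and
# deliberately kept separate from the package's implementations.

# Mann-Whitney AUC: mean over all positive x negative pairs with half credit
# for ties.
oracle_auc <- function(score, label) {
  sp <- score[label == 1]
  sn <- score[label == 0]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Literal tau-b: O(n^2) sign sum over pairs, tie-group-corrected denominator.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) {
    s <- s + sum(sign(x[i] - x[(i + 1):n]) * sign(y[i] - y[(i + 1):n]))
  }
  half <- function(k) k * (k - 1) / 2
  den1 <- half(n) - sum(half(as.numeric(table(x))))
  den2 <- half(n) - sum(half(as.numeric(table(y))))
  s / sqrt(den1 * den2)
}

# Truncated AUC by fine-grid quadrature of the piecewise-linear empirical
# ROC, built directly from threshold sweeps (not via roc_curve()).
oracle_truncated_auc <- function(score, label, cap, grid_n = 20001L) {
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score[label == 1] >= t), 0)
  fpr <- vapply(thr, function(t) mean(score[label == 0] >= t), 0)
  f <- c(0, fpr)
  t <- c(0, tpr)
  xs <- seq(0, cap, length.out = grid_n)
  ys <- stats::approx(f, t, xout = xs, ties = "ordered", rule = 2)$y
  h <- cap / (grid_n - 1)
  (sum(ys) - (ys[1] + ys[grid_n]) / 2) * h / cap
}

# Literal windowed-posterior rule, one grid point at a time: epsilon window,
# then grow by the nearest distinct score value (whole tie group at a time,
# distance ties toward the lower score) until the count rule is met.
oracle_local_posterior <- function(score, label, grid, window_fraction = 0.05,
                                   min_fraction = 0.10, max_count = 50) {
  n <- length(score)
  q <- stats::quantile(score, c(0.05, 0.95), names = FALSE)
  eps <- window_fraction * (q[2] - q[1])
  k <- min(ceiling(min_fraction * n), max_count)
  vapply(grid, function(s) {
    left <- s - eps
    right <- s + eps
    repeat {
      inside <- which(score >= left & score <= right)
      if (length(inside) >= k) break
      below <- score[score < left]
      above <- score[score > right]
      dl <- if (length(below)) s - max(below) else Inf
      dr <- if (length(above)) min(above) - s else Inf
      if (dl <= dr) left <- max(below) else right <- min(above)
    }
    mean(label[inside])
  }, 0)
}

random_tied_scores <- function(n, n_levels = max(2L, n %/% 3L)) {
  score <- sample(seq_len(n_levels), n, replace = TRUE) +
    ifelse(stats::runif(n) < 0.5, 0, 0.25)
  label <- stats::rbinom(n, 1L, 0.5)
  if (all(label == 1)) label[1] <- 0L
  if (all(label == 0)) label[1] <- 1L
  list(score = score, label = label)
}
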