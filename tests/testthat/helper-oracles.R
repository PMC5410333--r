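# Independent oracles used across the suite.  Each is a deliberately naive
# implementation (loops, exhaustive enumeration, generic numerical
# optimisation) kept separate from the vectorised package code it checks.

# Joint (block, m, t) binning by explicit per-cell loops.
oracle_block_histogram <- function(xi_field, gamma_field, params) {
  M <- params$M; T <- params$T; V <- params$V; H <- params$H
  L <- nrow(xi_field); W <- ncol(xi_field)
  rs <- L %/% V; cs <- W %/% H
  counts <- numeric(M * T * V * H)
  for (i in seq_len(L)) {
    for (j in seq_len(W)) {
      m <- min(floor((xi_field[i, j] + pi / 2) / (pi / M)), M - 1)
      t <- floor(gamma_field[i, j] / (2 * pi / T) + 0.5) %% T
      v <- min((i - 1) %/% rs, V - 1)
      h <- min((j - 1) %/% cs, H - 1)
      bin <- (v * H + h) * M * T + m * T + t + 1
      counts[bin] <- counts[bin] + 1
    }
  }
  counts
}

# Rank/pair-counting AUC: P(score_pos > score_neg), ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}

# Fixed-P objective of the DVM inner problem (Xk rows = neighbours).
oracle_objective <- function(beta, y, Xk, p, L, delta, gamma) {
  r <- y - drop(t(Xk) %*% beta)
  sum(p * r^2) + delta * sum(beta^2) + drop(gamma * t(beta) %*% L %*% beta)
}

# Generic numerical minimiser of the fixed-P objective.  Arguments are
# bound in a closure: optim() partially matches stray named arguments
# (e.g. `p` against `par`).
oracle_minimize_beta <- function(y, Xk, p, L, delta, gamma) {
  k <- nrow(Xk)
  stats::optim(rep(0, k),
               function(b) oracle_objective(b, y, Xk, p, L, delta, gamma),
               method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))$par
}

# Mean absolute difference between each cell and its 8 replicate-padded
# neighbours; the local-gradient statistic the texture regimes control.
mean_neighbor_absdiff <- function(m) {
  L <- nrow(m); W <- ncol(m)
  pad <- m[c(1, seq_len(L), L), c(1, seq_len(W), W)]
  tot <- 0
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      tot <- tot + mean(abs(pad[seq_len(L) + 1 + dr, seq_len(W) + 1 + dc] - m))
    }
  }
  tot / 8
}

random_intensity_matrix <- function(L, W = 20) {
  matrix(runif(L * W, 0.01, 0.99), L, W)
}
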