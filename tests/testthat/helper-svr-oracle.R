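# Independent brute-force solver for the epsilon-SVR dual, used as an oracle
# on tiny problems. Works directly on the dual in gamma_i = alpha_i -
# alpha_i^*:
#   minimize 0.5 t(g) K g - t(y) g + eps * sum(|g|)
#   subject to sum(g) = 0, |g_i| <= C
# by exhaustive pairwise coordinate descent (each pair update solves the
# piecewise-quadratic 1-D subproblem exactly), then recovers the offset from
# the KKT conditions. No part of this is shared with the package's SVR path.

svr_dual_oracle <- function(K, y, C, eps, tol = 1e-12, max_sweeps = 5000) {
  n <- length(y)
  g <- rep(0, n)
  obj <- function(g) 0.5 * sum(g * (K %*% g)) - sum(y * g) + eps * sum(abs(g))
  cur <- obj(g)
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- g[i] + g[j]
      Kg <- as.numeric(K %*% g)
      ci <- Kg[i] - K[i, i] * g[i] - K[i, j] * g[j]
      cj <- Kg[j] - K[j, i] * g[i] - K[j, j] * g[j]
      eta <- K[i, i] + K[j, j] - 2 * K[i, j]
      lo <- max(-C, s - C)
      hi <- min(C, s + C)
      if (lo > hi) next
      cand <- c(lo, hi)
      if (lo < 0 && hi > 0) cand <- c(cand, 0)
      if (lo < s && hi > s) cand <- c(cand, s)
      # unconstrained minimizer for each sign pattern of (g_i, s - g_i)
      for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
        if (eta <= 1e-14) next
        gi <- (y[i] - y[j] - ci + cj + (K[j, j] - K[i, j]) * s -
                 eps * (s1 - s2)) / eta
        if (gi >= lo - 1e-15 && gi <= hi + 1e-15)
          cand <- c(cand, min(max(gi, lo), hi))
      }
      best_v <- Inf; best_gi <- g[i]
      for (gi in cand) {
        gtry <- g; gtry[i] <- gi; gtry[j] <- s - gi
        v <- obj(gtry)
        if (v < best_v - 0) { best_v <- v; best_gi <- gi }
      }
      if (best_v < cur - tol) {
        g[i] <- best_gi; g[j] <- s - best_gi
        cur <- best_v
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  # offset from KKT: free points give equalities, bounded points inequalities
  Kg <- as.numeric(K %*% g)
  lo_b <- -Inf; hi_b <- Inf; eqs <- numeric(0)
  tol_b <- 1e-8 * max(C, 1)
  for (i in seq_len(n)) {
    if (g[i] > tol_b && g[i] < C - tol_b) eqs <- c(eqs, y[i] - Kg[i] - eps)
    else if (g[i] < -tol_b && g[i] > -C + tol_b) eqs <- c(eqs, y[i] - Kg[i] + eps)
    else if (abs(g[i]) <= tol_b) {
      lo_b <- max(lo_b, y[i] - Kg[i] - eps)
      hi_b <- min(hi_b, y[i] - Kg[i] + eps)
    } else if (g[i] >= C - tol_b) lo_b <- max(lo_b, y[i] - Kg[i] - eps)
    else hi_b <- min(hi_b, y[i] - Kg[i] + eps)
  }
  b <- if (length(eqs)) mean(eqs) else (lo_b + hi_b) / 2
  list(gamma = g, b = b,
       predict = function(Knew) as.numeric(Knew %*% g) + b)
}

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
  exp(-gamma * pmax(d2, 0))
}
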