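# Independent oracles, coded from first principles with plain loops so they
# share no code path with the package implementations they check.

# Kullback-Leibler specialization d' per column: availability q from row
# marginals, d_max = log(1/min positive q), d_min = 0.
dprime_oracle <- function(m, margin = "columns") {
  m <- as.matrix(m)
  if (margin == "rows") m <- t(m)
  res <- rep(NA_real_, ncol(m))
  names(res) <- colnames(m)
  grand <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    grand <- grand + m[i, j]
  if (grand == 0) return(res)
  row_tot <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) row_tot[i] <- sum(m[i, ])
  if (nrow(m) == 1L) {
    for (j in seq_len(ncol(m))) if (m[1, j] > 0) res[j] <- 0
    return(res)
  }
  q <- row_tot / grand
  qpos <- q[q > 0]
  dmax <- log(1 / min(qpos))
  for (j in seq_len(ncol(m))) {
    cj <- sum(m[, j])
    if (cj == 0) next
    d <- 0
    for (i in seq_len(nrow(m))) {
      if (m[i, j] > 0) {
        pij <- m[i, j] / cj
        d <- d + pij * log(pij / q[i])
      }
    }
    res[j] <- if (dmax > 0) min(1, max(0, d / dmax)) else 0
  }
  res
}

# all permutations of 1..n as a list (recursive, independent of the package)
all_perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms_oracle(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Clarke's ANOSIM R from the definition, by explicit loops over pairs
anosim_R_oracle <- function(d, g) {
  n <- nrow(d)
  dv <- c(); same <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dv <- c(dv, d[j, i]); same <- c(same, g[i] == g[j])
  }
  rk <- rank(dv)
  m <- length(dv)
  (mean(rk[!same]) - mean(rk[same])) / (m / 2)
}

# exhaustive-permutation ANOSIM p: fraction of relabelings (including the
# identity) whose R is >= the observed R
anosim_exact_oracle <- function(d, g) {
  obs <- anosim_R_oracle(d, g)
  stats <- vapply(all_perms_oracle(length(g)), function(ix)
    anosim_R_oracle(d, g[ix]), numeric(1))
  list(R = obs, p = mean(stats >= obs - 1e-12))
}

# one-way PERMANOVA via Gower-centered inner products and the hat matrix,
# a linear-algebra route disjoint from the package's pairwise-sum route
permanova_oracle <- function(d, g) {
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~ 0 + factor(g))
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  ssb <- sum(diag(H %*% G %*% H))
  sst <- sum(diag(G))
  a <- length(unique(g))
  list(F = (ssb / (a - 1)) / ((sst - ssb) / (n - a)), R2 = ssb / sst)
}

permanova_exact_oracle <- function(d, g) {
  obs <- permanova_oracle(d, g)$F
  stats <- vapply(all_perms_oracle(length(g)), function(ix)
    permanova_oracle(d, g[ix])$F, numeric(1))
  list(F = obs, p = mean(stats >= obs - 1e-12))
}

# Spearman rho as Pearson on average ranks, via explicit moment sums
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# exact expected richness of a without-replacement subsample of depth d
# (hypergeometric inclusion probabilities)
expected_sobs_oracle <- function(x, d) {
  N <- sum(x)
  sum(1 - exp(lchoose(N - x, d) - lchoose(N, d)))
}

# Welch t, Satterthwaite dof and two-sided p from the textbook formulas
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof))
}
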