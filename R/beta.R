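#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, computed between
#' all pairs of samples (columns).
#'
#' @param table [otu_table] with no all-zero samples.
#' @return symmetric matrix of class `dist_matrix` with zero diagonal and
#'   entries in \eqn{[0, 1]}, sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  stopifnot(is_otu_table(table))
  m <- as_counts(table)
  if (any(colSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  class(d) <- c("dist_matrix", class(matrix()))
  d
}

as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d)) || any(diag(d) != 0))
    stop("expected a symmetric dissimilarity matrix with zero diagonal")
  d
}

#' Kruskal stress-1 of a configuration
#'
#' Stress-1 between a set of dissimilarities and the interpoint distances
#' of a configuration, using monotone (isotonic) regression of the
#' configuration distances on the dissimilarity order (ties handled by the
#' primary approach: tied dissimilarities are free to untie).
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param coords numeric matrix of coordinates, rows aligned with `d`.
#' @return stress-1 in \eqn{[0, 1]}.
#' @export
kruskal_stress <- function(d, coords) {
  d <- as_dist_matrix(d)
  dd <- d[lower.tri(d)]
  conf <- as.matrix(stats::dist(coords))[lower.tri(d)]
  o <- order(dd, conf)  # primary tie treatment: within ties, follow config
  fit <- stats::isoreg(conf[o])$yf
  sqrt(sum((conf[o] - fit)^2) / sum(conf^2))
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 with vegan's `monoMDS` engine, keeping the
#' best configuration over `n_restarts` random starts (the first start is
#' monoMDS's default metric-scaling initialization).
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param k target dimension (default 2).
#' @param n_restarts number of starts.
#' @param max_iter,tol iteration cap and convergence tolerance per start.
#' @param seed integer seed for the random starts.
#' @return object of class `nmds_fit`: list with `coordinates` (n x k),
#'   `stress`, `converged`, `n_restarts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 50, max_iter = 300, tol = 1e-6,
                 seed = 1) {
  d <- as_dist_matrix(d)
  if (nrow(d) < 4) stop("NMDS needs at least 4 samples")
  dd <- stats::as.dist(d)
  if (max(dd) == min(dd))
    warning("all dissimilarities equal; ordination is degenerate")
  withr::with_seed(seed, {
    best <- vegan::monoMDS(dd, k = k, maxit = max_iter, sfgrmin = tol)
    for (r in seq_len(max(0, n_restarts - 1))) {
      init <- matrix(stats::runif(nrow(d) * k, -1, 1), nrow(d), k)
      fit <- vegan::monoMDS(dd, y = init, k = k, maxit = max_iter,
                            sfgrmin = tol)
      if (fit$stress < best$stress) best <- fit
    }
  })
  coords <- best$points
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords, stress = best$stress,
                 converged = best$iters < best$maxits,
                 n_restarts = n_restarts, seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat("NMDS ordination: ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates), " dimensions, stress-1 = ",
      signif(x$stress, 4), " (best of ", x$n_restarts, " starts)\n",
      sep = "")
  invisible(x)
}

#' @export
plot.nmds_fit <- function(x, groups = NULL, ...) {
  co <- x$coordinates
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(co[, 1], co[, 2], col = col, pch = 19,
                 xlab = "NMDS1", ylab = "NMDS2",
                 main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}

perm_indices <- function(n, n_perm, seed) {
  if (identical(n_perm, "exact")) {
    if (n > 8) stop("exact permutation only supported for n <= 8")
    pm <- permutation_matrix(n)
    list(perms = pm, exact = TRUE)
  } else {
    withr::with_seed(seed, {
      pm <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                     integer(n)))
    })
    list(perms = pm, exact = FALSE)
  }
}

permutation_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutation_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

anosim_stat <- function(rank_d, groups) {
  sm <- outer(groups, groups, "==")
  same <- sm[lower.tri(sm)]
  rb <- mean(rank_d[!same])
  rw <- mean(rank_d[same])
  m <- length(rank_d)
  (rb - rw) / (m / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's R: the difference between mean between-group and mean
#' within-group dissimilarity ranks, scaled by `M / 2` with
#' `M = n(n - 1) / 2`, so that R is 1 under perfect separation and near 0
#' under no structure. Significance by permuting group labels; the p-value
#' convention is `(count of permuted R >= observed + 1) / (n_perm + 1)`.
#' With `n_perm = "exact"` all `n!` relabelings are enumerated and
#' `p = #(R_perm >= R_obs) / n!`.
#'
#' @param d dissimilarity matrix (or `dist`).
#' @param groups grouping factor; at least 2 groups of at least 2 members.
#' @param n_perm number of random permutations (default 999) or `"exact"`.
#' @param seed integer seed.
#' @return one-row data.frame: statistic (R), p, n_perm, exact flag.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_dist_matrix(d)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  n <- nrow(d)
  lt <- lower.tri(d)
  rank_d <- rank(d[lt])
  g <- as.integer(groups)
  obs <- anosim_stat(rank_d, g)
  pi <- perm_indices(n, n_perm, seed)
  perm_stats <- apply(pi$perms, 1L, function(ix) anosim_stat(rank_d, g[ix]))
  p <- if (pi$exact) mean(perm_stats >= obs - 1e-12)
       else (sum(perm_stats >= obs - 1e-12) + 1) / (length(perm_stats) + 1)
  data.frame(statistic = obs, p = p, n_perm = nrow(pi$perms),
             exact = pi$exact)
}

permanova_ss <- function(d2, g) {
  n <- nrow(d2)
  lt <- lower.tri(d2)
  ss_total <- sum(d2[lt]) / n
  ss_within <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' One-way PERMANOVA
#'
#' Distance-based permutational multivariate analysis of variance for a
#' single factor: `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` from
#' within-group pairs (each group scaled by its size), pseudo-F =
#' `(SS_between / (a - 1)) / (SS_within / (n - a))` and
#' `R^2 = SS_between / SS_total`. Significance by permuting group labels
#' with the `(count + 1) / (n_perm + 1)` convention, or exhaustively with
#' `n_perm = "exact"`. A fully degenerate distance matrix (`SS_total = 0`)
#' is reported as `R^2 = 0, p = 1`.
#'
#' @inheritParams anosim
#' @return one-row data.frame: statistic (pseudo-F), r_squared, p, n_perm,
#'   exact flag.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_dist_matrix(d)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  n <- nrow(d)
  a <- nlevels(groups)
  g <- as.integer(groups)
  d2 <- d^2
  ss <- permanova_ss(d2, g)
  if (ss["total"] <= 0)
    return(data.frame(statistic = NA_real_, r_squared = 0, p = 1,
                      n_perm = 0L, exact = FALSE))
  fstat <- function(s) unname((s["between"] / (a - 1)) /
                                (s["within"] / (n - a)))
  obs <- fstat(ss)
  r2 <- unname(ss["between"] / ss["total"])
  pi <- perm_indices(n, n_perm, seed)
  perm_stats <- apply(pi$perms, 1L, function(ix)
    fstat(permanova_ss(d2, g[ix])))
  p <- if (pi$exact) mean(perm_stats >= obs - 1e-12)
       else (sum(perm_stats >= obs - 1e-12) + 1) / (length(perm_stats) + 1)
  data.frame(statistic = obs, r_squared = r2, p = p,
             n_perm = nrow(pi$perms), exact = pi$exact)
}
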