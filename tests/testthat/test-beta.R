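test_that("Bray-Curtis matches hand computation and bounds", {
  tab <- toy_table(cbind(c(6, 0, 2), c(2, 2, 0), c(6, 0, 2), c(0, 5, 0)))
  d <- bray_curtis(tab)
  expect_equal(d["S1", "S2"], 1 - 4 / 12)
  expect_equal(d["S1", "S3"], 0)       # identical columns
  expect_equal(d["S1", "S4"], 1)       # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_error(bray_curtis(toy_table(cbind(c(1, 1), c(0, 0)))), "all-zero")
})

test_that("NMDS recovers a 2-D Euclidean configuration with low stress", {
  withr::with_seed(2, pts <- matrix(rnorm(10), 5, 2))
  d <- as.matrix(dist(pts))
  fit <- nmds(d, k = 2, n_restarts = 10, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_equal(dim(fit$coordinates), c(5L, 2L))
})

test_that("duplicated samples land on coincident coordinates", {
  withr::with_seed(3, pts <- matrix(rnorm(12), 6, 2))
  pts[2, ] <- pts[1, ]
  d <- as.matrix(dist(pts))
  fit <- nmds(d, n_restarts = 10, seed = 1)
  # a zero dissimilarity is the smallest rank, so the duplicate pair must
  # end up as the closest pair of the configuration
  cd <- as.matrix(dist(fit$coordinates))
  dup <- cd[1, 2]
  others <- cd[lower.tri(cd)]
  expect_lte(dup, min(others[others != dup | duplicated(others)]) + 1e-8)
  expect_equal(dup, min(cd[lower.tri(cd)]))
})

test_that("stress is invariant under orthogonal transforms and rescaling", {
  withr::with_seed(5, pts <- matrix(rnorm(16), 8, 2))
  d0 <- as.matrix(dist(pts)) + 0.05  # non-embeddable perturbation
  diag(d0) <- 0
  fit <- nmds(d0, n_restarts = 5, seed = 2)
  s0 <- kruskal_stress(d0, fit$coordinates)
  theta <- 0.7
  Q <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(kruskal_stress(d0, fit$coordinates %*% Q), s0,
               tolerance = 1e-10)
  refl <- fit$coordinates %*% diag(c(-1, 1))
  expect_equal(kruskal_stress(d0, 3.7 * refl), s0, tolerance = 1e-10)
  # the reported stress agrees with the recomputed stress-1
  expect_equal(s0, fit$stress, tolerance = 0.02)
})

test_that("ANOSIM matches the brute-force oracle on 6-sample toys", {
  withr::with_seed(11, {
    for (rep in 1:3) {
      pts <- matrix(rnorm(12), 6, 2)
      d <- as.matrix(dist(pts))
      g <- rep(c("a", "b"), each = 3)
      mine <- anosim(d, g, n_perm = "exact")
      oracle <- anosim_exact_oracle(d, g)
      expect_equal(mine$statistic, oracle$R, tolerance = 1e-12)
      expect_equal(mine$p, oracle$p, tolerance = 1e-12)
      # vegan agrees on the statistic (independent cross-check)
      veg <- suppressWarnings(suppressMessages(
        vegan::anosim(as.dist(d), g, permutations = 19)))
      expect_equal(mine$statistic, unname(veg$statistic), tolerance = 1e-10)
    }
  })
})

test_that("ANOSIM hits R = 1 with the minimal p under perfect separation", {
  withr::with_seed(23,
    pts <- rbind(matrix(rnorm(10, 0, 1e-3), 5, 2),
                 matrix(rnorm(10, 10, 1e-3), 5, 2)))
  d <- as.matrix(dist(pts))
  res <- anosim(d, rep(c("a", "b"), each = 5), n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1)
  # permutations that preserve the two-group partition tie with the
  # observed R = 1, so the attainable floor is the partition probability
  # 2 * 5! * 5! / 10! ~ 0.0079, not 1/(n_perm + 1)
  expect_lt(res$p, 0.02)
  expect_error(anosim(d[1:6, 1:6], c("a", "a", "a", "a", "a", "b")),
               "2 members")
})

test_that("PERMANOVA matches the Gower-trace oracle and exact permutations", {
  withr::with_seed(13, {
    for (rep in 1:3) {
      pts <- matrix(rnorm(12), 6, 2)
      d <- as.matrix(dist(pts))
      g <- c("a", "a", "b", "b", "b", "a")
      mine <- permanova(d, g, n_perm = "exact")
      oracle <- permanova_oracle(d, g)
      exact <- permanova_exact_oracle(d, g)
      expect_equal(mine$statistic, oracle$F, tolerance = 1e-10)
      expect_equal(mine$r_squared, oracle$R2, tolerance = 1e-10)
      expect_equal(mine$p, exact$p, tolerance = 1e-12)
      # vegan::adonis2 agrees on F and R2 (independent cross-check)
      veg <- suppressWarnings(suppressMessages(
        vegan::adonis2(as.dist(d) ~ g, permutations = 19)))
      expect_equal(mine$statistic, veg$F[1], tolerance = 1e-10)
      expect_equal(mine$r_squared, veg$R2[1], tolerance = 1e-10)
    }
  })
})

test_that("PERMANOVA limits: identical points and separated clusters", {
  d <- matrix(0, 6, 6)
  res <- permanova(d, rep(c("a", "b"), each = 3))
  expect_equal(res$r_squared, 0)
  expect_equal(res$p, 1)
  pts <- rbind(matrix(rnorm(8, sd = 0.01), 4, 2),
               matrix(rnorm(8, 50, sd = 0.01), 4, 2))
  d2 <- as.matrix(dist(pts))
  res2 <- permanova(d2, rep(c("a", "b"), each = 4), n_perm = 99, seed = 1)
  expect_gt(res2$r_squared, 0.99)
})

test_that("R and R2 are invariant to sample reordering", {
  sim <- generate_community(null_spec(19, n_otus = 25))
  tab <- sim$table
  g <- sim$meta$organ[match(colnames(tab), sim$meta$sample_id)]
  d <- bray_curtis(tab)
  perm <- withr::with_seed(1, sample.int(ncol(tab)))
  r1 <- anosim(d, g, n_perm = 49, seed = 3)$statistic
  r2 <- anosim(d[perm, perm], g[perm], n_perm = 49, seed = 3)$statistic
  expect_equal(r1, r2, tolerance = 1e-12)
  f1 <- permanova(d, g, n_perm = 49, seed = 3)
  f2 <- permanova(d[perm, perm], g[perm], n_perm = 49, seed = 3)
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_true(r1 >= -1 && r1 <= 1)
  expect_true(f1$r_squared >= 0 && f1$r_squared <= 1)
})

test_that("rejection rate is non-decreasing in host effect size", {
  rates <- sapply(c(0, 0.8, 2), function(es) {
    p <- sapply(1:12, function(s) {
      spec <- synthetic_spec(n_otus = 40, depth_mean = 3000,
                             depth_min = 1000, depth_dispersion = 0.1,
                             baseline_logabundance_sd = 1.5,
                             host_effect_sd = es, organ_effect_sd = 0,
                             interaction_sd = 0, seed = 1000 + s)
      sim <- generate_community(spec)
      root <- subset_samples(sim$table, sim$meta, organ = "root")
      g <- sim$meta$host[match(colnames(root), sim$meta$sample_id)]
      permanova(bray_curtis(root), g, n_perm = 199, seed = s)$p
    })
    mean(p < 0.05)
  })
  expect_true(rates[3] >= rates[1])
  expect_gt(rates[3], 0.8)  # a 2-log-unit host effect is easily detected
})

test_that("organ-dependent host effects reproduce the R2 ordering", {
  spec <- synthetic_spec(n_otus = 80, depth_mean = 4000, depth_min = 2000,
                         depth_dispersion = 0.1,
                         baseline_logabundance_sd = 1.5,
                         host_effect_sd = 1.2, organ_effect_sd = 0.5,
                         interaction_sd = 0,
                         host_effect_sd_by_organ = c(stem = 1.6, leaf = 1,
                                                     root = 1),
                         seed = 77)
  sim <- generate_community(spec)
  r2 <- sapply(c("stem", "leaf", "root"), function(org) {
    sub <- subset_samples(sim$table, sim$meta, organ = org)
    g <- sim$meta$host[match(colnames(sub), sim$meta$sample_id)]
    permanova(bray_curtis(sub), g, n_perm = 99, seed = 5)$r_squared
  })
  expect_gt(r2["stem"], r2["leaf"])
  expect_gt(r2["stem"], r2["root"])
})
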