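star_graph <- function(nleaf) {
  igraph::make_star(nleaf + 1, mode = "undirected", center = 1)
}

test_that("edges satisfy both thresholds and every node has degree >= 1", {
  sim <- generate_community(synthetic_spec(
    n_otus = 40, depth_mean = 10000, depth_min = 5000,
    depth_dispersion = 0.1, baseline_logabundance_sd = 1,
    host_effect_sd = 0, organ_effect_sd = 0, interaction_sd = 0,
    n_correlated_blocks = 2, block_size = 5, block_rho = 0.9,
    overdispersion = Inf, seed = 101))
  net <- suppressMessages(build_network(sim$table))
  expect_true(all(abs(net$edges$rho) > 0.5))
  expect_true(all(net$edges$p < 0.01))
  expect_true(all(net$nodes$degree >= 1))
  expect_false(any(net$edges$from == net$edges$to))
  # loosening either threshold only adds edges
  net2 <- suppressMessages(build_network(sim$table, rho_threshold = 0.3))
  net3 <- suppressMessages(build_network(sim$table, p_threshold = 0.05))
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(net) %in% key(net2)))
  expect_true(all(key(net) %in% key(net3)))
  expect_error(build_network(sim$table[, 1:3]), "at least 4")
})

test_that("Spearman rho and sign follow monotone profiles", {
  # constant column totals so relative abundances are proportional to
  # counts: rows 1-2 increase monotonically, row 3 = filler decreases
  k <- 1:15
  m <- rbind(2 * k, k^2, 500 - 2 * k - k^2)
  tab <- toy_table(m)
  net <- suppressMessages(build_network(tab, min_prevalence = 0))
  e <- net$edges
  pos <- e[(e$from %in% c("OTU1", "OTU2")) & (e$to %in% c("OTU1", "OTU2")), ]
  expect_equal(pos$rho, 1)
  expect_equal(pos$sign, "positive")
  neg <- e[(e$from %in% c("OTU1", "OTU3")) & (e$to %in% c("OTU1", "OTU3")), ]
  expect_equal(neg$rho, -1)
  expect_equal(neg$sign, "negative")
})

test_that("Spearman matches the rank-then-Pearson oracle with ties", {
  withr::with_seed(103, {
    for (i in 1:200) {
      x <- sample(0:5, 15, replace = TRUE)  # heavy ties
      y <- sample(0:5, 15, replace = TRUE)
      if (length(unique(x)) < 2 || length(unique(y)) < 2) next
      expect_equal(cor(x, y, method = "spearman"), spearman_oracle(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("topology matches hand-computed closed forms", {
  # star K1,4
  t1 <- topology(star_graph(4))
  expect_equal(t1$density, 0.4)
  expect_equal(t1$centralization, 1)
  expect_equal(t1$characteristic_path_length, 1.6)
  expect_equal(t1$heterogeneity, 0.75)
  expect_equal(t1$clustering_coefficient, 0)
  # complete K4
  t2 <- topology(igraph::make_full_graph(4))
  expect_equal(t2$density, 1)
  expect_equal(t2$clustering_coefficient, 1)
  expect_equal(t2$centralization, 0)
  expect_equal(t2$characteristic_path_length, 1)
  expect_equal(t2$heterogeneity, 0)
})

test_that("topology closed forms hold over parameterized families", {
  for (n in c(3, 5, 10, 17, 30)) {
    # cycle: 2-regular, density 2/(n-1), clustering 0 (n > 3)
    tc <- topology(igraph::make_ring(n))
    expect_equal(tc$density, 2 / (n - 1))
    expect_equal(tc$heterogeneity, 0)
    expect_equal(tc$connectivity, 2)
    expect_equal(tc$centralization, 0)  # regular graph
    # cycle path length: mean distance = sum over k of min(k, n-k)
    dists <- vapply(1:(n - 1), function(k) min(k, n - k), numeric(1))
    expect_equal(tc$characteristic_path_length,
                 sum(dists * n / 2) / choose(n, 2))
    # star K1,(n-1): density 2/n, centralization 1
    ts <- topology(star_graph(n - 1))
    expect_equal(ts$density, 2 / n)
    expect_equal(ts$centralization, 1)
    # complete graph
    tk <- topology(igraph::make_full_graph(n))
    expect_equal(tk$density, 1)
    expect_equal(tk$characteristic_path_length, 1)
  }
})

test_that("density recomputes bit-for-bit from stored node/edge counts", {
  sim <- generate_community(synthetic_spec(
    n_otus = 30, depth_mean = 8000, depth_min = 4000,
    baseline_logabundance_sd = 1, n_correlated_blocks = 1, block_size = 6,
    block_rho = 0.9, overdispersion = Inf, seed = 107))
  net <- suppressMessages(build_network(sim$table))
  tp <- topology(net)
  expect_identical(tp$density,
                   2 * tp$n_edges / (tp$n_nodes * (tp$n_nodes - 1)))
})

test_that("mcode recovers cliques and applies the haircut", {
  # a 6-clique attached by one bridge to a 10-path: rank-1 module is the
  # clique; the path never forms a 2-core
  g <- igraph::disjoint_union(igraph::make_full_graph(6),
                              igraph::make_ring(10, circular = FALSE))
  g <- igraph::add_edges(g, c(6, 7))
  igraph::V(g)$name <- paste0("v", 1:16)
  mods <- mcode(g)
  expect_equal(length(mods), 1)
  expect_setequal(mods[[1]]$nodes, paste0("v", 1:6))
  expect_equal(mods[[1]]$score, 6)  # density 1 x size 6
  # on any clique: the clique itself, score = size
  for (k in c(3, 5, 9)) {
    gk <- igraph::make_full_graph(k)
    igraph::V(gk)$name <- paste0("c", seq_len(k))
    mk <- mcode(gk)
    expect_equal(length(mk), 1)
    expect_equal(mk[[1]]$score, k)
    expect_setequal(mk[[1]]$nodes, paste0("c", seq_len(k)))
  }
  # edgeless graph -> empty list
  ge <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(mcode(ge), list())
})

test_that("mcode separates two planted cliques and ranks by score", {
  g <- igraph::disjoint_union(igraph::make_full_graph(8),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 9, 2, 10))  # sparse cross-links
  igraph::V(g)$name <- paste0("n", 1:13)
  mods <- mcode(g)
  expect_gte(length(mods), 2)
  expect_setequal(mods[[1]]$nodes, paste0("n", 1:8))
  expect_setequal(mods[[2]]$nodes, paste0("n", 9:13))
  expect_gt(mods[[1]]$score, mods[[2]]$score)
})

test_that("keystones ranks by degree with deterministic tie-breaks", {
  sim <- generate_community(synthetic_spec(
    n_otus = 20, depth_mean = 8000, depth_min = 4000,
    baseline_logabundance_sd = 1, n_correlated_blocks = 1, block_size = 6,
    block_rho = 0.95, overdispersion = Inf, seed = 109))
  net <- suppressMessages(build_network(sim$table))
  expect_warning(ks <- keystones(net, top_k = nrow(net$nodes) + 5),
                 "returning all")
  expect_true(!is.unsorted(-ks$degree))
  # ties broken by abundance then id: re-rank manually
  o <- order(-net$nodes$degree, -net$nodes$abundance, net$nodes$otu_id)
  expect_identical(ks$otu_id, net$nodes$otu_id[o])
})

test_that("niche classification partitions the nodes", {
  sim <- generate_community(synthetic_spec(
    n_otus = 30, depth_mean = 8000, depth_min = 4000,
    baseline_logabundance_sd = 1, n_correlated_blocks = 2, block_size = 5,
    block_rho = 0.9, overdispersion = Inf, seed = 113))
  net <- suppressMessages(build_network(sim$table))
  cls <- niche_overlap_nodes(net, sim$table, sim$meta)
  expect_equal(sum(cls$summary$n_nodes), nrow(net$nodes))
  expect_equal(sum(cls$summary$percent), 100, tolerance = 1e-9)
  # spike one network OTU to be root-only and another ubiquitous
  organ <- sim$meta$organ[match(colnames(sim$table), sim$meta$sample_id)]
  tab2 <- unclass(sim$table)
  target <- net$nodes$otu_id[1]
  tab2[target, organ != "root"] <- 0L
  tab2[target, organ == "root"] <- 5L
  cls2 <- niche_overlap_nodes(net, otu_table(tab2), sim$meta)
  expect_equal(cls2$nodes$niche_set[cls2$nodes$otu_id == target], "root")
  tab2[target, ] <- 3L
  cls3 <- niche_overlap_nodes(net, otu_table(tab2), sim$meta)
  expect_equal(cls3$nodes$niche_set[cls3$nodes$otu_id == target],
               "leaf+root+stem")
})

test_that("edge sign summary counts co-presence vs exclusion", {
  net <- structure(list(
    nodes = data.frame(otu_id = c("a", "b", "c"), abundance = 1:3 / 6,
                       degree = c(2L, 2L, 2L)),
    edges = data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                       rho = c(0.8, -0.6, 0.7), p = rep(0.001, 3),
                       sign = c("positive", "negative", "positive"))),
    class = "cooccurrence_network")
  s <- edge_sign_summary(net)
  expect_equal(s$n_positive, 2)
  expect_equal(s$n_negative, 1)
  expect_equal(s$fraction_copresence, 2 / 3)
})

test_that("network export writes Cytoscape-compatible tables", {
  sim <- generate_community(synthetic_spec(
    n_otus = 15, depth_mean = 8000, depth_min = 4000,
    baseline_logabundance_sd = 1, n_correlated_blocks = 1, block_size = 5,
    block_rho = 0.95, overdispersion = Inf, seed = 127))
  net <- suppressMessages(build_network(sim$table))
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, ep, np)
  ed <- read.delim(ep)
  expect_true(all(c("source", "target", "rho", "p", "neg_log10_p", "sign")
                  %in% names(ed) |
                    c("from", "to", "rho", "p", "neg_log10_p", "sign")
                  %in% names(ed)))
  expect_equal(nrow(ed), nrow(net$edges))
  nd <- read.delim(np)
  expect_equal(nrow(nd), nrow(net$nodes))
})
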