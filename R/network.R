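#' Spearman co-occurrence network
#'
#' Spearman rank correlations (average ranks for ties) between all OTU
#' pairs on per-sample relative abundances, with p-values from the
#' t-approximation on `n - 2` degrees of freedom. An edge is kept iff
#' `|rho| > rho_threshold` and `p < p_threshold` (both strict); OTUs with
#' no surviving edge are dropped, so every node has degree >= 1. OTUs
#' constant across samples (including those present in fewer than
#' `min_prevalence` samples, which cannot support a rank correlation) are
#' excluded up front with a message.
#'
#' No multiple-testing correction is applied to edges by default (a known
#' liberal convention); `adjust = "BH"` filters on BH-adjusted p instead.
#'
#' @param table abundant-OTU [otu_table] with at least 4 samples.
#' @param rho_threshold minimum `|rho|` (default 0.5, strict).
#' @param p_threshold maximum p (default 0.01, strict).
#' @param min_prevalence minimum number of samples an OTU must occur in
#'   (default 3).
#' @param positive_only if TRUE, keep only positive correlations.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method
#'   applied to the edge p-values before thresholding.
#' @return object of class `cooccurrence_network`: list with `nodes`
#'   (otu_id, abundance = total relative abundance, degree), `edges`
#'   (from, to, rho, p, sign) and the thresholds used.
#' @export
build_network <- function(table, rho_threshold = 0.5, p_threshold = 0.01,
                          min_prevalence = 3, positive_only = FALSE,
                          adjust = "none") {
  stopifnot(is_otu_table(table))
  n <- ncol(table)
  if (n < 4) stop("need at least 4 samples to estimate correlations")
  m <- as_counts(table)
  rel <- sweep(m, 2, colSums(m), "/")
  prevalence <- rowSums(m > 0)
  constant <- apply(rel, 1, function(x) length(unique(x)) == 1L)
  drop <- constant | prevalence < min_prevalence
  if (any(drop))
    message(sum(drop), " OTU(s) constant or present in < ", min_prevalence,
            " samples excluded before correlation")
  rel <- rel[!drop, , drop = FALSE]
  if (nrow(rel) < 2)
    stop("fewer than 2 OTUs remain after prevalence filtering")

  rho <- stats::cor(t(rel), method = "spearman")
  tstat <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  pmat <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pmat[abs(rho) >= 1] <- 0

  lt <- which(lower.tri(rho), arr.ind = TRUE)
  edges <- data.frame(from = rownames(rho)[lt[, 1]],
                      to = rownames(rho)[lt[, 2]],
                      rho = rho[lt], p = pmat[lt],
                      stringsAsFactors = FALSE)
  if (adjust != "none") edges$p <- stats::p.adjust(edges$p, method = adjust)
  keep <- abs(edges$rho) > rho_threshold & edges$p < p_threshold
  if (positive_only) keep <- keep & edges$rho > 0
  edges <- edges[keep, , drop = FALSE]
  edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
  rownames(edges) <- NULL

  deg <- table(factor(c(edges$from, edges$to),
                      levels = rownames(rel)))
  keep_nodes <- names(deg)[deg > 0]
  abundance <- rowSums(rel[keep_nodes, , drop = FALSE]) / ncol(rel)
  nodes <- data.frame(otu_id = keep_nodes,
                      abundance = as.numeric(abundance),
                      degree = as.integer(deg[keep_nodes]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 rho_threshold = rho_threshold, p_threshold = p_threshold,
                 n_samples = n),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (|rho| > ", x$rho_threshold, ", p < ",
      x$p_threshold, ")\n", sep = "")
  invisible(x)
}

as_igraph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Network topology attributes
#'
#' NetworkAnalyzer-style summary of an undirected simple graph: density
#' `2E / (N(N-1))`, connectivity (mean degree `2E / N`), mean local
#' clustering coefficient (nodes of degree < 2 contribute 0), degree
#' centralization `(N / (N-2)) * (max_degree / (N-1) - density)` (NA for
#' `N < 3`), characteristic path length (mean shortest-path length over
#' connected node pairs only, so disconnected graphs remain summarizable),
#' and heterogeneity (coefficient of variation of the degrees, population
#' sd).
#'
#' @param net a `cooccurrence_network` or an \pkg{igraph} graph.
#' @return one-row data.frame: n_nodes, n_edges, density, connectivity,
#'   clustering_coefficient, centralization, characteristic_path_length,
#'   heterogeneity.
#' @export
topology <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) stop("empty network")
  deg <- igraph::degree(g)
  density <- if (n > 1) 2 * e / (n * (n - 1)) else NA_real_
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  centralization <- if (n >= 3)
    (n / (n - 2)) * (max(deg) / (n - 1) - density) else NA_real_
  sp <- igraph::distances(g)
  finite <- sp[upper.tri(sp)][is.finite(sp[upper.tri(sp)])]
  cpl <- if (length(finite)) mean(finite) else NA_real_
  het <- if (mean(deg) > 0)
    sqrt(mean((deg - mean(deg))^2)) / mean(deg) else NA_real_
  data.frame(n_nodes = n, n_edges = e, density = density,
             connectivity = 2 * e / n,
             clustering_coefficient = mean(cc_local),
             centralization = centralization,
             characteristic_path_length = cpl,
             heterogeneity = het)
}

# Bader-Hogue vertex weight: coreness of the highest k-core of the closed
# neighborhood, times the density of that core subgraph
mcode_vertex_weights <- function(g) {
  vapply(seq_len(igraph::vcount(g)), function(v) {
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0) return(0)
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    nk <- igraph::vcount(core_sub)
    dens <- if (nk > 1)
      2 * igraph::ecount(core_sub) / (nk * (nk - 1)) else 0
    kmax * dens
  }, numeric(1))
}

#' MCODE module detection
#'
#' Bader-Hogue molecular-complex detection on an undirected simple graph:
#' vertices are weighted by the density-weighted coreness of their closed
#' neighborhood's highest k-core; complexes grow greedily outward from the
#' highest-weight unused seed, including neighbors whose weight is at
#' least `seed_weight * (1 - node_score_cutoff)` up to `max_depth` steps;
#' post-processing keeps complexes containing a `k_core`-core (haircut
#' trims the complex to its 2-core). Modules are node-disjoint and ranked
#' by score = module density x module size.
#'
#' @param net a `cooccurrence_network` or an \pkg{igraph} graph.
#' @param node_score_cutoff inclusion tolerance below the seed weight
#'   (default 0.2).
#' @param k_core minimum core a complex must contain (default 2).
#' @param degree_cutoff minimum degree for a vertex to seed or join a
#'   complex (default 2).
#' @param haircut trim each complex to its 2-core (default TRUE).
#' @param fluff Bader-Hogue fluff step (default FALSE; unimplemented
#'   beyond the standard parameter surface, must be FALSE).
#' @param max_depth maximum growth depth from the seed (default 100).
#' @return list of modules, each a list with `rank`, `nodes` (ids),
#'   `seed` (id), `n_edges`, `density` and `score`; empty list if no
#'   complex survives.
#' @export
mcode <- function(net, node_score_cutoff = 0.2, k_core = 2,
                  degree_cutoff = 2, haircut = TRUE, fluff = FALSE,
                  max_depth = 100) {
  if (fluff) stop("fluff post-processing is not implemented")
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) return(list())
  w <- mcode_vertex_weights(g)
  deg <- igraph::degree(g)
  usable <- deg >= degree_cutoff
  used <- rep(FALSE, n)
  complexes <- list()
  for (seed in order(-w)) {
    if (used[seed] || !usable[seed]) next
    thresh <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    frontier <- seed
    depth <- 0
    repeat {
      depth <- depth + 1
      if (depth > max_depth) break
      nbs <- unique(unlist(lapply(frontier, function(v)
        as.integer(igraph::neighbors(g, v)))))
      nbs <- setdiff(nbs, members)
      add <- nbs[!used[nbs] & usable[nbs] & w[nbs] >= thresh]
      if (!length(add)) break
      members <- c(members, add)
      frontier <- add
    }
    used[members] <- TRUE
    complexes[[length(complexes) + 1L]] <- list(seed = seed,
                                                members = members)
  }
  mods <- list()
  for (cx in complexes) {
    sub <- igraph::induced_subgraph(g, cx$members)
    core <- igraph::coreness(sub)
    if (max(core) < k_core) next
    keep <- if (haircut) which(core >= 2) else seq_len(igraph::vcount(sub))
    if (length(keep) < 2) next
    sub2 <- igraph::induced_subgraph(sub, keep)
    nk <- igraph::vcount(sub2)
    ek <- igraph::ecount(sub2)
    dens <- 2 * ek / (nk * (nk - 1))
    mods[[length(mods) + 1L]] <-
      list(nodes = igraph::V(sub2)$name, seed = igraph::V(g)$name[cx$seed],
           n_edges = ek, density = dens, score = dens * nk)
  }
  if (!length(mods)) return(list())
  mods <- mods[order(-vapply(mods, `[[`, numeric(1), "score"))]
  for (i in seq_along(mods)) mods[[i]]$rank <- i
  mods
}

#' Keystone OTUs by degree
#'
#' The `top_k` network nodes ranked by degree; ties are broken by total
#' relative abundance (descending), then lexicographic OTU id, so the
#' ranking is deterministic.
#'
#' @param net `cooccurrence_network`.
#' @param top_k number of keystones (default 10); if the network is
#'   smaller, all nodes are returned with a warning.
#' @return data.frame: rank, otu_id, degree, abundance.
#' @export
keystones <- function(net, top_k = 10) {
  stopifnot(inherits(net, "cooccurrence_network"))
  nd <- net$nodes
  if (nrow(nd) == 0) stop("empty network")
  if (nrow(nd) < top_k) {
    warning("network has only ", nrow(nd), " nodes; returning all")
    top_k <- nrow(nd)
  }
  o <- order(-nd$degree, -nd$abundance, nd$otu_id)
  out <- nd[o[seq_len(top_k)], c("otu_id", "degree", "abundance")]
  out <- cbind(rank = seq_len(top_k), out)
  rownames(out) <- NULL
  out
}

#' Niche-sharing classification of network nodes
#'
#' Labels each node of an integrated network by the set of organs in which
#' the OTU has at least one read, and tabulates the node percentage per
#' organ-set category.
#'
#' @param net `cooccurrence_network` built from all samples.
#' @param table the [otu_table] the network was built from (full sample
#'   set).
#' @param meta metadata data.frame with `sample_id` and `organ`.
#' @return list with `nodes` (otu_id, niche_set) and `summary`
#'   (niche_set, n_nodes, percent; percentages sum to 100).
#' @export
niche_overlap_nodes <- function(net, table, meta) {
  stopifnot(inherits(net, "cooccurrence_network"), is_otu_table(table))
  organ <- meta$organ[match(colnames(table), meta$sample_id)]
  if (anyNA(organ)) stop("samples missing from metadata")
  organs <- unique(organ)
  m <- as_counts(table)
  sets <- vapply(net$nodes$otu_id, function(o) {
    present <- organs[vapply(organs, function(g)
      sum(m[o, organ == g]) > 0, logical(1))]
    paste(sort(present), collapse = "+")
  }, character(1))
  nodes <- data.frame(otu_id = net$nodes$otu_id, niche_set = unname(sets),
                      stringsAsFactors = FALSE)
  tab <- table(nodes$niche_set)
  summary <- data.frame(niche_set = names(tab), n_nodes = as.integer(tab),
                        percent = 100 * as.integer(tab) / nrow(nodes),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$n_nodes), ]
  rownames(summary) <- NULL
  list(nodes = nodes, summary = summary)
}

#' Edge sign summary
#'
#' Counts of positive (co-presence) and negative (mutual-exclusion) edges
#' and the co-presence fraction.
#'
#' @param net `cooccurrence_network`.
#' @return one-row data.frame: n_positive, n_negative,
#'   fraction_copresence.
#' @export
edge_sign_summary <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (nrow(net$edges) == 0) stop("network has no edges")
  np <- sum(net$edges$sign == "positive")
  nn <- sum(net$edges$sign == "negative")
  data.frame(n_positive = np, n_negative = nn,
             fraction_copresence = np / (np + nn))
}

#' Export a network as edge-list and node-attribute tables
#'
#' Cytoscape-compatible TSVs: an edge list (source, target, rho, p,
#' neg_log10_p, sign) and a node table (otu_id, abundance, degree).
#'
#' @param net `cooccurrence_network`.
#' @param edge_path,node_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, edge_path, node_path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  ed <- net$edges
  ed$neg_log10_p <- -log10(pmax(ed$p, .Machine$double.xmin))
  utils::write.table(ed[c("from", "to", "rho", "p", "neg_log10_p", "sign")],
                     edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, node_path))
}
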