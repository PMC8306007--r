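#' Aggregate relative abundances by a taxonomic rank
#'
#' Sums reads per taxon at the requested rank within each group of samples
#' and converts to fractions. Taxa whose share of the *whole table's* reads
#' is strictly below `others_threshold` are merged into an `"Others"`
#' bucket (a taxon exactly at the threshold is retained). Unclassified
#' ranks are reported as `unclassified_<parent rank label>` so that sister
#' clades remain distinguishable.
#'
#' @param table [otu_table].
#' @param tax taxonomy data.frame ([read_taxonomy()] layout).
#' @param rank one of kingdom, phylum, class, order, family, genus,
#'   species.
#' @param groups optional factor over samples (e.g. `host x organ`);
#'   default pools all samples into one group.
#' @param others_threshold fraction of total reads below which a taxon is
#'   bucketed (default `1e-4`, i.e. 0.01\%).
#' @return data.frame with columns group, taxon, fraction; fractions sum
#'   to 1 within each group.
#' @export
aggregate_by_rank <- function(table, tax, rank, groups = NULL,
                              others_threshold = 1e-4) {
  stopifnot(is_otu_table(table))
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  if (!rank %in% ranks)
    stop("unknown rank '", rank, "'; expected one of ",
         paste(ranks, collapse = ", "))
  ti <- match(rownames(table), tax$otu_id)
  if (anyNA(ti))
    stop("taxonomy missing for OTU(s): ",
         paste(rownames(table)[is.na(ti)], collapse = ", "))
  lab <- tax[[rank]][ti]
  if (rank != "kingdom") {
    parent <- tax[[ranks[match(rank, ranks) - 1L]]][ti]
    lab <- ifelse(lab == "unclassified",
                  paste0("unclassified_", parent), lab)
  }
  if (is.null(groups)) groups <- rep("all", ncol(table))
  groups <- factor(groups)
  if (length(groups) != ncol(table))
    stop("groups must have one value per sample")

  m <- as_counts(table)
  total_share <- tapply(rowSums(m), lab, sum) / sum(m)
  minor <- names(total_share)[total_share < others_threshold]
  lab2 <- ifelse(lab %in% minor, "Others", lab)

  out <- do.call(rbind, lapply(levels(groups), function(g) {
    sub <- m[, groups == g, drop = FALSE]
    reads <- tapply(rowSums(sub), lab2, sum)
    reads <- reads[reads > 0 | names(reads) == "Others"]
    data.frame(group = g, taxon = names(reads),
               fraction = as.numeric(reads) / sum(reads),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Venn region accounting for OTU presence sets
#'
#' Counts OTUs in every non-empty region of the Venn diagram over 2-5
#' groups of samples; presence means at least one read in at least one
#' sample of the group. Percentages are relative to the union over all
#' groups.
#'
#' @param table [otu_table].
#' @param groups factor over samples defining 2-5 groups.
#' @return data.frame with columns region (`+`-joined group names), n_otus,
#'   percent; plus attribute `unique` (per-group unique counts).
#' @export
venn_regions <- function(table, groups) {
  stopifnot(is_otu_table(table))
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2 || nlevels(groups) > 5)
    stop("venn_regions supports 2-5 groups")
  m <- as_counts(table)
  present <- vapply(levels(groups), function(g)
    rowSums(m[, groups == g, drop = FALSE]) > 0,
    logical(nrow(m)))
  if (nrow(m) == 1L) present <- matrix(present, nrow = 1)
  in_union <- rowSums(present) > 0
  pattern <- apply(present, 1L, function(z)
    paste(levels(groups)[z], collapse = "+"))
  pattern <- pattern[in_union]
  # enumerate all 2^g - 1 regions, including empty ones
  g <- nlevels(groups)
  combos <- unlist(lapply(seq_len(g), function(k)
    utils::combn(levels(groups), k, paste, collapse = "+",
                 simplify = FALSE)), use.names = FALSE)
  counts <- table(factor(pattern, levels = combos))
  total <- sum(in_union)
  out <- data.frame(region = combos, n_otus = as.integer(counts),
                    percent = if (total > 0)
                      100 * as.integer(counts) / total else 0,
                    stringsAsFactors = FALSE)
  uniq <- out[out$region %in% levels(groups), c("region", "n_otus")]
  names(uniq) <- c("group", "n_unique")
  attr(out, "unique") <- uniq
  out
}

#' Per-OTU differential abundance (Kruskal-Wallis)
#'
#' Kruskal-Wallis test on each OTU's relative abundances across groups.
#' Raw p-values and BH q-values are both reported; the significance flag
#' follows raw `p < 0.05` (the conventional STAMP-style per-OTU screen),
#' which is anticonservative across many OTUs -- consult `q` for an
#' FDR-controlled view. Constant OTUs give `H = 0, p = 1`.
#'
#' @param table [otu_table] (typically [select_abundant_otus()] output).
#' @param groups grouping factor over samples (>= 2 groups).
#' @param alpha raw-p significance threshold for the flag (default 0.05).
#' @return data.frame ranked by p: otu_id, per-group mean relative
#'   abundance columns (`mean_<group>`), statistic (H), p, q, significant.
#' @export
differential_abundance <- function(table, groups, alpha = 0.05) {
  stopifnot(is_otu_table(table))
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  m <- as_counts(table)
  rel <- sweep(m, 2, colSums(m), "/")
  res <- lapply(seq_len(nrow(rel)), function(i) {
    x <- rel[i, ]
    if (length(unique(x)) == 1L) {
      h <- 0; p <- 1
    } else {
      kt <- stats::kruskal.test(x, groups)
      h <- unname(kt$statistic); p <- kt$p.value
    }
    means <- tapply(x, groups, mean)
    out <- data.frame(otu_id = rownames(rel)[i], statistic = h, p = p,
                      stringsAsFactors = FALSE)
    for (g in levels(groups)) out[[paste0("mean_", g)]] <- means[[g]]
    out
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Top-N most abundant OTUs as a relative-abundance matrix
#'
#' Utility for heatmap-style displays: the `n` OTUs with the highest total
#' reads, as relative abundances per sample.
#'
#' @param table [otu_table].
#' @param n number of OTUs (default 50).
#' @return numeric matrix (OTUs x samples) of relative abundances.
#' @export
top_abundance_matrix <- function(table, n = 50) {
  stopifnot(is_otu_table(table))
  m <- as_counts(table)
  keep <- utils::head(order(rowSums(m), decreasing = TRUE), n)
  sweep(m[keep, , drop = FALSE], 2, colSums(m), "/")
}
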