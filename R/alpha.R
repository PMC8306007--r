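#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample's reads uniformly without replacement to exactly
#' `depth` reads (a single draw, as in MOTHUR's subsample command). Samples
#' whose total is below `depth` are dropped with a warning; a sample whose
#' total equals `depth` is returned unchanged.
#'
#' @param table [otu_table].
#' @param depth target depth in reads, or `"min"` for the smallest sample
#'   total.
#' @param seed integer seed for the subsampling draw.
#' @return rarefied [otu_table] in which every column sums to `depth`.
#' @export
rarefy_table <- function(table, depth = "min", seed = 1) {
  stopifnot(is_otu_table(table))
  totals <- colSums(as_counts(table))
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0) stop("depth must be a positive integer")
  low <- totals < depth
  if (any(low)) {
    warning(sum(low), " sample(s) below depth ", depth, " dropped: ",
            paste(names(totals)[low], collapse = ", "))
    table <- table[, !low, drop = FALSE]
  }
  m <- t(as_counts(table))
  # rrarefy heuristically warns on tables whose smallest positive count
  # exceeds 1; our inputs are validated integer reads, so silence it
  out <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  otu_table(t(out))
}

#' Alpha diversity indices per sample
#'
#' For each sample: observed richness (`sobs`, OTUs with at least one
#' read), Shannon diversity in natural-log units, and Pielou evenness
#' `shannon / log(sobs)` (NA when `sobs <= 1`).
#'
#' @param table [otu_table]; every sample must have at least one read.
#' @return data.frame with columns sample_id, sobs, shannon, evenness.
#' @export
alpha_indices <- function(table) {
  stopifnot(is_otu_table(table))
  m <- as_counts(table)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("all-zero sample(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "))
  sobs <- colSums(m > 0)
  shannon <- vapply(seq_len(ncol(m)), function(j) {
    p <- m[, j][m[, j] > 0] / totals[j]
    -sum(p * log(p))
  }, numeric(1))
  evenness <- ifelse(sobs > 1, shannon / log(sobs), NA_real_)
  data.frame(sample_id = colnames(m), sobs = as.integer(sobs),
             shannon = shannon, evenness = evenness,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rarefaction curve for one sample
#'
#' Mean (and sd) observed richness over repeated uniform subsamples at each
#' requested depth.
#'
#' @param table [otu_table].
#' @param sample_id sample to rarefy.
#' @param depths integer vector of subsample depths (each at most the
#'   sample's total reads).
#' @param replicates subsample draws per depth.
#' @param seed integer seed.
#' @return data.frame with columns depth, mean_sobs, sd_sobs.
#' @export
rarefaction_curve <- function(table, sample_id, depths, replicates = 10,
                              seed = 1) {
  stopifnot(is_otu_table(table), sample_id %in% colnames(table))
  x <- as_counts(table)[, sample_id]
  if (any(depths > sum(x)))
    stop("depths must not exceed the sample total (", sum(x), ")")
  if (any(depths < 1)) stop("depths must be >= 1")
  reads <- rep.int(seq_along(x), x)
  withr::with_seed(seed, {
    res <- lapply(sort(unique(as.integer(depths))), function(d) {
      sobs <- vapply(seq_len(replicates), function(r)
        length(unique(sample(reads, d))), numeric(1))
      data.frame(depth = d, mean_sobs = mean(sobs), sd_sobs = stats::sd(sobs))
    })
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-squared p-value on `k - 1`
#' degrees of freedom. When every pooled value is identical the test is
#' degenerate and reported as `H = 0, p = 1`.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor aligned with `values` (>= 2 non-empty
#'   groups).
#' @return one-row data.frame: statistic (H), dof, p, n per group and group
#'   labels (collapsed).
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  if (length(unique(values)) == 1L) {
    h <- 0; p <- 1; dof <- nlevels(groups) - 1L
  } else {
    kt <- stats::kruskal.test(values, groups)
    h <- unname(kt$statistic); p <- kt$p.value; dof <- unname(kt$parameter)
  }
  data.frame(statistic = h, dof = dof, p = p,
             groups = paste(levels(groups), collapse = "|"),
             n = paste(as.integer(table(groups)), collapse = "|"),
             stringsAsFactors = FALSE)
}

#' Welch's t-tests for all group pairs
#'
#' Welch (unequal-variance) two-sample t-tests with Satterthwaite degrees
#' of freedom for every unordered pair of groups; raw two-sided p-values
#' with Benjamini-Hochberg q-values alongside. Two degenerate equal
#' constant groups give `t = 0, p = 1`.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor aligned with `values`; each group needs
#'   at least 2 values.
#' @return data.frame with one row per pair: group1, group2, statistic (t),
#'   dof, p, q.
#' @export
welch_pairwise <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 values")
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- values[groups == pairs[1, k]]
    b <- values[groups == pairs[2, k]]
    res <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) {
      # both groups constant: identical means -> no evidence; else separated
      if (isTRUE(all.equal(mean(a), mean(b))))
        data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                   statistic = 0, dof = NA_real_, p = 1)
      else
        data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                   statistic = sign(mean(a) - mean(b)) * Inf,
                   dof = NA_real_, p = 0)
    } else {
      data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                 statistic = unname(res$statistic),
                 dof = unname(res$parameter), p = res$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
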