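#' Species-level co-occurrence count matrix
#'
#' Binarizes the OTU table to presence/absence per sample, then counts for
#' every (row category, fungal OTU) pair the number of samples of that
#' category in which the OTU occurs. Rows are the levels of `row_factor`
#' (host species or organ), columns are fungal OTUs.
#'
#' @param table [otu_table] (typically abundant-OTU subset).
#' @param meta metadata data.frame with `sample_id` and the row factor.
#' @param row_factor `"host"` or `"organ"`.
#' @return integer matrix, categories x OTUs, with a `capacity` attribute
#'   giving the number of samples per category.
#' @export
build_species_matrix <- function(table, meta, row_factor = c("host",
                                                             "organ")) {
  stopifnot(is_otu_table(table))
  row_factor <- match.arg(row_factor)
  labels <- meta[[row_factor]][match(colnames(table), meta$sample_id)]
  if (anyNA(labels))
    stop("samples missing from metadata: ",
         paste(colnames(table)[is.na(labels)], collapse = ", "))
  species_matrix_from_presence(t(as_counts(table) > 0), labels)
}

# presence: samples x OTUs logical; labels: one category per sample
species_matrix_from_presence <- function(presence, labels) {
  labels <- factor(labels)
  ind <- stats::model.matrix(~ 0 + labels)
  m <- t(ind) %*% presence
  rownames(m) <- levels(labels)
  storage.mode(m) <- "integer"
  attr(m, "capacity") <- as.integer(table(labels))
  names(attr(m, "capacity")) <- levels(labels)
  m
}

#' Bipartite specialization index d'
#'
#' Kullback-Leibler specialization of each partner against availability,
#' rescaled to \eqn{[0, 1]}. For column `j` with interaction proportions
#' `p_i = a_ij / sum_i(a_ij)` and availabilities `q_i` = row totals /
#' grand total: `d_j = sum_i p_i log(p_i / q_i)`; `d'_j = d_j / d_max`
#' with `d_max = log(1 / min(q))`, the divergence attained by interacting
#' exclusively with the rarest partner. A column proportional to the
#' availabilities has `d' = 0`; a column concentrated on the single rarest
#' partner has `d' = 1`. With `margin = "rows"` the matrix is transposed
#' and the roles swap.
#'
#' With a single row (one partner category) every column trivially matches
#' availability and all d' are 0. Columns (or rows) with zero marginal
#' total are undefined and returned as NA.
#'
#' @param m non-negative interaction matrix (e.g.
#'   [build_species_matrix()] output).
#' @param margin `"columns"` (default: one d' per column) or `"rows"`.
#' @return named numeric vector of d' values in \eqn{[0, 1]} (NA where
#'   undefined).
#' @export
dprime <- function(m, margin = c("columns", "rows")) {
  margin <- match.arg(margin)
  m <- as.matrix(m)
  if (any(m < 0)) stop("interaction matrix must be non-negative")
  if (margin == "rows") m <- t(m)
  out <- rep(NA_real_, ncol(m))
  names(out) <- colnames(m)
  tot <- sum(m)
  if (tot == 0) return(out)
  if (nrow(m) == 1L) {
    out[colSums(m) > 0] <- 0
    return(out)
  }
  q <- rowSums(m) / tot
  dmax <- log(1 / min(q[q > 0]))
  ctot <- colSums(m)
  for (j in which(ctot > 0)) {
    p <- m[, j] / ctot[j]
    nz <- p > 0
    if (any(q[nz] == 0)) {  # unreachable from marginals, defensive
      out[j] <- NA_real_
      next
    }
    d <- sum(p[nz] * log(p[nz] / q[nz]))
    out[j] <- if (dmax > 0) min(1, max(0, d / dmax)) else 0
  }
  out
}

#' Permutation-standardized preference analysis (d' and 2DP)
#'
#' The host/organ-fungus preference framework. The observed species-level
#' matrix is built once; then for each of `n_perm` permutations the
#' row-factor labels of the samples are shuffled (sample contents intact)
#' and the matrix rebuilt. Three statistic families are standardized
#' against their permutation nulls:
#' \itemize{
#'   \item per fungal OTU: `standardized d' = (d'_obs - mean(d'_rand)) /
#'     sd(d'_rand)`;
#'   \item per row category (host or organ): the same standardization of
#'     the row-margin d';
#'   \item per (category, OTU) cell: the two-dimensional preference
#'     `2DP(i, j) = (N_obs(i, j) - mean(N_rand(i, j))) / sd(N_rand(i, j))`
#'     where N is the species-level sample count.
#' }
#' Permutation p-values are one-sided upper by default
#' (`p = (#(rand >= obs) + 1) / (n_perm + 1)`; `tail = "two.sided"`
#' doubles the smaller tail), and Benjamini-Hochberg q-values are computed
#' within each family. Cells or margins whose permutation sd is 0 (e.g. a
#' fungus present in every sample, which no shuffle can change) are
#' returned as NA with a reason code and excluded from the FDR family.
#'
#' @param table abundant-OTU [otu_table].
#' @param meta metadata data.frame.
#' @param row_factor `"host"` or `"organ"`.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @param tail `"upper"` (default) or `"two.sided"`.
#' @param fdr_method multiplicity correction, default `"BH"` (any
#'   [stats::p.adjust()] method).
#' @param stratify_by optional metadata column; labels are then shuffled
#'   only within strata of that column (e.g. within organ for the host
#'   analysis in an unbalanced design).
#' @return object of class `preference`: list with `fungi`, `categories`
#'   and `cells` data.frames, the observed matrix, and the call
#'   parameters.
#' @export
standardized_preference <- function(table, meta,
                                    row_factor = c("host", "organ"),
                                    n_perm = 1000, seed = 1,
                                    tail = c("upper", "two.sided"),
                                    fdr_method = "BH",
                                    stratify_by = NULL) {
  stopifnot(is_otu_table(table))
  row_factor <- match.arg(row_factor)
  tail <- match.arg(tail)
  mrow <- match(colnames(table), meta$sample_id)
  if (anyNA(mrow)) stop("samples missing from metadata")
  labels <- factor(meta[[row_factor]][mrow])
  if (nlevels(labels) < 2) stop("need at least 2 row categories")
  strata <- if (is.null(stratify_by)) NULL
            else factor(meta[[stratify_by]][mrow])

  presence <- t(as_counts(table) > 0)  # samples x OTUs
  obs <- species_matrix_from_presence(presence, labels)
  nr <- nrow(obs); nc <- ncol(obs)
  d_fungi_obs <- dprime(obs, "columns")
  d_cat_obs <- dprime(obs, "rows")

  d_fungi_rand <- matrix(NA_real_, n_perm, nc)
  d_cat_rand <- matrix(NA_real_, n_perm, nr)
  n_rand_sum <- matrix(0, nr, nc)
  n_rand_sq <- matrix(0, nr, nc)
  ge_fungi <- numeric(nc); ge_cat <- numeric(nr); ge_cell <- matrix(0, nr, nc)

  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- shuffle_within(length(labels), strata)
      perm <- species_matrix_from_presence(presence, labels[idx])
      d_fungi_rand[b, ] <- dprime(perm, "columns")
      d_cat_rand[b, ] <- dprime(perm, "rows")
      n_rand_sum <- n_rand_sum + perm
      n_rand_sq <- n_rand_sq + perm^2
      ge_fungi <- ge_fungi + (d_fungi_rand[b, ] >= d_fungi_obs - 1e-12)
      ge_cat <- ge_cat + (d_cat_rand[b, ] >= d_cat_obs - 1e-12)
      ge_cell <- ge_cell + (perm >= obs)
    }
  })

  std_block <- function(obs_v, rand_mean, rand_sd, ge, ids) {
    z <- ifelse(rand_sd > 0, (obs_v - rand_mean) / rand_sd, NA_real_)
    p_up <- (ge + 1) / (n_perm + 1)
    p <- if (tail == "upper") p_up
         else pmin(1, 2 * pmin(p_up, 1 - ge / (n_perm + 1)))
    p[rand_sd == 0 | is.na(z)] <- NA_real_
    reason <- ifelse(is.na(obs_v), "undefined_dprime",
                     ifelse(rand_sd == 0, "zero_permutation_sd", ""))
    q <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    q[ok] <- stats::p.adjust(p[ok], method = fdr_method)
    data.frame(id = ids, observed = obs_v, mean_rand = rand_mean,
               sd_rand = rand_sd, standardized = z, p = p, q = q,
               reason = reason, stringsAsFactors = FALSE)
  }

  fungi <- std_block(d_fungi_obs,
                     colMeans(d_fungi_rand),
                     apply(d_fungi_rand, 2, stats::sd),
                     ge_fungi, colnames(obs))
  names(fungi)[1] <- "otu_id"
  categories <- std_block(d_cat_obs,
                          colMeans(d_cat_rand),
                          apply(d_cat_rand, 2, stats::sd),
                          ge_cat, rownames(obs))
  names(categories)[1] <- "category"

  cell_mean <- n_rand_sum / n_perm
  cell_sd <- sqrt(pmax(0, n_rand_sq / n_perm - cell_mean^2) *
                    n_perm / max(1, n_perm - 1))
  z_cell <- ifelse(cell_sd > 0, (obs - cell_mean) / cell_sd, NA_real_)
  p_up <- (ge_cell + 1) / (n_perm + 1)
  p_cell <- if (tail == "upper") p_up
            else pmin(1, 2 * pmin(p_up, 1 - ge_cell / (n_perm + 1)))
  p_cell[cell_sd == 0] <- NA_real_
  cells <- data.frame(category = rep(rownames(obs), nc),
                      otu_id = rep(colnames(obs), each = nr),
                      n_observed = as.integer(obs),
                      mean_rand = as.numeric(cell_mean),
                      sd_rand = as.numeric(cell_sd),
                      twodp = as.numeric(z_cell),
                      p = as.numeric(p_cell),
                      stringsAsFactors = FALSE)
  cells$q <- NA_real_
  ok <- !is.na(cells$p)
  cells$q[ok] <- stats::p.adjust(cells$p[ok], method = fdr_method)
  cells$reason <- ifelse(is.na(cells$twodp), "zero_permutation_sd", "")

  structure(list(fungi = fungi, categories = categories, cells = cells,
                 observed = obs, row_factor = row_factor, n_perm = n_perm,
                 seed = seed, tail = tail, fdr_method = fdr_method),
            class = "preference")
}

shuffle_within <- function(n, strata) {
  if (is.null(strata)) return(sample.int(n))
  idx <- seq_len(n)
  for (s in levels(strata)) {
    w <- which(strata == s)
    idx[w] <- w[sample.int(length(w))]
  }
  idx
}

#' @export
print.preference <- function(x, ...) {
  cat("Preference analysis by ", x$row_factor, ": ",
      nrow(x$observed), " categories x ", ncol(x$observed),
      " fungal OTUs (", nrow(x$cells), " 2DP cells), ",
      x$n_perm, " permutations, seed ", x$seed, "\n", sep = "")
  sig <- sum(x$fungi$q < 0.05, na.rm = TRUE)
  cat("  fungi with FDR-significant d' (q < 0.05): ", sig, "\n", sep = "")
  invisible(x)
}

#' Strongly preferred category-fungus pairs
#'
#' Cells of the 2DP matrix exceeding a threshold, sorted by descending
#' 2DP.
#'
#' @param pref [standardized_preference()] result.
#' @param threshold minimum 2DP (strict `>`).
#' @return data.frame of cells with `twodp > threshold`.
#' @export
strong_pairs <- function(pref, threshold) {
  stopifnot(inherits(pref, "preference"))
  keep <- !is.na(pref$cells$twodp) & pref$cells$twodp > threshold
  out <- pref$cells[keep, , drop = FALSE]
  out[order(-out$twodp), , drop = FALSE]
}
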