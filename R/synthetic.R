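#' Specify a synthetic endophyte community
#'
#' Defines the parameters of a Dirichlet-multinomial community generator
#' that emulates a crossed host-species x plant-organ amplicon survey: one
#' sample per (host, organ, plot) combination except those listed as
#' missing, a lognormal baseline rank-abundance profile, additive log-scale
#' host/organ/interaction effects, optional planted specialist OTUs and
#' correlated OTU blocks, and per-sample sequencing depths drawn lognormal
#' and clamped below.
#'
#' The defaults emulate a five-shrub, three-organ desert survey: 5 hosts x
#' 3 organs x 3 plots minus the missing EP-leaf combination (42 samples),
#' 337 OTUs, and depths around 60,000 reads clamped at 40,000 so that
#' rarefaction to a common depth near 40,000 remains meaningful.
#'
#' @param n_otus number of OTUs.
#' @param hosts,organs,plots design factors; `plots` is the number of
#'   replicate plots per host x organ combination.
#' @param missing_combinations list of `c(host=, organ=)` pairs absent from
#'   the design (default: EP has no leaf samples).
#' @param depth_mean,depth_dispersion lognormal read-depth parameters
#'   (mean depth in reads; dispersion is the sdlog).
#' @param depth_min lower clamp on depths, in reads.
#' @param baseline_logabundance_sd sd of the baseline log-abundance profile.
#' @param baseline_logabundance optional numeric vector of length `n_otus`
#'   fixing the baseline log-abundances instead of drawing them (effects and
#'   blocks still apply; block members keep the supplied baselines).
#' @param host_effect_sd,organ_effect_sd,interaction_sd sds of the additive
#'   log-scale effects; set all three to 0 for a null community in which
#'   every sample shares one expected composition.
#' @param host_effect_sd_by_organ optional named numeric vector of
#'   multipliers (one per organ) scaling the host effect within that organ,
#'   used to plant organ-dependent host structure.
#' @param n_specialists number of specialist OTUs planted automatically at
#'   generation time (alternating host/organ targets); specialists can also
#'   be planted explicitly with [plant_specialist()].
#' @param specialist_exclusivity exclusivity of auto-planted specialists.
#' @param n_correlated_blocks,block_size,block_rho,block_scale correlated
#'   OTU blocks: each block shares a latent per-sample factor with loading
#'   `sqrt(block_rho)` (idiosyncratic part `sqrt(1 - block_rho)`), scaled by
#'   `block_scale` log-units. `block_size` may be a vector with one size per
#'   block.
#' @param overdispersion Dirichlet concentration scale; counts are drawn
#'   multinomially from a Dirichlet(overdispersion x composition) draw.
#'   `Inf` gives a pure multinomial.
#' @param fixed_composition optional probability vector of length `n_otus`
#'   overriding all effects (every sample gets this composition).
#' @param seed integer seed; a fixed seed makes [generate_community()]
#'   byte-identical.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_otus = 337,
                           hosts = c("RS", "SR", "NS", "SP", "EP"),
                           organs = c("stem", "leaf", "root"),
                           plots = 3,
                           missing_combinations = list(c(host = "EP",
                                                         organ = "leaf")),
                           depth_mean = 60000,
                           depth_dispersion = 0.2,
                           depth_min = 40000,
                           baseline_logabundance_sd = 2,
                           baseline_logabundance = NULL,
                           host_effect_sd = 1,
                           organ_effect_sd = 1,
                           interaction_sd = 0.5,
                           host_effect_sd_by_organ = NULL,
                           n_specialists = 0,
                           specialist_exclusivity = 0.9,
                           n_correlated_blocks = 0,
                           block_size = 5,
                           block_rho = 0.8,
                           block_scale = 2,
                           overdispersion = 200,
                           fixed_composition = NULL,
                           seed = 1) {
  spec <- list(n_otus = as.integer(n_otus), hosts = hosts, organs = organs,
               plots = as.integer(plots),
               missing_combinations = missing_combinations,
               depth_mean = depth_mean, depth_dispersion = depth_dispersion,
               depth_min = depth_min,
               baseline_logabundance_sd = baseline_logabundance_sd,
               baseline_logabundance = baseline_logabundance,
               host_effect_sd = host_effect_sd,
               organ_effect_sd = organ_effect_sd,
               interaction_sd = interaction_sd,
               host_effect_sd_by_organ = host_effect_sd_by_organ,
               n_specialists = as.integer(n_specialists),
               specialist_exclusivity = specialist_exclusivity,
               n_correlated_blocks = as.integer(n_correlated_blocks),
               block_size = rep_len(as.integer(block_size),
                                    max(1L, as.integer(n_correlated_blocks))),
               block_rho = block_rho, block_scale = block_scale,
               overdispersion = overdispersion,
               fixed_composition = fixed_composition,
               specialists = list(),
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_otus < 1) stop("n_otus must be >= 1")
    if (depth_mean <= 0) stop("depth_mean must be > 0")
    sds <- c(depth_dispersion, baseline_logabundance_sd, host_effect_sd,
             organ_effect_sd, interaction_sd, block_scale)
    if (any(sds < 0)) stop("dispersions and effect sds must be >= 0")
    if (overdispersion <= 0) stop("overdispersion must be > 0 (Inf allowed)")
    if (n_correlated_blocks > 0 && sum(block_size) > n_otus)
      stop("correlated blocks require sum(block_size) <= n_otus")
    if (block_rho < 0 || block_rho > 1) stop("block_rho must be in [0, 1]")
    if (!is.null(baseline_logabundance) &&
        length(baseline_logabundance) != n_otus)
      stop("baseline_logabundance must have length n_otus")
    if (!is.null(fixed_composition)) {
      if (length(fixed_composition) != n_otus)
        stop("fixed_composition must have length n_otus")
      if (any(fixed_composition < 0) || sum(fixed_composition) <= 0)
        stop("fixed_composition must be a non-negative, non-zero vector")
    }
  })
  invisible(spec)
}

#' Plant a specialist OTU in a synthetic spec
#'
#' Marks one OTU as a specialist of a host species or an organ: its
#' expected relative abundance in every sample *outside* the target is
#' scaled by `1 - exclusivity` (exclusivity 1 confines the OTU to the
#' target up to sampling zeros; exclusivity 0 leaves the spec unchanged).
#'
#' @param spec [synthetic_spec()] object.
#' @param otu_index integer OTU index in `1:n_otus`.
#' @param host,organ exactly one of these names the target level.
#' @param exclusivity fraction in \eqn{[0, 1]}.
#' @return modified `synthetic_spec`.
#' @export
plant_specialist <- function(spec, otu_index, host = NULL, organ = NULL,
                             exclusivity = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exclusivity < 0 || exclusivity > 1)
    stop("exclusivity must be in [0, 1]")
  if (is.null(host) == is.null(organ))
    stop("specify exactly one of host or organ")
  if (!is.null(host) && !host %in% spec$hosts)
    stop("unknown host level: ", host)
  if (!is.null(organ) && !organ %in% spec$organs)
    stop("unknown organ level: ", organ)
  if (otu_index < 1 || otu_index > spec$n_otus)
    stop("otu_index out of range")
  if (exclusivity > 0)
    spec$specialists[[length(spec$specialists) + 1L]] <-
      list(otu = as.integer(otu_index),
           factor = if (is.null(host)) "organ" else "host",
           level = if (is.null(host)) organ else host,
           exclusivity = exclusivity)
  spec
}

#' Generate a synthetic community
#'
#' Draws an OTU count table, sample metadata and taxonomy according to a
#' [synthetic_spec()], together with a truth record of every planted
#' parameter. Per-sample expected composition is
#' `softmax(baseline + host + organ + interaction + block latent)`, with
#' specialist down-weighting applied on the probability scale; counts are
#' Dirichlet-multinomial at the sample's depth. A fixed seed gives
#' byte-identical output; the seed feeds separate substreams for design,
#' latent factors and count sampling so the phases do not interleave.
#'
#' @param spec [synthetic_spec()] object.
#' @return list with components `table` ([otu_table]), `meta` (data.frame:
#'   sample_id, host, organ, plot), `taxonomy` (data.frame) and `truth`
#'   (list of planted parameters: effects, specialists, blocks, depths,
#'   expected compositions).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, generate_community_impl(spec))
}

generate_community_impl <- function(spec) {
  n <- spec$n_otus
  otu_ids <- sprintf("OTU%03d", seq_len(n))

  design <- expand.grid(plot = seq_len(spec$plots), organ = spec$organs,
                        host = spec$hosts, stringsAsFactors = FALSE)
  design <- design[, c("host", "organ", "plot")]
  for (mc in spec$missing_combinations)
    design <- design[!(design$host == mc[["host"]] &
                       design$organ == mc[["organ"]]), ]
  meta <- data.frame(
    sample_id = sprintf("%s_%s_%d", design$host, design$organ, design$plot),
    host = design$host, organ = design$organ,
    plot = as.character(design$plot), stringsAsFactors = FALSE)
  rownames(meta) <- NULL
  ns <- nrow(meta)

  seeds <- sample.int(.Machine$integer.max, 4L)

  # -- design substream: baseline, effects, auto specialists, blocks
  withr::with_seed(seeds[1], {
    fixed_baseline <- !is.null(spec$baseline_logabundance)
    baseline <- if (fixed_baseline) spec$baseline_logabundance
                else stats::rnorm(n, 0, spec$baseline_logabundance_sd)
    host_eff <- matrix(stats::rnorm(length(spec$hosts) * n, 0,
                                    spec$host_effect_sd),
                       length(spec$hosts), n,
                       dimnames = list(spec$hosts, otu_ids))
    organ_eff <- matrix(stats::rnorm(length(spec$organs) * n, 0,
                                     spec$organ_effect_sd),
                        length(spec$organs), n,
                        dimnames = list(spec$organs, otu_ids))
    inter_eff <- array(stats::rnorm(length(spec$hosts) * length(spec$organs) *
                                      n, 0, spec$interaction_sd),
                       dim = c(length(spec$hosts), length(spec$organs), n),
                       dimnames = list(spec$hosts, spec$organs, otu_ids))
    specialists <- spec$specialists
    if (spec$n_specialists > 0) {
      pool <- setdiff(order(baseline, decreasing = TRUE),
                      vapply(specialists, `[[`, 1L, "otu"))
      picks <- pool[seq_len(spec$n_specialists)]
      for (k in seq_along(picks)) {
        if (k %% 2L == 1L)
          specialists[[length(specialists) + 1L]] <-
            list(otu = picks[k], factor = "host",
                 level = sample(spec$hosts, 1L),
                 exclusivity = spec$specialist_exclusivity)
        else
          specialists[[length(specialists) + 1L]] <-
            list(otu = picks[k], factor = "organ",
                 level = sample(spec$organs, 1L),
                 exclusivity = spec$specialist_exclusivity)
      }
    }
    blocks <- list()
    if (spec$n_correlated_blocks > 0) {
      idx <- seq_len(sum(spec$block_size))
      blocks <- split(idx, rep(seq_len(spec$n_correlated_blocks),
                               times = spec$block_size))
      # correlated blocks model abundant co-varying taxa (downstream
      # networks are built on abundant OTUs only), so block members sit at
      # the upper end of the baseline rank-abundance profile unless the
      # baselines were supplied explicitly
      if (!fixed_baseline)
        baseline[idx] <- stats::quantile(baseline, 0.8) +
          stats::runif(length(idx), 0, 0.5)
    }
  })

  # -- latent substream: per-sample block factors and idiosyncratic noise
  withr::with_seed(seeds[2], {
    block_term <- matrix(0, ns, n)
    for (b in blocks) {
      f <- stats::rnorm(ns)
      e <- matrix(stats::rnorm(ns * length(b)), ns, length(b))
      block_term[, b] <- spec$block_scale *
        (sqrt(spec$block_rho) * f +
           sqrt(1 - spec$block_rho) * e)
    }
  })

  # -- expected compositions
  hscale <- rep(1, length(spec$organs))
  names(hscale) <- spec$organs
  if (!is.null(spec$host_effect_sd_by_organ))
    hscale[names(spec$host_effect_sd_by_organ)] <-
      spec$host_effect_sd_by_organ
  probs <- matrix(0, n, ns, dimnames = list(otu_ids, meta$sample_id))
  for (s in seq_len(ns)) {
    if (!is.null(spec$fixed_composition)) {
      p <- spec$fixed_composition / sum(spec$fixed_composition)
    } else {
      h <- meta$host[s]; g <- meta$organ[s]
      eta <- baseline + hscale[[g]] * host_eff[h, ] + organ_eff[g, ] +
        inter_eff[h, g, ] + block_term[s, ]
      eta <- eta - max(eta)
      p <- exp(eta)
      for (sp in specialists) {
        in_target <- if (sp$factor == "host") h == sp$level else g == sp$level
        if (!in_target) p[sp$otu] <- p[sp$otu] * (1 - sp$exclusivity)
      }
      p <- p / sum(p)
    }
    probs[, s] <- p
  }

  # -- sampling substream: depths and Dirichlet-multinomial counts
  withr::with_seed(seeds[3], {
    depths <- pmax(spec$depth_min,
                   round(stats::rlnorm(ns, log(spec$depth_mean) -
                                         spec$depth_dispersion^2 / 2,
                                       spec$depth_dispersion)))
    counts <- matrix(0L, n, ns, dimnames = dimnames(probs))
    for (s in seq_len(ns)) {
      p <- probs[, s]
      if (is.finite(spec$overdispersion)) {
        a <- spec$overdispersion * p
        g <- ifelse(a > 0, stats::rgamma(n, shape = a), 0)
        p <- if (sum(g) > 0) g / sum(g) else p
      }
      counts[, s] <- stats::rmultinom(1, depths[s], p)
    }
  })

  taxonomy <- withr::with_seed(seeds[4], simulate_taxonomy(otu_ids))

  truth <- list(baseline = baseline, host_effects = host_eff,
                organ_effects = organ_eff, specialists = specialists,
                blocks = blocks, block_rho = spec$block_rho,
                depths = depths, expected_composition = probs)
  list(table = otu_table(counts), meta = meta, taxonomy = taxonomy,
       truth = truth)
}

# class/order labels with Dothideomycetes/Pleosporales given the largest
# prior mass; labels are static provenance, they carry no dynamics
simulate_taxonomy <- function(otu_ids) {
  classes <- c(Dothideomycetes = 0.45, Sordariomycetes = 0.20,
               Tremellomycetes = 0.10, Eurotiomycetes = 0.10,
               Agaricomycetes = 0.10, unclassified = 0.05)
  orders <- list(
    Dothideomycetes = c(Pleosporales = 0.70, Botryosphaeriales = 0.15,
                        Dothideales = 0.15),
    Sordariomycetes = c(Hypocreales = 0.50, Sordariales = 0.30,
                        Xylariales = 0.20),
    Tremellomycetes = c(Tremellales = 1),
    Eurotiomycetes = c(Eurotiales = 0.60, Chaetothyriales = 0.40),
    Agaricomycetes = c(Agaricales = 1),
    unclassified = c(unclassified = 1))
  basidio <- c("Tremellomycetes", "Agaricomycetes")
  cl <- sample(names(classes), length(otu_ids), replace = TRUE,
               prob = classes)
  or <- vapply(cl, function(x)
    sample(names(orders[[x]]), 1L, prob = orders[[x]]), character(1))
  data.frame(otu_id = otu_ids, kingdom = "Fungi",
             phylum = ifelse(cl %in% basidio, "Basidiomycota",
                             ifelse(cl == "unclassified", "unclassified",
                                    "Ascomycota")),
             class = cl, order = unname(or), family = "unclassified",
             genus = "unclassified", species = "unclassified",
             confidence = round(stats::runif(length(otu_ids), 0.7, 1), 3),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic community spec: ", x$n_otus, " OTUs, ",
      length(x$hosts), " hosts x ", length(x$organs), " organs x ",
      x$plots, " plots (", length(x$missing_combinations),
      " missing combination(s)), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
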