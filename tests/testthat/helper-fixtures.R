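# Fixture builders shared across test files. Simulation sizes here are
# scaled-down versions of the canonical design so the suite stays fast;
# the canonical defaults themselves are exercised in the design tests.

toy_table <- function(m, otu_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(m)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(m)))
  otu_table(m, otu_ids, sample_ids)
}

# zero-effect community: every sample shares one expected composition
null_spec <- function(seed, n_otus = 60, overdispersion = 200) {
  synthetic_spec(n_otus = n_otus, depth_mean = 5000, depth_min = 1000,
                 depth_dispersion = 0.1, baseline_logabundance_sd = 1.5,
                 host_effect_sd = 0, organ_effect_sd = 0,
                 interaction_sd = 0, overdispersion = overdispersion,
                 seed = seed)
}

# community with planted host/organ specialists on a quiet background
specialist_spec <- function(seed, n_specialists = 10) {
  synthetic_spec(n_otus = 60, depth_mean = 5000, depth_min = 1000,
                 depth_dispersion = 0.1, baseline_logabundance_sd = 1.5,
                 host_effect_sd = 0.3, organ_effect_sd = 0.3,
                 interaction_sd = 0.1, n_specialists = n_specialists,
                 specialist_exclusivity = 1, seed = seed)
}

# star-structured correlation: OTU1 is a pure latent factor, OTUs 2..13
# load on it with a = 0.7 (hub-satellite latent correlation 0.7,
# satellite-satellite 0.49, below the 0.5 edge threshold), independent
# background OTUs dilute compositional closure
hub_community <- function(seed, a = 0.7, nsat = 12, nbg = 40, ns = 42,
                          depth = 30000, scale = 2.5) {
  set.seed(seed)
  f <- rnorm(ns)
  eta <- rbind(scale * f,
               t(sapply(seq_len(nsat), function(k)
                 scale * (a * f + sqrt(1 - a^2) * rnorm(ns)))),
               matrix(rnorm(nbg * ns, sd = 1.5), nbg, ns))
  base <- c(rep(0, 1 + nsat), rnorm(nbg, 0, 1))
  counts <- sapply(seq_len(ns), function(s) {
    p <- exp(base + eta[, s])
    rmultinom(1, depth, p / sum(p))
  })
  toy_table(counts)
}

# the canonical 42-sample metadata (5 hosts x 3 organs x 3 plots minus
# EP-leaf), without generating counts
canonical_meta <- function() {
  generate_community(synthetic_spec(n_otus = 5, depth_mean = 100,
                                    depth_min = 50, seed = 1))$meta
}
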