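# Shared fixtures and independent oracles for the test suite.

# Toy genome of n single-region ("whole") chromosomes.
toy_whole_catalog <- function(n = 6, len = 2e6) {
  region_catalog(regions = data.frame(
    region = as.character(seq_len(n)), chrom = as.character(seq_len(n)),
    start = 0, end = len, kind = "whole", stringsAsFactors = FALSE))
}

# Toy genome of n chromosomes, each with p and q arms.
toy_arm_catalog <- function(n = 3, arm_len = 1e6) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(region = paste0(i, c("p", "q")), chrom = as.character(i),
               start = c(0, arm_len), end = c(arm_len, 2 * arm_len),
               kind = "arm", stringsAsFactors = FALSE)))
  region_catalog(regions = rows)
}

# Brute-force BH step-up (independent of stats::p.adjust).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Per-base brute-force gained/lost fraction of a region (integer coords).
base_fraction_oracle <- function(segments, region_start, region_end,
                                 ploidy = 2) {
  bases <- region_start:(region_end - 1)
  cn <- rep(ploidy, length(bases))  # gaps count as neutral
  for (i in seq_len(nrow(segments))) {
    hit <- bases >= segments$start[i] & bases < segments$end[i]
    cn[hit] <- segments$cn[i]
  }
  c(gain = mean(cn > ploidy), loss = mean(cn < ploidy))
}

# Exhaustive hypergeometric tails by enumerating all n-subsets of 1:N.
hyper_enum_tails <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= K)  # elements 1..K are the annotated ones
  c(upper = mean(overlaps >= k), lower = mean(overlaps <= k))
}

# Small NB count matrix with optional per-transcript fold effect in group A.
nb_matrix <- function(G = 200, nA = 10, nB = 10, mu_meanlog = log(100),
                      dispersion = 0.1, effect = rep(1, G), seed = 1) {
  set.seed(seed)
  mu <- stats::rlnorm(G, mu_meanlog, 1)
  a <- matrix(stats::rnbinom(G * nA, size = 1 / dispersion,
                             mu = rep(mu * effect, nA)), nrow = G)
  b <- matrix(stats::rnbinom(G * nB, size = 1 / dispersion,
                             mu = rep(mu, nB)), nrow = G)
  m <- cbind(a, b)
  dimnames(m) <- list(paste0("t", seq_len(G)),
                      paste0("s", seq_len(nA + nB)))
  m
}

# Compact simulated cohort on the whole-chromosome toy genome with a
# recurrent gain of chromosome "2".
toy_cohort_config <- function(seed = 1, n_tumour = 60, n_normal = 20,
                              gain_freq = 0.5, n_per_region = 100, ...) {
  toy <- data.frame(region = as.character(1:6), chrom = as.character(1:6),
                    start = 0, end = 2e6, kind = "whole",
                    stringsAsFactors = FALSE)
  simulation_config(seed = seed, n_tumour = n_tumour, n_normal = n_normal,
                    n_cin = n_tumour, n_msi = 0, regions = toy,
                    per_region_gain_freq = c("2" = gain_freq),
                    whole_gain_freq = numeric(),
                    per_region_loss_freq = numeric(), iso_freq = numeric(),
                    n_transcripts_per_region = n_per_region,
                    mean_log_expression = log(50), ...)
}
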