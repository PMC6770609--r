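test_that("default genome layout partitions the genome into 42 regions", {
  cat <- region_catalog()
  expect_equal(nrow(cat), 42)
  # arms within a chromosome are disjoint and regions have positive length
  expect_true(all(cat$end > cat$start))
  for (ch in unique(cat$chrom)) {
    r <- cat[cat$chrom == ch, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  }
  # acrocentric autosomes are single whole-chromosome regions
  expect_setequal(cat$region[cat$kind == "whole"],
                  c("13", "14", "15", "21", "22", "Y"))
  expect_error(region_catalog("nonexistent-layout"), "unknown region layout")
})

test_that("genome model places transcripts inside regions deterministically", {
  cfg <- simulation_config(seed = 3, n_transcripts_per_region = 10,
                           regions = as.data.frame(toy_whole_catalog(2)))
  gm1 <- build_genome_model(cfg)
  gm2 <- build_genome_model(cfg)
  expect_identical(gm1$annotation, gm2$annotation)
  expect_equal(gm1$catalog$X_n, c(10L, 10L))
  ann <- gm1$annotation
  cat <- gm1$catalog
  for (i in seq_len(nrow(ann))) {
    r <- cat[cat$region == ann$region[i], ]
    expect_gte(ann$start[i], r$start)
    expect_lte(ann$end[i], r$end)
  }
  expect_true(all(ann$length > 0))
  expect_true(all(ann$biotype %in% c("protein_coding", "lincRNA",
                                     "other_noncoding")))
})

test_that("forced and null copy-number events render as specified", {
  cat2 <- toy_arm_catalog(8)
  cfg <- simulation_config(seed = 5, n_tumour = 5, n_normal = 2,
                           n_cin = 5, n_msi = 0,
                           regions = as.data.frame(cat2),
                           per_region_gain_freq = c("8q" = 1.0),
                           whole_gain_freq = numeric(),
                           per_region_loss_freq = numeric(),
                           iso_freq = numeric(),
                           n_transcripts_per_region = 5)
  prof <- simulate_cna_profiles(cfg, cat2)
  tum <- prof$metadata$sample[prof$metadata$type == "tumour"]
  r8q <- cat2[cat2$region == "8q", ]
  for (s in tum) {
    seg <- prof$segments[prof$segments$sample == s & prof$segments$cn >= 3, ]
    ov <- sum(pmax(0, pmin(seg$end, r8q$end) - pmax(seg$start, r8q$start)))
    expect_gt(ov / (r8q$end - r8q$start), 0.5)
  }
  # all-zero frequencies give flat CN=2 everywhere
  cfg0 <- simulation_config(seed = 5, n_tumour = 4, n_normal = 2,
                            n_cin = 4, n_msi = 0,
                            regions = as.data.frame(cat2),
                            per_region_gain_freq = numeric(),
                            whole_gain_freq = numeric(),
                            per_region_loss_freq = numeric(),
                            iso_freq = numeric(),
                            n_transcripts_per_region = 5)
  prof0 <- simulate_cna_profiles(cfg0, cat2)
  expect_true(all(prof0$segments$cn == 2))
  expect_equal(nrow(prof0$events), 0)
})

test_that("recovered event frequency lies in the 99% binomial interval", {
  cfg <- toy_cohort_config(seed = 11, n_tumour = 400, n_normal = 2,
                           gain_freq = 0.5, n_per_region = 1)
  gm <- build_genome_model(cfg)
  prof <- simulate_cna_profiles(cfg, gm$catalog)
  tum <- prof$metadata$sample[prof$metadata$type == "tumour"]
  arm <- call_arm_cna_cohort(
    prof$segments[prof$segments$sample %in% tum, ], gm$catalog)
  freq <- cna_frequencies(arm)
  obs <- freq$pct_gain[freq$region == "2"] / 100
  ci <- qbinom(c(0.005, 0.995), 400, 0.5) / 400
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
})

test_that("dosage model produces the expected trisomic/disomic mean ratios", {
  # Monte-Carlo oracle over >= 1e4 draws per setting; no tumour effect
  cat1 <- toy_whole_catalog(2)
  base_cfg <- function(s) simulation_config(
    seed = 21, n_tumour = 50, n_normal = 50, n_cin = 50, n_msi = 0,
    regions = as.data.frame(cat1),
    per_region_gain_freq = c("1" = 1.0), whole_gain_freq = numeric(),
    per_region_loss_freq = numeric(), iso_freq = numeric(),
    n_transcripts_per_region = 100, gain_cn = 3L, gain_cn_prob = 1,
    frac_upregulated = 0, frac_downregulated = 0,
    dosage_exponent_null = s, library_size_sdlog = 0,
    nb_dispersion = 0.05, sd_log_expression = 0.2)
  for (case in list(list(s = 1, ratio = 1.5),
                    list(s = 0, ratio = 1.0),
                    list(s = log(1.25) / log(1.5), ratio = 1.25))) {
    cfg <- base_cfg(case$s)
    gm <- build_genome_model(cfg)
    prof <- simulate_cna_profiles(cfg, gm$catalog)
    cm <- simulate_counts(cfg, gm$annotation, prof)
    tum <- prof$metadata$type == "tumour"
    gained <- gm$annotation$region == "1"
    # 100 transcripts x 50 samples = 5e3 draws per group per region
    ratio <- mean(cm$counts[gained, tum]) / mean(cm$counts[gained, !tum])
    expect_equal(ratio, case$ratio, tolerance = 0.03)
    neutral <- mean(cm$counts[!gained, tum]) / mean(cm$counts[!gained, !tum])
    expect_equal(neutral, 1.0, tolerance = 0.03)
  }
})

test_that("simulated cohorts are reproducible and internally consistent", {
  cfg <- toy_cohort_config(seed = 9, n_tumour = 12, n_normal = 4,
                           n_per_region = 8)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$counts, co2$counts)
  expect_identical(co1$segments, co2$segments)
  expect_identical(co1$gene_sets, co2$gene_sets)
  # conservation: counts rows == annotation; every sample has a profile
  expect_equal(nrow(co1$counts), nrow(co1$annotation))
  expect_setequal(unique(co1$segments$sample), co1$metadata$sample)
  expect_equal(colnames(co1$counts), co1$metadata$sample)
  # every transcript appears exactly once in the truth
  expect_identical(sort(co1$truth$transcript), sort(co1$annotation$transcript))
})

test_that("gene sets respect the configured enrichment factor", {
  cfg <- toy_cohort_config(seed = 31, n_tumour = 4, n_normal = 2,
                           n_per_region = 2000, geneset_fraction = 0.05,
                           geneset_enrichment_factor = 3)
  gm <- build_genome_model(cfg)
  truth <- assign_truth(cfg, gm$annotation)
  sets <- make_gene_sets(cfg, truth)
  sensitive <- truth$transcript[truth$regulation == "up" & truth$s > 0]
  rate_ratio <- function(set) {
    r_s <- mean(sensitive %in% set)
    r_o <- mean(setdiff(truth$transcript, sensitive) %in% set)
    r_s / r_o
  }
  ratios <- vapply(sets, rate_ratio, 0)
  expect_true(all(ratios > 2 & ratios < 4))

  # factor 1: membership independent of truth
  cfg1 <- toy_cohort_config(seed = 31, n_tumour = 4, n_normal = 2,
                            n_per_region = 2000, geneset_fraction = 0.05,
                            geneset_enrichment_factor = 1)
  sets1 <- make_gene_sets(cfg1, truth)
  ratios1 <- vapply(sets1, rate_ratio, 0)
  expect_true(all(ratios1 > 0.7 & ratios1 < 1.4))

  # degenerate pool
  empty_truth <- truth[0, ]
  expect_warning(sets0 <- make_gene_sets(cfg, empty_truth), "empty")
  expect_true(all(lengths(sets0) == 0))

  # invalid factor is a configuration error
  expect_error(toy_cohort_config(seed = 1, geneset_enrichment_factor = 0.5),
               "geneset_enrichment_factor")
})
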