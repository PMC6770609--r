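# Synthetic tumour-cohort generator: arm-level copy-number events rendered
# as segment profiles, negative-binomial counts under an explicit
# copy-number dosage model, sample metadata and synthetic gene sets.
#
# All stochastic stages derive their stream deterministically from the one
# config seed (a fixed per-stage offset), so each stage is reproducible both
# standalone and inside simulate_cohort().

.stage_seed <- function(config, stage)
  (config$seed + c(genome = 0L, cna = 1L, counts = 2L, sets = 3L)[[stage]]) %% .Machine$integer.max

#' Configuration for a synthetic tumour cohort
#'
#' Defaults describe a mixed chromosomal-instability (CIN) / microsatellite-
#' instability (MSI) colon-adenocarcinoma-like cohort: 433 tumours (223 CIN,
#' 60 MSI) and 41 normal mucosa samples; recurrent arm-level gains on 20p/q,
#' 13, 7p/q and 8q; recurrent losses on 18p/q, 8p, 17p, 14, 15, 4p/q, 21, 22
#' and 1p; isochromosome patterns i(8q), i(20q), i(17q), i(1q) and i(5p) at
#' their observed cohort rates. The dosage model scales the expected
#' expression of a transcript by `(CN/2)^s`, where the sensitivity `s`
#' depends on the transcript's regulation class: tumour up-regulated
#' transcripts are more dosage-sensitive than down-regulated ones (the
#' asymmetry behind the positive caricature effect), with unregulated
#' transcripts in between so that a trisomy produces on average the
#' 1.2-1.3-fold transcriptional increase expected of bulk genes.
#'
#' @param seed single integer seed; every stochastic draw in the generator
#'   flows deterministically from it.
#' @param n_tumour,n_normal,n_cin,n_msi cohort sizes; tumours beyond
#'   `n_cin + n_msi` are labelled genome-stable (`GS`).
#' @param region_layout layout id passed to [region_catalog()].
#' @param regions optional custom region table (toy genomes).
#' @param per_region_gain_freq,per_region_loss_freq named numeric vectors,
#'   region id -> per-tumour event probability in \[0, 1\]. Unnamed regions
#'   default to 0.
#' @param whole_gain_freq named numeric vector, chromosome -> probability of
#'   a whole-chromosome gain (a single mis-segregation event gaining every
#'   arm of the chromosome at once); this is what makes wChrN-gain groups
#'   exist at realistic rates even when one arm is individually loss-prone.
#' @param iso_freq named numeric vector of isochromosome probabilities. A
#'   name like `"8q"` means loss of 8p with gain of 8q; `"5p"` the reverse;
#'   a bare chromosome name gains the q arm.
#' @param msi_event_scale multiplier applied to all event probabilities in
#'   MSI samples (MSI tumours carry few broad CNAs).
#' @param n_transcripts_per_region transcripts simulated per region.
#' @param frac_upregulated,frac_downregulated proportions of transcripts
#'   truly up-/down-regulated in tumour vs normal tissue.
#' @param tumour_effect_fc linear fold-change (> 1) of up-regulated
#'   transcripts in tumours; down-regulated transcripts use its reciprocal.
#' @param dosage_exponent_up,dosage_exponent_down,dosage_exponent_null
#'   dosage sensitivities `s` in \[0, 1\] for up-regulated, down-regulated
#'   and unregulated transcripts.
#' @param gain_cn,gain_cn_prob integer copy numbers used for gain events and
#'   their sampling probabilities; `loss_cn` analogous for losses.
#' @param loss_cn copy number of a lost region.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param mean_log_expression,sd_log_expression log-normal parameters of the
#'   per-transcript baseline mean count.
#' @param library_size_sdlog log-normal sd of per-sample library factors.
#' @param geneset_enrichment_factor relative over-representation (>= 1) of
#'   dosage-sensitive up-regulated transcripts in the synthetic fitness /
#'   gained-enhancer-target gene sets.
#' @param geneset_fraction fraction of the transcriptome drawn into each
#'   synthetic gene set.
#' @return object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(seed = 1L,
                              n_tumour = 433L, n_normal = 41L,
                              n_cin = 223L, n_msi = 60L,
                              region_layout = "hg42", regions = NULL,
                              per_region_gain_freq = c(
                                "20p" = 0.10, "20q" = 0.20, "13" = 0.35,
                                "7p" = 0.08, "7q" = 0.08, "8q" = 0.18),
                              whole_gain_freq = c("20" = 0.25, "7" = 0.22,
                                                  "8" = 0.12),
                              per_region_loss_freq = c(
                                "18p" = 0.40, "18q" = 0.45, "8p" = 0.30,
                                "17p" = 0.35, "14" = 0.25, "15" = 0.25,
                                "4p" = 0.25, "4q" = 0.25, "21" = 0.25,
                                "22" = 0.25, "1p" = 0.22),
                              iso_freq = c("8q" = 0.242, "20q" = 0.134,
                                           "17q" = 0.087, "1q" = 0.067,
                                           "5p" = 0.046),
                              msi_event_scale = 0.2,
                              n_transcripts_per_region = 150L,
                              frac_upregulated = 0.15,
                              frac_downregulated = 0.15,
                              tumour_effect_fc = 2,
                              dosage_exponent_up = 0.8,
                              dosage_exponent_down = 0.3,
                              dosage_exponent_null = 0.55,
                              gain_cn = c(3L, 4L), gain_cn_prob = c(0.75, 0.25),
                              loss_cn = 1L,
                              nb_dispersion = 0.1,
                              mean_log_expression = log(100),
                              sd_log_expression = 1,
                              library_size_sdlog = 0.2,
                              geneset_enrichment_factor = 3,
                              geneset_fraction = 0.05) {
  cfg <- list(seed = check_count(seed, "seed"),
              n_tumour = check_count(n_tumour, "n_tumour"),
              n_normal = check_count(n_normal, "n_normal"),
              n_cin = check_count(n_cin, "n_cin"),
              n_msi = check_count(n_msi, "n_msi"),
              region_layout = region_layout, regions = regions,
              per_region_gain_freq = check_prob(per_region_gain_freq, "per_region_gain_freq"),
              whole_gain_freq = check_prob(whole_gain_freq, "whole_gain_freq"),
              per_region_loss_freq = check_prob(per_region_loss_freq, "per_region_loss_freq"),
              iso_freq = check_prob(iso_freq, "iso_freq"),
              msi_event_scale = check_prob(msi_event_scale, "msi_event_scale"),
              n_transcripts_per_region = check_count(n_transcripts_per_region,
                                                     "n_transcripts_per_region", 1L),
              frac_upregulated = check_prob(frac_upregulated, "frac_upregulated"),
              frac_downregulated = check_prob(frac_downregulated, "frac_downregulated"),
              tumour_effect_fc = tumour_effect_fc,
              dosage_exponent_up = dosage_exponent_up,
              dosage_exponent_down = dosage_exponent_down,
              dosage_exponent_null = dosage_exponent_null,
              gain_cn = gain_cn, gain_cn_prob = gain_cn_prob, loss_cn = loss_cn,
              nb_dispersion = nb_dispersion,
              mean_log_expression = mean_log_expression,
              sd_log_expression = sd_log_expression,
              library_size_sdlog = library_size_sdlog,
              geneset_enrichment_factor = geneset_enrichment_factor,
              geneset_fraction = geneset_fraction)
  if (cfg$frac_upregulated + cfg$frac_downregulated > 1)
    stop_config("frac_upregulated + frac_downregulated must be <= 1")
  if (cfg$nb_dispersion <= 0) stop_config("nb_dispersion must be > 0")
  if (cfg$tumour_effect_fc <= 1) stop_config("tumour_effect_fc must be > 1")
  if (cfg$n_cin + cfg$n_msi > cfg$n_tumour)
    stop_config("n_cin + n_msi must not exceed n_tumour")
  if (cfg$geneset_enrichment_factor < 1)
    stop_config("geneset_enrichment_factor must be >= 1")
  class(cfg) <- "simulation_config"
  cfg
}

.draw_gain_cn <- function(config)
  config$gain_cn[sample.int(length(config$gain_cn), 1, prob = config$gain_cn_prob)]

# Resolve an iso_freq name ("8q", "5p" or bare "8") against the catalog.
# Returns NULL for chromosomes without two arm regions.
.iso_target <- function(name, catalog) {
  gain_arm <- if (grepl("[pq]$", name)) substring(name, nchar(name)) else "q"
  chrom <- sub("[pq]$", "", name)
  regs <- catalog[catalog$chrom == chrom & catalog$kind == "arm", , drop = FALSE]
  if (nrow(regs) != 2) return(NULL)
  gain <- paste0(chrom, gain_arm)
  loss <- setdiff(regs$region, gain)
  if (!gain %in% regs$region || length(loss) != 1) return(NULL)
  list(chrom = chrom, gain = gain, loss = loss)
}

#' Simulate segmented copy-number profiles for a cohort
#'
#' Draws independent per-region gain/loss events and per-chromosome
#' isochromosome events (p-loss plus q-gain, or the mirrored pattern) at the
#' configured frequencies, then renders each event as a segment covering a
#' random fraction in (0.55, 1\] of the region so that the >50%-of-arm
#' caller must recover it. Remaining genomic stretches are emitted as CN = 2
#' segments; normal samples are flat CN = 2. MSI samples use event
#' probabilities scaled by `msi_event_scale`.
#'
#' @param config a [simulation_config()].
#' @param catalog region catalog from [build_genome_model()].
#' @return list with `segments` (data frame: `sample`, `chrom`, `start`,
#'   `end`, `cn`; 0-based half-open), `metadata` (data frame: `sample`,
#'   `type`, `instability`), and `events` (ground-truth data frame:
#'   `sample`, `region`, `event`, `cn`).
#' @export
simulate_cna_profiles <- function(config, catalog) {
  set.seed(.stage_seed(config, "cna"))
  gainf <- config$per_region_gain_freq
  lossf <- config$per_region_loss_freq
  bad <- setdiff(c(names(gainf), names(lossf)), catalog$region)
  if (length(bad)) stop_config("event frequencies name unknown regions: ",
                               paste(bad, collapse = ", "))
  badc <- setdiff(names(config$whole_gain_freq), catalog$chrom)
  if (length(badc)) stop_config("whole_gain_freq names unknown chromosomes: ",
                                paste(badc, collapse = ", "))
  instability <- c(rep("CIN", config$n_cin), rep("MSI", config$n_msi),
                   rep("GS", config$n_tumour - config$n_cin - config$n_msi))
  metadata <- data.frame(
    sample = c(sprintf("TUM%03d", seq_len(config$n_tumour)),
               sprintf("NOR%03d", seq_len(config$n_normal))),
    type = c(rep("tumour", config$n_tumour), rep("normal", config$n_normal)),
    instability = c(instability, rep(NA_character_, config$n_normal)),
    stringsAsFactors = FALSE)

  iso_targets <- Filter(Negate(is.null),
                        lapply(names(config$iso_freq), .iso_target, catalog = catalog))
  names(iso_targets) <- vapply(iso_targets, `[[`, "", "chrom")
  iso_p <- config$iso_freq[seq_along(iso_targets)]

  events <- list(); seglist <- list()
  for (i in seq_len(nrow(metadata))) {
    s <- metadata$sample[i]
    ev <- data.frame(region = character(), event = character(), cn = integer(),
                     stringsAsFactors = FALSE)
    if (metadata$type[i] == "tumour") {
      scale <- if (identical(metadata$instability[i], "MSI")) config$msi_event_scale else 1
      # isochromosomes first: they claim both arms of their chromosome
      claimed <- character()
      if (length(iso_targets)) {
        hit <- stats::runif(length(iso_targets)) < unname(iso_p) * scale
        for (t in iso_targets[hit]) {
          gcn <- .draw_gain_cn(config)
          ev <- rbind(ev, data.frame(region = c(t$gain, t$loss),
                                     event = c("gain", "loss"),
                                     cn = c(gcn, config$loss_cn)))
          claimed <- c(claimed, t$gain, t$loss)
        }
      }
      for (ch in names(config$whole_gain_freq)) {
        regs_ch <- catalog$region[catalog$chrom == ch]
        if (!length(regs_ch) || any(regs_ch %in% claimed)) next
        if (stats::runif(1) < config$whole_gain_freq[[ch]] * scale) {
          gcn <- .draw_gain_cn(config)
          ev <- rbind(ev, data.frame(region = regs_ch, event = "gain", cn = gcn))
          claimed <- c(claimed, regs_ch)
        }
      }
      for (r in names(gainf)) {
        if (r %in% claimed) next
        if (stats::runif(1) < gainf[[r]] * scale) {
          ev <- rbind(ev, data.frame(region = r, event = "gain",
                                     cn = .draw_gain_cn(config)))
          claimed <- c(claimed, r)
        }
      }
      for (r in names(lossf)) {
        if (r %in% claimed) next
        if (stats::runif(1) < lossf[[r]] * scale)
          ev <- rbind(ev, data.frame(region = r, event = "loss", cn = config$loss_cn))
      }
    }
    seglist[[s]] <- .render_segments(s, ev, catalog)
    if (nrow(ev)) events[[s]] <- cbind(sample = s, ev)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(sample = character(), region = character(),
               event = character(), cn = integer())
  rownames(events) <- NULL
  segments <- do.call(rbind, seglist)
  rownames(segments) <- NULL
  list(segments = segments, metadata = metadata, events = events)
}

# Render a sample's region events as segments; uncovered stretches are CN=2.
.render_segments <- function(sample, ev, catalog) {
  out <- list()
  for (ch in unique(catalog$chrom)) {
    regs <- catalog[catalog$chrom == ch, , drop = FALSE]
    chrom_lo <- min(regs$start); chrom_hi <- max(regs$end)
    evc <- ev[ev$region %in% regs$region, , drop = FALSE]
    ab <- NULL
    for (j in seq_len(nrow(evc))) {
      r <- regs[regs$region == evc$region[j], ]
      frac <- stats::runif(1, 0.55, 1)
      w <- max(1, round(frac * (r$end - r$start)))
      lo <- if (stats::runif(1) < 0.5) r$start else r$end - w
      ab <- rbind(ab, c(lo, lo + w, evc$cn[j]))
    }
    rows <- NULL
    if (!is.null(ab)) {
      ab <- ab[order(ab[, 1]), , drop = FALSE]
      pos <- chrom_lo
      for (j in seq_len(nrow(ab))) {
        if (ab[j, 1] > pos) rows <- rbind(rows, c(pos, ab[j, 1], 2))
        rows <- rbind(rows, ab[j, ])
        pos <- ab[j, 2]
      }
      if (pos < chrom_hi) rows <- rbind(rows, c(pos, chrom_hi, 2))
    } else {
      rows <- rbind(rows, c(chrom_lo, chrom_hi, 2))
    }
    out[[ch]] <- data.frame(sample = sample, chrom = ch,
                            start = rows[, 1], end = rows[, 2],
                            cn = as.integer(rows[, 3]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Assign ground-truth regulation classes and dosage sensitivities
#'
#' @param config a [simulation_config()].
#' @param annotation transcript annotation from [build_genome_model()].
#' @return data frame: `transcript`, `regulation` (up/down/null), `s`
#'   (dosage sensitivity), `baseline` (mean normal-tissue count).
#' @export
assign_truth <- function(config, annotation) {
  set.seed(.stage_seed(config, "counts"))
  n <- nrow(annotation)
  reg <- sample(c("up", "down", "null"), n, replace = TRUE,
                prob = c(config$frac_upregulated, config$frac_downregulated,
                         1 - config$frac_upregulated - config$frac_downregulated))
  s <- c(up = config$dosage_exponent_up, down = config$dosage_exponent_down,
         null = config$dosage_exponent_null)[reg]
  baseline <- stats::rlnorm(n, config$mean_log_expression, config$sd_log_expression)
  data.frame(transcript = annotation$transcript, regulation = reg,
             s = unname(s), baseline = baseline, stringsAsFactors = FALSE)
}

#' Simulate the RNA-seq count matrix
#'
#' Counts are negative-binomial with mean
#' `baseline * tumourEffect * (CN/2)^s * libraryFactor`, where `CN` is the
#' transcript's region copy number in that sample (from the ground-truth arm
#' events), `s` the transcript's dosage sensitivity and `tumourEffect` the
#' up/down regulation fold in tumours.
#'
#' @param config a [simulation_config()].
#' @param annotation transcript annotation.
#' @param profiles result of [simulate_cna_profiles()].
#' @param truth result of [assign_truth()] (drawn internally when `NULL`).
#' @return list with `counts` (integer matrix, transcripts x samples) and
#'   `truth`.
#' @export
simulate_counts <- function(config, annotation, profiles, truth = NULL) {
  if (is.null(truth)) truth <- assign_truth(config, annotation)
  stopifnot(identical(truth$transcript, annotation$transcript))
  meta <- profiles$metadata
  set.seed((.stage_seed(config, "counts") + 7L) %% .Machine$integer.max)
  libfac <- stats::rlnorm(nrow(meta), 0, config$library_size_sdlog)
  regions <- sort(unique(annotation$region))
  cnmat <- matrix(2, nrow = length(regions), ncol = nrow(meta),
                  dimnames = list(regions, meta$sample))
  ev <- profiles$events
  if (nrow(ev)) {
    keep <- ev$region %in% regions
    cnmat[cbind(match(ev$region[keep], regions), match(ev$sample[keep], meta$sample))] <-
      ev$cn[keep]
  }
  effect <- rep(1, nrow(annotation))
  effect[truth$regulation == "up"] <- config$tumour_effect_fc
  effect[truth$regulation == "down"] <- 1 / config$tumour_effect_fc
  is_tum <- meta$type == "tumour"
  ridx <- match(annotation$region, regions)
  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, nrow = nrow(annotation), ncol = nrow(meta),
                   dimnames = list(annotation$transcript, meta$sample))
  for (j in seq_len(nrow(meta))) {
    mu <- truth$baseline * libfac[j]
    if (is_tum[j]) {
      dos <- (cnmat[ridx, j] / 2)^truth$s
      mu <- mu * effect * dos
    }
    counts[, j] <- as.integer(stats::rnbinom(nrow(annotation), size = size, mu = mu))
  }
  list(counts = counts, truth = truth)
}

#' Draw synthetic gene sets with controlled enrichment
#'
#' Emulates external gene sets (cancer-fitness transcripts, gained-enhancer
#' target transcripts, focal-amplification transcripts) by sampling
#' transcripts with weight `geneset_enrichment_factor` for dosage-sensitive
#' up-regulated transcripts and 1 otherwise.
#'
#' @param config a [simulation_config()].
#' @param truth ground-truth table from [assign_truth()].
#' @param set_names character vector of set names to draw.
#' @return named list of transcript-id character vectors.
#' @export
make_gene_sets <- function(config, truth,
                           set_names = c("fitness", "vel", "amp")) {
  if (config$geneset_enrichment_factor < 1)
    stop_config("geneset_enrichment_factor must be >= 1")
  set.seed(.stage_seed(config, "sets"))
  pool <- truth$transcript
  if (!length(pool)) {
    warning("empty candidate pool: emitting empty gene sets")
    return(stats::setNames(rep(list(character()), length(set_names)), set_names))
  }
  w <- ifelse(truth$regulation == "up" & truth$s > 0,
              config$geneset_enrichment_factor, 1)
  size <- max(1L, round(config$geneset_fraction * length(pool)))
  sets <- lapply(set_names, function(nm) sort(sample(pool, size, prob = w)))
  stats::setNames(sets, set_names)
}

#' Simulate a complete synthetic study
#'
#' Runs the full generator: genome model, copy-number profiles, metadata,
#' count matrix, ground truth and gene sets. Identical `config` (including
#' the seed) reproduces identical output.
#'
#' @param config a [simulation_config()].
#' @return object of class `bcng_cohort`: list with `config`, `catalog`,
#'   `annotation`, `segments`, `metadata`, `counts`, `truth`, `events`,
#'   `gene_sets`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  gm <- build_genome_model(config)
  prof <- simulate_cna_profiles(config, gm$catalog)
  cm <- simulate_counts(config, gm$annotation, prof)
  sets <- make_gene_sets(config, cm$truth)
  structure(list(config = config, catalog = gm$catalog,
                 annotation = gm$annotation, segments = prof$segments,
                 metadata = prof$metadata, counts = cm$counts,
                 truth = cm$truth, events = prof$events, gene_sets = sets),
            class = "bcng_cohort")
}

#' @export
print.bcng_cohort <- function(x, ...) {
  cat("Synthetic cohort:", sum(x$metadata$type == "tumour"), "tumours,",
      sum(x$metadata$type == "normal"), "normals;",
      nrow(x$annotation), "transcripts over", nrow(x$catalog), "regions\n")
  tab <- table(x$truth$regulation)
  cat("Regulation truth:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("Arm events:", nrow(x$events), " Gene sets:",
      paste(names(x$gene_sets), lengths(x$gene_sets), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
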