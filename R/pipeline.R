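# End-to-end orchestration: simulate -> arm calls -> groups -> four DE
# contrasts -> taxonomy -> NCDI -> enrichment, with a manifest of outputs.

#' Run the selected-group analysis on a cohort
#'
#' Calls arm-level CNAs on the tumour samples, builds the selected
#' (BCNG-bearing) and control groups for the target chromosome, runs the
#' four fold-change contrasts, classifies transcripts, computes NCDI
#' profiles and aberration-frequency correlations, and scores per-region
#' enrichment of OverT among the taxonomy classes and gene sets. The
#' ground-truth tables of a synthetic cohort are never consulted.
#'
#' @param cohort a `bcng_cohort` (or a list with `segments`, `metadata`,
#'   `counts`, `annotation`, `catalog` and optional `gene_sets`).
#' @param chromosome target chromosome for group construction.
#' @param mode selection mode passed to [select_gain_group()].
#' @param instability `"all"`, `"CIN"` or `"MSI"`.
#' @param config an [analysis_config()].
#' @param selected_regions regions for the enrichment grid (default: the
#'   target chromosome's regions).
#' @return a `bcng_analysis` list: `groups`, `arm_calls`, `frequencies`,
#'   `de` (FC1..FC4), `classes`, `ncdi` (per class), `correlations`,
#'   `enrichment`, `tested_annotation`.
#' @export
analyze_cohort <- function(cohort, chromosome, mode = "whole-gain",
                           instability = "all", config = analysis_config(),
                           selected_regions = NULL) {
  meta <- cohort$metadata
  tumours <- meta$sample[meta$type == "tumour"]
  normals <- meta$sample[meta$type == "normal"]
  seg_t <- cohort$segments[cohort$segments$sample %in% tumours, , drop = FALSE]
  arm <- call_arm_cna_cohort(seg_t, cohort$catalog)
  sel <- select_gain_group(arm, chromosome, mode, metadata = meta,
                           instability = instability)
  ctl <- select_control_group(arm, chromosome, metadata = meta,
                              instability = instability)
  if (length(sel$samples) < 2 || length(ctl$samples) < 2)
    stop("selected or control group has fewer than 2 samples (",
         sel$id, ": ", length(sel$samples), ", ", ctl$id, ": ",
         length(ctl$samples), ")")
  contrasts <- make_contrasts(sel$samples, ctl$samples, normals)
  de <- lapply(names(contrasts), function(nm)
    de_test(cohort$counts, contrasts[[nm]]$a, contrasts[[nm]]$b,
            contrast = nm))
  names(de) <- names(contrasts)
  common <- Reduce(intersect, lapply(de, `[[`, "transcript"))
  de_c <- lapply(de, function(d) d[d$transcript %in% common, , drop = FALSE])
  classes <- classify_transcripts(de_c$FC1, de_c$FC2, de_c$FC3, de_c$FC4,
                                  config)
  tested_ann <- cohort$annotation[cohort$annotation$transcript %in% common, ,
                                  drop = FALSE]
  class_sets <- list(
    PositiveT = classes$transcript[classes$positive_t],
    NegativeT = classes$transcript[classes$negative_t],
    OverT = classes$transcript[classes$over_t],
    OverPositiveT = classes$transcript[classes$over_positive_t],
    OverNegativeT = classes$transcript[classes$over_negative_t])
  ncdis <- lapply(names(class_sets), function(nm)
    ncdi(class_sets[[nm]], tested_ann, cohort$catalog, class_id = nm))
  names(ncdis) <- names(class_sets)
  freqs <- cna_frequencies(arm)
  correlations <- c(
    positive_gain = .safe_cor(ncdis$PositiveT, freqs, "pct_gain"),
    negative_loss = .safe_cor(ncdis$NegativeT, freqs, "pct_loss"))
  if (is.null(selected_regions))
    selected_regions <- cohort$catalog$region[cohort$catalog$chrom == chromosome]
  enr <- run_enrichment_grid(classes, cohort$gene_sets %||% list(),
                             tested_ann, selected_regions)
  structure(list(groups = list(selected = sel, control = ctl),
                 arm_calls = arm, frequencies = freqs, de = de_c,
                 classes = classes, ncdi = ncdis,
                 correlations = correlations, enrichment = enr,
                 tested_annotation = tested_ann),
            class = "bcng_analysis")
}

.safe_cor <- function(profile, freqs, which) {
  tryCatch(correlate_ncdi_cna(profile, freqs, which),
           error = function(e) NA_real_)
}

#' @export
print.bcng_analysis <- function(x, ...) {
  cat("BCNG analysis:", x$groups$selected$id, "(n =",
      length(x$groups$selected$samples), ") vs", x$groups$control$id,
      "(n =", length(x$groups$control$samples), ")\n")
  cat("Tested transcripts:", nrow(x$classes),
      " OverT:", sum(x$classes$over_t),
      " PositiveT:", sum(x$classes$positive_t),
      " NegativeT:", sum(x$classes$negative_t), "\n")
  cat("NCDI/CNA correlations:",
      paste(names(x$correlations), round(x$correlations, 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a pipeline configuration file
#'
#' YAML with two optional sections: `simulation` (arguments of
#' [simulation_config()]) and `analysis` (`chromosome`, `mode`,
#' `instability`, `fdr_threshold`, `overt_fc2_threshold`, `vt_scope`).
#'
#' @param path YAML file path.
#' @return list with `simulation` (a `simulation_config`) and `analysis`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$simulation %||% list()
  for (nm in c("per_region_gain_freq", "per_region_loss_freq", "iso_freq",
               "whole_gain_freq"))
    if (nm %in% names(sim_args)) {
      v <- unlist(sim_args[[nm]])
      sim_args[[nm]] <- if (is.null(v)) stats::setNames(numeric(0), character(0)) else v
    }
  if (!is.null(sim_args$regions))
    sim_args$regions <- as.data.frame(sim_args$regions,
                                      stringsAsFactors = FALSE)
  sim <- do.call(simulation_config, sim_args)
  an <- raw$analysis %||% list()
  bad <- setdiff(names(an), c("chromosome", "mode", "instability",
                              "fdr_threshold", "overt_fc2_threshold",
                              "vt_scope"))
  if (length(bad)) stop_config("unknown analysis config keys: ",
                               paste(bad, collapse = ", "))
  an$chromosome <- as.character(an$chromosome %||% "8")
  an$mode <- an$mode %||% "whole-gain"
  an$instability <- an$instability %||% "all"
  list(simulation = sim, analysis = an)
}

# Stable hash of a config: canonical (recursively name-sorted) JSON, md5.
.config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x) %||% seq_along(x))]
      lapply(x, canon)
    } else x
  }
  json <- jsonlite::toJSON(canon(unclass(config)), auto_unbox = TRUE,
                           digits = NA, null = "null")
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline from a config file
#'
#' Simulates the cohort, writes its tables, runs [analyze_cohort()] and
#' writes every stage output (calls, frequencies, group membership, one DE
#' table per contrast, class assignment, NCDI profiles, enrichment grid)
#' plus a JSON manifest. Re-running with an identical config reproduces
#' identical outputs.
#'
#' @param config path to a YAML config file, or the list returned by
#'   [read_pipeline_config()].
#' @param outdir output directory.
#' @return a `bcng_run` manifest (invisibly the written structure): list
#'   with `config_hash`, `seed`, `version`, `stages` (file paths and row
#'   counts per stage).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  log_stage <- function(name, files, counts) {
    stages[[name]] <<- list(files = as.list(files), rows = as.list(counts))
    message(sprintf("[%s] %s", name,
                    paste(names(counts), counts, sep = "=", collapse = " ")))
  }
  cohort <- simulate_cohort(config$simulation)
  sim_files <- write_cohort(cohort, file.path(outdir, "cohort"))
  log_stage("simulate", sim_files,
            c(samples = nrow(cohort$metadata),
              transcripts = nrow(cohort$annotation),
              segments = nrow(cohort$segments)))
  an <- config$analysis
  res <- analyze_cohort(cohort, chromosome = an$chromosome, mode = an$mode,
                        instability = an$instability,
                        config = analysis_config(
                          fdr_threshold = an$fdr_threshold %||% 0.05,
                          overt_fc2_threshold = an$overt_fc2_threshold %||% 1.3,
                          vt_scope = an$vt_scope %||% "per-contrast"))
  p <- function(f) file.path(outdir, f)
  calls_df <- data.frame(sample = rownames(res$arm_calls$calls),
                         res$arm_calls$calls, check.names = FALSE)
  f <- c(calls = write_tsv(calls_df, p("arm_calls.tsv")),
         stats = write_tsv(res$arm_calls$sample_stats, p("sample_karyotypes.tsv")),
         freq = write_tsv(res$frequencies, p("cna_frequencies.tsv")))
  log_stage("armcall", f, c(samples = nrow(calls_df),
                            regions = nrow(res$frequencies)))
  members <- rbind(
    data.frame(group = res$groups$selected$id,
               sample = res$groups$selected$samples),
    data.frame(group = res$groups$control$id,
               sample = res$groups$control$samples))
  f <- c(groups = write_tsv(members, p("groups.tsv")))
  log_stage("groups", f, c(selected = length(res$groups$selected$samples),
                           control = length(res$groups$control$samples)))
  de_files <- counts <- c()
  for (nm in names(res$de)) {
    de_files[nm] <- write_tsv(res$de[[nm]], p(paste0("de_", nm, ".tsv")))
    counts[nm] <- nrow(res$de[[nm]])
  }
  log_stage("de", de_files, counts)
  f <- c(classes = write_tsv(res$classes, p("transcript_classes.tsv")))
  log_stage("classify", f,
            c(transcripts = nrow(res$classes), over_t = sum(res$classes$over_t),
              positive_t = sum(res$classes$positive_t),
              negative_t = sum(res$classes$negative_t)))
  ncdi_all <- do.call(rbind, lapply(names(res$ncdi), function(nm)
    cbind(class = nm, as.data.frame(res$ncdi[[nm]]))))
  f <- c(ncdi = write_tsv(ncdi_all, p("ncdi.tsv")),
         correlations = write_tsv(
           data.frame(statistic = names(res$correlations),
                      pearson_r = unname(res$correlations)),
           p("ncdi_cna_correlations.tsv")))
  log_stage("ncdi", f, c(classes = length(res$ncdi)))
  f <- c(enrichment = write_tsv(res$enrichment, p("enrichment.tsv")))
  log_stage("enrich", f, c(cells = nrow(res$enrichment),
                           nc = sum(res$enrichment$nc)))
  manifest <- list(config_hash = .config_hash(config$simulation),
                   seed = config$simulation$seed,
                   version = as.character(utils::packageVersion("bcngdose")),
                   stages = stages)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  for (st in stages)
    for (fp in st$files)
      if (!file.exists(fp)) stop("declared output missing: ", fp)
  structure(c(manifest, list(analysis = res, cohort = cohort)),
            class = "bcng_run")
}

#' @export
print.bcng_run <- function(x, ...) {
  cat("Pipeline run (seed", x$seed, ", config", substr(x$config_hash, 1, 8),
      "):", length(x$stages), "stages completed\n")
  invisible(x)
}
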