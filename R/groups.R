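# Selected (BCNG-bearing) and control tumour groups, and the profile-
# similarity score between their aberration-frequency vectors.

#' Select the tumour group bearing a specific broad copy-number gain
#'
#' Modes: `whole-gain` requires every region of the chromosome to be called
#' gain; `iso-q` requires p-arm loss with q-arm gain (the isochromosome
#' pattern); `iso-p` the mirror image. Isochromosome modes are undefined for
#' single-region (whole-acrocentric) chromosomes.
#'
#' @param arm_calls an `arm_calls` object.
#' @param chromosome chromosome name (e.g. `"8"`).
#' @param mode `"whole-gain"`, `"iso-q"` or `"iso-p"`.
#' @param metadata optional sample metadata with columns `sample` and
#'   `instability`; required when `instability != "all"`.
#' @param instability `"all"`, `"CIN"` or `"MSI"` pre-filter.
#' @return a `group_definition`: list with `id`, `mode`, `chromosome`,
#'   `instability`, `samples`.
#' @export
select_gain_group <- function(arm_calls, chromosome, mode = "whole-gain",
                              metadata = NULL, instability = "all") {
  catalog <- arm_calls$catalog
  regs <- catalog[catalog$chrom == chromosome, , drop = FALSE]
  if (!nrow(regs)) stop("chromosome not in catalog: ", chromosome)
  mode <- match.arg(mode, c("whole-gain", "iso-q", "iso-p"))
  if (mode != "whole-gain" && nrow(regs) < 2)
    stop("isochromosome mode is undefined for single-region chromosome ", chromosome)
  pool <- .instability_pool(arm_calls, metadata, instability)
  m <- arm_calls$calls[pool, regs$region, drop = FALSE]
  members <- switch(mode,
    "whole-gain" = pool[rowSums(m == "gain") == nrow(regs)],
    "iso-q" = pool[m[, paste0(chromosome, "p")] == "loss" &
                   m[, paste0(chromosome, "q")] == "gain"],
    "iso-p" = pool[m[, paste0(chromosome, "p")] == "gain" &
                   m[, paste0(chromosome, "q")] == "loss"])
  id <- if (mode == "whole-gain") paste0("wChr", chromosome, "-gain")
        else paste0("i(", chromosome, sub("iso-", "", mode), ")")
  structure(list(id = id, mode = mode, chromosome = chromosome,
                 instability = instability, samples = members),
            class = "group_definition")
}

#' Select the control group for a chromosome
#'
#' Control tumours have a neutral call on every region of the target
#' chromosome; aberrations elsewhere are not constraining.
#'
#' @inheritParams select_gain_group
#' @return a `group_definition`.
#' @export
select_control_group <- function(arm_calls, chromosome,
                                 metadata = NULL, instability = "all") {
  catalog <- arm_calls$catalog
  regs <- catalog[catalog$chrom == chromosome, , drop = FALSE]
  if (!nrow(regs)) stop("chromosome not in catalog: ", chromosome)
  pool <- .instability_pool(arm_calls, metadata, instability)
  m <- arm_calls$calls[pool, regs$region, drop = FALSE]
  members <- pool[rowSums(m == "neutral") == nrow(regs)]
  if (!length(members)) warning("empty control group for chromosome ", chromosome)
  structure(list(id = paste0("Chr", chromosome, "-control"), mode = "control",
                 chromosome = chromosome, instability = instability,
                 samples = members),
            class = "group_definition")
}

.instability_pool <- function(arm_calls, metadata, instability) {
  pool <- rownames(arm_calls$calls)
  if (identical(instability, "all")) return(pool)
  if (is.null(metadata)) stop("metadata required for instability filtering")
  keep <- metadata$sample[!is.na(metadata$instability) &
                          metadata$instability == instability]
  intersect(pool, keep)
}

#' @export
print.group_definition <- function(x, ...) {
  cat("Group", x$id, "(", x$mode, ", instability:", x$instability, "):",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Profile similarity between two aberration-frequency tables
#'
#' Pearson correlation of the concatenated gain and loss frequency vectors
#' of two groups, after dropping both the gain and the loss entries of the
#' excluded regions (typically the selected chromosome, whose frequencies
#' are structurally 0%/100% by construction).
#'
#' @param freq_a,freq_b frequency tables from [cna_frequencies()] over the
#'   same regions.
#' @param excluded_regions region ids dropped before correlating.
#' @return Pearson correlation coefficient.
#' @export
profile_similarity <- function(freq_a, freq_b, excluded_regions = character()) {
  if (!identical(freq_a$region, freq_b$region))
    stop("frequency tables cover different regions")
  keep <- !freq_a$region %in% excluded_regions
  a <- c(freq_a$pct_gain[keep], freq_a$pct_loss[keep])
  b <- c(freq_b$pct_gain[keep], freq_b$pct_loss[keep])
  if (length(a) < 3) stop("fewer than 3 retained frequency points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant frequency vector: correlation undefined")
  stats::cor(a, b)
}
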