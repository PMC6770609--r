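# Arm-level copy-number calling: convert segmented profiles to per-region
# gain/loss/neutral calls, isochromosome flags, karyotype classes and
# per-region aberration frequencies.
#
# Call rule: a region is called gained (lost) when segments with CN above
# (below) the cohort ploidy cover strictly more than 50% of the region.
# Unsegmented gaps count as neutral bases, which dilutes the aberrant
# fraction (conservative).

# Overlap width of [s1,e1) with [s2,e2), 0-based half-open.
.overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Call arm-level copy-number aberrations for one sample
#'
#' @param segments data frame with columns `chrom`, `start`, `end`, `cn`
#'   (one sample's segmented profile; 0-based half-open).
#' @param catalog a [region_catalog()].
#' @param ploidy reference copy number (default 2); CN above it counts as
#'   gained bases, below as lost bases.
#' @return data frame with one row per catalog region: `region`, `call`
#'   (`gain`/`loss`/`neutral`), `gain_frac`, `loss_frac`.
#' @export
call_arm_cna <- function(segments, catalog, ploidy = 2L) {
  if (any(catalog$end <= catalog$start)) stop("zero-length region in catalog")
  bad <- setdiff(unique(segments$chrom), catalog$chrom)
  if (length(bad))
    stop("segment chromosome(s) outside catalog: ", paste(bad, collapse = ", "))
  gain_frac <- loss_frac <- numeric(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    seg <- segments[segments$chrom == catalog$chrom[i], , drop = FALSE]
    if (!nrow(seg)) next
    ov <- .overlap(seg$start, seg$end, catalog$start[i], catalog$end[i])
    len <- catalog$end[i] - catalog$start[i]
    gain_frac[i] <- sum(ov[seg$cn > ploidy]) / len
    loss_frac[i] <- sum(ov[seg$cn < ploidy]) / len
  }
  call <- ifelse(gain_frac > 0.5, "gain", ifelse(loss_frac > 0.5, "loss", "neutral"))
  data.frame(region = catalog$region, call = call,
             gain_frac = gain_frac, loss_frac = loss_frac,
             stringsAsFactors = FALSE)
}

#' Call arm-level CNAs for a whole cohort
#'
#' @param segments segment table for all samples (column `sample` plus the
#'   columns of [call_arm_cna()]).
#' @param catalog a [region_catalog()].
#' @param ploidy reference copy number.
#' @return an `arm_calls` object: list with `calls` (character matrix,
#'   samples x regions, values `gain`/`loss`/`neutral`), `catalog`, and
#'   `sample_stats` (data frame: `sample`, `n_broad_cna`, `karyotype`).
#' @export
call_arm_cna_cohort <- function(segments, catalog, ploidy = 2L) {
  samples <- unique(segments$sample)
  calls <- matrix("neutral", nrow = length(samples), ncol = nrow(catalog),
                  dimnames = list(samples, catalog$region))
  for (s in samples) {
    row <- call_arm_cna(segments[segments$sample == s, , drop = FALSE],
                        catalog, ploidy)
    calls[s, ] <- row$call
  }
  n_broad <- rowSums(calls != "neutral")
  stats <- data.frame(sample = samples, n_broad_cna = unname(n_broad),
                      karyotype = vapply(n_broad, .karyotype_from_count, ""),
                      stringsAsFactors = FALSE)
  structure(list(calls = calls, catalog = catalog, sample_stats = stats),
            class = "arm_calls")
}

#' @export
print.arm_calls <- function(x, ...) {
  cat("Arm-level CNA calls:", nrow(x$calls), "samples x",
      ncol(x$calls), "regions\n")
  cat("Karyotypes:", paste(names(table(x$sample_stats$karyotype)),
                           table(x$sample_stats$karyotype),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.karyotype_from_count <- function(n) {
  if (n == 0) "normal" else if (n <= 2) "near-normal" else "aberrant"
}

#' Classify a sample's karyotype from its broad-CNA count
#'
#' Zero broad (arm-level) CNAs is a normal karyotype, one or two is
#' near-normal, more than two is aberrant.
#'
#' @param calls character vector of per-region calls
#'   (`gain`/`loss`/`neutral`) for one sample.
#' @return `"normal"`, `"near-normal"` or `"aberrant"`.
#' @export
karyotype_class <- function(calls) {
  .karyotype_from_count(sum(calls != "neutral"))
}

#' Detect isochromosome patterns in one sample's arm calls
#'
#' An isochromosome of the q arm, i(Nq), is flagged when the p arm of
#' chromosome N is lost and its q arm gained; i(Np) is the mirror pattern.
#' Whole-chromosome regions (acrocentrics, Y) are never isochromosomes.
#'
#' @param calls named character vector of per-region calls for one sample
#'   (names are region ids).
#' @param catalog a [region_catalog()].
#' @return data frame: `chrom`, `iso_p`, `iso_q` (logical flags), for every
#'   chromosome with two arm regions in the catalog.
#' @export
detect_isochromosome <- function(calls, catalog) {
  arms <- catalog[catalog$kind == "arm", , drop = FALSE]
  chroms <- unique(arms$chrom)
  chroms <- chroms[vapply(chroms, function(ch) sum(arms$chrom == ch) == 2, TRUE)]
  out <- data.frame(chrom = chroms, iso_p = logical(length(chroms)),
                    iso_q = logical(length(chroms)), stringsAsFactors = FALSE)
  for (i in seq_along(chroms)) {
    p <- calls[[paste0(chroms[i], "p")]]
    q <- calls[[paste0(chroms[i], "q")]]
    if (is.null(p) || is.null(q)) next
    out$iso_q[i] <- identical(p, "loss") && identical(q, "gain")
    out$iso_p[i] <- identical(p, "gain") && identical(q, "loss")
  }
  out
}

#' Per-region aberration frequencies in a sample subset
#'
#' @param arm_calls an `arm_calls` object.
#' @param samples sample ids to tabulate (default: all).
#' @return data frame: `region`, `pct_gain`, `pct_loss` (percentages of the
#'   subset carrying a gain/loss call).
#' @export
cna_frequencies <- function(arm_calls, samples = rownames(arm_calls$calls)) {
  if (!length(samples)) stop("empty sample subset")
  missing <- setdiff(samples, rownames(arm_calls$calls))
  if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
  m <- arm_calls$calls[samples, , drop = FALSE]
  data.frame(region = colnames(m),
             pct_gain = 100 * colMeans(m == "gain"),
             pct_loss = 100 * colMeans(m == "loss"),
             row.names = NULL, stringsAsFactors = FALSE)
}
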