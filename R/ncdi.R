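# Normalized Chromosomal Distribution Index (NCDI): per-region density of a
# transcript class, normalized so the values sum to 100 across regions.

#' NCDI profile of a transcript class
#'
#' For region n, the density is `d_n = x_n / X_n` (class members over all
#' transcripts in the region) and
#' `NCDI_n = d_n / sum_i d_i * 100`, so the profile sums to 100 across the
#' `T` retained regions. Regions with no transcripts at all are dropped with
#' a warning (reducing `T`).
#'
#' @param class_members character vector of transcript ids in the class.
#' @param annotation transcript annotation (`transcript`, `region`) defining
#'   the universe; pass the filtered (tested) annotation to compute NCDI
#'   over the tested universe.
#' @param catalog a [region_catalog()].
#' @param class_id label stored on the profile.
#' @return an `ncdi_profile` data frame: `region`, `x_n`, `X_n`, `density`,
#'   `ncdi`.
#' @export
ncdi <- function(class_members, annotation, catalog, class_id = "class") {
  missing <- setdiff(class_members, annotation$transcript)
  if (length(missing))
    stop("class member(s) absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  regions <- catalog$region
  X_n <- as.integer(table(factor(annotation$region, levels = regions)))
  member_regions <- annotation$region[annotation$transcript %in% class_members]
  x_n <- as.integer(table(factor(member_regions, levels = regions)))
  if (any(X_n == 0)) {
    warning("dropping region(s) with no transcripts: ",
            paste(regions[X_n == 0], collapse = ", "))
    keep <- X_n > 0
    regions <- regions[keep]; X_n <- X_n[keep]; x_n <- x_n[keep]
  }
  density <- x_n / X_n
  total <- sum(density)
  ncdi_v <- if (total > 0) density / total * 100 else rep(0, length(density))
  structure(data.frame(region = regions, x_n = x_n, X_n = X_n,
                       density = density, ncdi = ncdi_v,
                       stringsAsFactors = FALSE),
            class_id = class_id, class = c("ncdi_profile", "data.frame"))
}

#' @export
print.ncdi_profile <- function(x, ...) {
  cat("NCDI profile for class '", attr(x, "class_id"), "' over ",
      nrow(x), " regions (", sum(x$x_n), " members)\n", sep = "")
  top <- x[order(-x$ncdi), ][seq_len(min(5, nrow(x))), c("region", "ncdi")]
  cat("Top regions:", paste(top$region, round(top$ncdi, 1),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' NCDI of a region computed within TPM bins
#'
#' Transcripts are binned on a per-transcript TPM summary (half-open bins
#' `[lo, hi)`, last bin closed), the NCDI computation is restricted to each
#' bin's transcripts, and the value of the requested region is reported per
#' bin. Bins whose restricted universe contains no transcripts in any region
#' yield `NA` (flagged, not an error).
#'
#' @param class_members transcript ids in the class.
#' @param tpm_summary named numeric vector: per-transcript TPM summary (e.g.
#'   mean TPM over the selected group's samples).
#' @param bin_edges strictly increasing bin edges.
#' @param region region id whose NCDI is reported.
#' @inheritParams ncdi
#' @return data frame: `bin`, `lo`, `hi`, `n_universe`, `n_class`, `ncdi`.
#' @export
ncdi_by_tpm_bin <- function(class_members, tpm_summary, bin_edges, region,
                            annotation, catalog) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (!region %in% catalog$region) stop("unknown region: ", region)
  tpm <- tpm_summary[annotation$transcript]
  if (anyNA(tpm)) stop("tpm_summary missing for some annotated transcripts")
  nb <- length(bin_edges) - 1
  out <- data.frame(bin = seq_len(nb), lo = bin_edges[-length(bin_edges)],
                    hi = bin_edges[-1], n_universe = 0L, n_class = 0L,
                    ncdi = NA_real_)
  idx <- findInterval(tpm, bin_edges, rightmost.closed = TRUE)
  for (b in seq_len(nb)) {
    ann_b <- annotation[idx == b, , drop = FALSE]
    out$n_universe[b] <- nrow(ann_b)
    if (!nrow(ann_b)) next
    members_b <- intersect(class_members, ann_b$transcript)
    out$n_class[b] <- length(members_b)
    prof <- suppressWarnings(ncdi(members_b, ann_b, catalog))
    v <- prof$ncdi[prof$region == region]
    out$ncdi[b] <- if (length(v)) v else NA_real_
  }
  out
}

#' Correlate an NCDI profile with aberration frequencies
#'
#' Pearson correlation across regions between a class's NCDI values and
#' per-region aberration percentages (gain or loss).
#'
#' @param profile an [ncdi()] profile.
#' @param freqs frequency table from [cna_frequencies()].
#' @param which `"pct_gain"` or `"pct_loss"`.
#' @return Pearson correlation coefficient.
#' @export
correlate_ncdi_cna <- function(profile, freqs, which = "pct_gain") {
  which <- match.arg(which, c("pct_gain", "pct_loss"))
  m <- match(profile$region, freqs$region)
  if (anyNA(m)) stop("frequency table missing region(s): ",
                     paste(profile$region[is.na(m)], collapse = ", "))
  x <- profile$ncdi; y <- freqs[[which]][m]
  if (length(x) < 3) stop("need at least 3 regions")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  stats::cor(x, y)
}
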