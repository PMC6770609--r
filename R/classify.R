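# Transcript taxonomy from the four fold-change contrasts, biotype
# partition and Venn partitions.

#' Analysis configuration for transcript classification
#'
#' @param fdr_threshold FDR cut-off defining variable transcripts (VT).
#' @param overt_fc2_threshold linear FC2 threshold defining overexpressed
#'   transcripts (OverT).
#' @param tpm_bin_edges strictly increasing bin edges for TPM binning.
#' @param vt_scope `"per-contrast"` (significance of each flag comes from
#'   its own contrast) or `"fc1"` (the VT universe is fixed by the FC1
#'   contrast and reused for OverT).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(fdr_threshold = 0.05, overt_fc2_threshold = 1.3,
                            tpm_bin_edges = c(0, 1, 5, 10, 50, 100, 500, Inf),
                            vt_scope = c("per-contrast", "fc1")) {
  if (fdr_threshold <= 0 || overt_fc2_threshold <= 0)
    stop_config("thresholds must be positive")
  if (any(diff(tpm_bin_edges) <= 0))
    stop_config("tpm_bin_edges must be strictly increasing")
  structure(list(fdr_threshold = fdr_threshold,
                 overt_fc2_threshold = overt_fc2_threshold,
                 tpm_bin_edges = tpm_bin_edges,
                 vt_scope = match.arg(vt_scope)),
            class = "analysis_config")
}

#' Assign the transcript taxonomy from the four contrasts
#'
#' Flags per transcript: `vt_fc1..vt_fc4` (FDR below threshold in that
#' contrast); cohort-level `positive_t_fc1`/`negative_t_fc1` (VT in FC1 with
#' linear FC above/below 1); `positive_t_fc3`/`positive_t_fc4` (VT in
#' FC3/FC4 with FC above 1); group-level `positive_t` (VT in both FC3 and
#' FC4 with both FCs above 1) and `negative_t` (both below 1); `over_t` (VT
#' in FC2 with linear FC2 above the OverT threshold); `over_positive_t`
#' (OverT with FC3 and FC4 above 1) and `over_negative_t` (OverT with both
#' below 1). Signed linear fold-changes below 1 are negative under the
#' reporting convention, so "FC < 1" is tested as a negative signed value.
#'
#' @param de_fc1,de_fc2,de_fc3,de_fc4 `de_result` tables over the same
#'   transcript universe.
#' @param config an [analysis_config()].
#' @return a `transcript_classes` data frame of logical flags keyed by
#'   `transcript`.
#' @export
classify_transcripts <- function(de_fc1, de_fc2, de_fc3, de_fc4,
                                 config = analysis_config()) {
  tabs <- list(de_fc1, de_fc2, de_fc3, de_fc4)
  u <- tabs[[1]]$transcript
  for (t in tabs[-1]) {
    if (!setequal(t$transcript, u) || length(t$transcript) != length(u)) {
      diff <- union(setdiff(t$transcript, u), setdiff(u, t$transcript))
      stop("contrast universes differ; symmetric difference: ",
           paste(utils::head(diff, 10), collapse = ", "),
           if (length(diff) > 10) " ..." else "")
    }
  }
  tabs <- lapply(tabs, function(t) t[match(u, t$transcript), ])
  thr <- config$fdr_threshold
  vt <- lapply(tabs, function(t) t$fdr < thr)
  fc <- lapply(tabs, function(t) t$fc)
  # signed convention: fc > 1 means up, fc < 0 means linear ratio < 1
  up3 <- fc[[3]] > 1; dn3 <- fc[[3]] < 0
  up4 <- fc[[4]] > 1; dn4 <- fc[[4]] < 0
  over_sig <- if (config$vt_scope == "fc1") vt[[1]] else vt[[2]]
  over_t <- over_sig & fc[[2]] > config$overt_fc2_threshold
  out <- data.frame(
    transcript = u,
    vt_fc1 = vt[[1]], vt_fc2 = vt[[2]], vt_fc3 = vt[[3]], vt_fc4 = vt[[4]],
    positive_t_fc1 = vt[[1]] & fc[[1]] > 1,
    negative_t_fc1 = vt[[1]] & fc[[1]] < 0,
    positive_t_fc3 = vt[[3]] & up3,
    positive_t_fc4 = vt[[4]] & up4,
    positive_t = vt[[3]] & vt[[4]] & up3 & up4,
    negative_t = vt[[3]] & vt[[4]] & dn3 & dn4,
    over_t = over_t,
    over_positive_t = over_t & up3 & up4,
    over_negative_t = over_t & dn3 & dn4,
    stringsAsFactors = FALSE)
  class(out) <- c("transcript_classes", "data.frame")
  out
}

#' @export
print.transcript_classes <- function(x, ...) {
  n <- vapply(x[vapply(x, is.logical, TRUE)], sum, 0L)
  cat("Transcript classes over", nrow(x), "transcripts:\n")
  print(n)
  invisible(x)
}

#' Partition class assignments by transcript biotype
#'
#' Splits the assignment into protein-coding, lincRNA and other non-coding
#' tables. `TEC` (to be experimentally confirmed) and missing biotypes are
#' excluded; unknown biotype labels are routed to the other-non-coding table
#' with a warning.
#'
#' @param assignment a `transcript_classes` table.
#' @param annotation annotation with `transcript` and `biotype` columns.
#' @return named list of three disjoint `transcript_classes` tables
#'   (`protein_coding`, `lincRNA`, `other_noncoding`) plus `excluded`
#'   (character vector of excluded transcript ids).
#' @export
biotype_partition <- function(assignment, annotation) {
  bt <- annotation$biotype[match(assignment$transcript, annotation$transcript)]
  if (anyNA(match(assignment$transcript, annotation$transcript)))
    stop("transcripts missing from annotation")
  excluded <- is.na(bt) | bt %in% c("TEC", "not_assessed", "NA")
  known <- c("protein_coding", "lincRNA", "other_noncoding")
  odd <- !excluded & !bt %in% known
  if (any(odd)) {
    warning("unknown biotype label(s) routed to other_noncoding: ",
            paste(unique(bt[odd]), collapse = ", "))
    bt[odd] <- "other_noncoding"
  }
  out <- lapply(known, function(k) assignment[!excluded & bt == k, , drop = FALSE])
  names(out) <- known
  out$excluded <- assignment$transcript[excluded]
  out
}

#' Three-set Venn partition counts
#'
#' @param set_a,set_b,set_c character vectors (e.g. transcripts with
#'   FC2 > 1.3, FC3 > 1, FC4 > 1; the triple overlap then counts the
#'   Over-PositiveT candidates).
#' @return named integer vector of the 7 intersection regions:
#'   `a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`.
#' @export
venn_counts <- function(set_a, set_b, set_c) {
  u <- unique(c(set_a, set_b, set_c))
  ina <- u %in% set_a; inb <- u %in% set_b; inc <- u %in% set_c
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}
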