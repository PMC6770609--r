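# Differential-expression engine: TMM normalization, exact conditional
# negative-binomial two-group test with moderated dispersion, BH-FDR,
# signed linear fold-changes and TPM.

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Composition-bias normalization for count libraries: for each sample, the
#' precision-weighted mean of per-transcript log2 expression ratios (M
#' values) against a reference sample, after trimming the most extreme M and
#' A (average abundance) values. The reference is the column whose
#' upper-quartile/library-size ratio is closest to the cohort mean. Factors
#' are rescaled to have geometric mean 1.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param trim_m two-sided trim proportion on M values (default 0.30).
#' @param trim_a two-sided trim proportion on A values (default 0.05).
#' @return named numeric vector of per-sample normalization factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with all-zero counts: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  uq <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], lib[j], counts[, ref], lib[ref], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# One sample's TMM factor against the reference column.
.tmm_pair <- function(obs, nobs, ref, nref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  p_o <- obs[keep] / nobs
  p_r <- ref[keep] / nref
  m <- log2(p_o / p_r)
  a <- (log2(p_o) + log2(p_r)) / 2
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  # asymptotic variance of M (delta method, binomial sampling)
  w <- (nobs - obs[keep]) / (nobs * obs[keep]) +
       (nref - ref[keep]) / (nref * ref[keep])
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' Signed linear fold-change
#'
#' Converts a log2 fold-change to the linear scale with the
#' negative-reciprocal reporting convention: linear fold-changes below 1 are
#' reported as the negative of their reciprocal, so a ratio of 1/2 is
#' reported as -2. Signed values never fall strictly inside (-1, 1).
#'
#' @param log2fc numeric vector of log2 fold-changes.
#' @return numeric vector of signed linear fold-changes.
#' @examples
#' signed_linear_fc(c(-1, 0, 1))  # -2, 1, 2
#' @export
signed_linear_fc <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  linear <- 2^log2fc
  ifelse(linear >= 1, linear, -1 / linear)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted FDR values, in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Transcripts-per-million (TPM) matrix
#'
#' Length-normalized expression: per sample, `rate = count/length` is
#' rescaled so the column sums to 1e6.
#'
#' @param counts matrix, transcripts x samples.
#' @param lengths transcript lengths (bp), aligned with rows.
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts)) stop("lengths must match rows of counts")
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

# Conditional log-pmf of the group-A sum given the total, for iid NB counts
# with common mean and size r per sample: beta-binomial(t, nA*r, nB*r).
.dbetabinom_log <- function(s, t, a, b) {
  lchoose(t, s) + lbeta(s + a, t - s + b) - lbeta(a, b)
}

# Per-group conditional log-likelihood of counts given their sum (dispersion
# estimation; the common mean cancels out). y: counts, r: NB size (1/phi).
.cond_loglik_group <- function(y, r) {
  n <- length(y); z <- sum(y)
  sum(lgamma(y + r)) - n * lgamma(r) - sum(lfactorial(y)) +
    lfactorial(z) + lgamma(n * r) - lgamma(z + n * r)
}

# Conditional log-likelihood matrix: transcripts x dispersion-grid values.
.cond_loglik_matrix <- function(ya, yb, phi_grid) {
  vapply(phi_grid, function(phi) {
    r <- 1 / phi
    apply(ya, 1, .cond_loglik_group, r = r) +
      apply(yb, 1, .cond_loglik_group, r = r)
  }, numeric(nrow(ya)))
}

#' Exact negative-binomial two-group differential-expression test
#'
#' Libraries are TMM-normalized and equalized to a common effective size;
#' per-transcript dispersions are estimated by conditional maximum
#' likelihood on a grid and shrunk toward the cohort-common estimate with
#' `prior_n` transcripts' worth of weight. The test conditions on the total
#' count of each transcript: under the null of equal means the group-A sum
#' follows a beta-binomial law, and the two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#' Fold-changes are ratios of normalized group means (with a small prior
#' count), reported as log2 and as signed linear values.
#'
#' @param counts matrix, transcripts x samples (raw counts).
#' @param group_a,group_b column names (or indices) of the two groups;
#'   fold-changes are group A over group B.
#' @param factors optional per-sample normalization factors for the
#'   involved samples; computed by [tmm_factors()] on the submatrix when
#'   `NULL`.
#' @param contrast label stored in the result (e.g. `"FC2"`).
#' @param cpm_filter keep transcripts with counts-per-million above this
#'   value in at least `min(|A|, |B|)` samples (default 1). Transcripts with
#'   all-zero counts are always excluded.
#' @param prior_n shrinkage weight (in equivalent transcripts) pulling
#'   per-transcript dispersions toward the common value.
#' @param prior_count prior count added to normalized group means for
#'   fold-change stabilisation.
#' @return a `de_result` data frame: `transcript`, `mean_expr` (mean
#'   normalized count), `log2fc`, `fc` (signed linear), `pvalue`, `fdr`;
#'   attributes `contrast`, `n_a`, `n_b`, `common_dispersion`.
#' @export
de_test <- function(counts, group_a, group_b, factors = NULL,
                    contrast = "FC", cpm_filter = 1, prior_n = 10,
                    prior_count = 0.5) {
  counts <- as.matrix(counts)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  sub <- counts[, c(group_a, group_b), drop = FALSE]
  if (is.null(factors)) factors <- tmm_factors(sub)
  eff <- colSums(sub) * factors
  # expression filter
  cpm <- sweep(sub, 2, eff, "/") * 1e6
  nmin <- min(length(group_a), length(group_b))
  keep <- rowSums(cpm > cpm_filter) >= nmin & rowSums(sub) > 0
  sub <- sub[keep, , drop = FALSE]
  if (!nrow(sub)) stop("no transcripts pass the expression filter")
  # equalize libraries to their geometric mean (pseudo-counts)
  target <- exp(mean(log(eff)))
  pseudo <- round(sweep(sub, 2, eff, "/") * target)
  ia <- seq_along(group_a); ib <- length(group_a) + seq_along(group_b)
  ya <- pseudo[, ia, drop = FALSE]; yb <- pseudo[, ib, drop = FALSE]

  phi_grid <- exp(seq(log(1e-4), log(5), length.out = 49))
  ll <- .cond_loglik_matrix(ya, yb, phi_grid)
  llbar <- colMeans(ll)
  # continuous refinement of the common (cohort) dispersion around the grid max
  j <- which.max(llbar)
  lo <- phi_grid[max(1, j - 1)]; hi <- phi_grid[min(length(phi_grid), j + 1)]
  common_phi <- stats::optimize(function(phi) {
    r <- 1 / phi
    mean(apply(ya, 1, .cond_loglik_group, r = r) +
         apply(yb, 1, .cond_loglik_group, r = r))
  }, c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum
  score <- ll + matrix(prior_n * llbar, nrow(ll), ncol(ll), byrow = TRUE)
  phi <- phi_grid[max.col(score, ties.method = "first")]
  # snap tagwise values near the consensus onto the refined common estimate
  phi[abs(log(phi) - log(phi_grid[j])) < 1e-8] <- common_phi

  sa <- rowSums(ya); sb <- rowSums(yb); tt <- sa + sb
  na <- length(ia); nb <- length(ib)
  pval <- vapply(seq_len(nrow(pseudo)), function(i) {
    if (tt[i] == 0) return(1)
    .exact_nb_p(sa[i], tt[i], na / phi[i], nb / phi[i])
  }, 0)

  norm <- sweep(sub, 2, eff, "/") * target
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  log2fc <- log2((mean_a + prior_count) / (mean_b + prior_count))
  res <- data.frame(transcript = rownames(sub) %||% as.character(seq_len(nrow(sub))),
                    mean_expr = (mean_a + mean_b) / 2,
                    log2fc = log2fc, fc = signed_linear_fc(log2fc),
                    pvalue = pval, fdr = bh_adjust(pval),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, contrast = contrast, n_a = na, n_b = nb,
            common_dispersion = common_phi,
            class = c("de_result", "data.frame"))
}

# Exact conditional two-sided p: total probability of outcomes whose
# conditional pmf does not exceed the observed one.
.exact_nb_p <- function(s_obs, t, a, b) {
  s <- 0:t
  lp <- .dbetabinom_log(s, t, a, b)
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  min(1, sum(p[p <= p[s_obs + 1] * (1 + 1e-10)]))
}

#' @export
print.de_result <- function(x, ...) {
  cat("Differential expression (", attr(x, "contrast"), "): ",
      nrow(x), " transcripts tested, ",
      sum(x$fdr < 0.05), " at FDR < 0.05; groups ",
      attr(x, "n_a"), " vs ", attr(x, "n_b"),
      "; common dispersion ", signif(attr(x, "common_dispersion"), 3), "\n", sep = "")
  invisible(x)
}

#' Build the four fold-change contrasts of the selected-group analysis
#'
#' FC1 compares all tumours (selected plus control) with normals, FC2 the
#' selected group with its control group, FC3 the control group with
#' normals, FC4 the selected group with normals.
#'
#' @param selected,control,normals character vectors of sample ids.
#' @return named list of contrasts, each `list(a = , b = )` with fold-change
#'   direction a over b.
#' @export
make_contrasts <- function(selected, control, normals) {
  if (length(intersect(selected, control)))
    stop("selected and control groups overlap")
  if (length(intersect(c(selected, control), normals)))
    stop("normals overlap a tumour group")
  list(FC1 = list(a = c(selected, control), b = normals),
       FC2 = list(a = selected, b = control),
       FC3 = list(a = control, b = normals),
       FC4 = list(a = selected, b = normals))
}
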