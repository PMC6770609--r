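# Signed hypergeometric enrichment/depletion of a query transcript class
# within annotated sets, per chromosomal region.

#' Signed hypergeometric enrichment or depletion test
#'
#' Given a universe of `N` transcripts of which `K` belong to the annotated
#' set, a query of size `n` with overlap `k` is scored against
#' `X ~ Hypergeometric(N, K, n)`: the direction is enrichment when `k`
#' meets or exceeds the expectation `nK/N` (upper-tail p, `P(X >= k)`) and
#' depletion otherwise (lower tail, `P(X <= k)`). The fold `k/expected` is
#' reported with the negative-reciprocal convention (folds below 1 as minus
#' the reciprocal), matching the signed depletion entries of enrichment
#' tables.
#'
#' @param universe character vector of transcript ids (e.g. all tested
#'   transcripts of one region).
#' @param annotated_set,query_set transcript id vectors; intersected with
#'   the universe before testing.
#' @param region optional region label carried into the result.
#' @return an `enrichment_result` one-row data frame: `region`, `N`, `K`,
#'   `n`, `k`, `expected`, `fold`, `signed_fold`, `pvalue`, `direction`.
#' @export
hypergeom_enrichment <- function(universe, annotated_set, query_set,
                                 region = NA_character_) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  K <- length(intersect(annotated_set, universe))
  q <- intersect(query_set, universe)
  n <- length(q)
  if (n == 0) stop("empty query set (after restriction to the universe)")
  N <- length(universe)
  k <- length(intersect(q, annotated_set))
  expected <- n * K / N
  if (expected == 0) stop("expected overlap is zero (empty annotated set)")
  fold <- k / expected
  signed <- if (fold >= 1) fold else -1 / fold
  if (k >= expected) {
    direction <- "enrichment"
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    direction <- "depletion"
    p <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
  }
  structure(data.frame(region = region, N = N, K = K, n = n, k = k,
                       expected = expected, fold = fold, signed_fold = signed,
                       pvalue = p, direction = direction,
                       stringsAsFactors = FALSE),
            class = c("enrichment_result", "data.frame"))
}

#' Per-region enrichment grid of OverT among transcript classes
#'
#' For each selected region, tests the enrichment/depletion of the
#' overexpressed transcripts (OverT) among each annotated class: the
#' taxonomy's PositiveT and NegativeT plus any external gene sets (e.g.
#' fitness transcripts, gained-enhancer targets, focal-amplification
#' transcripts). The universe of each test is the set of transcripts
#' annotated to the region (pass the tested-only annotation for a
#' tested-transcript universe). Cells whose annotated set is empty in the
#' region are marked not computable (`NC`).
#'
#' @param assignment a `transcript_classes` table.
#' @param gene_sets named list of transcript-id vectors (may be empty).
#' @param annotation transcript annotation defining the per-region universe.
#' @param selected_regions region ids to test.
#' @return an `enrichment_grid` data frame: one row per region x class with
#'   the columns of [hypergeom_enrichment()] plus `class` and `nc`.
#' @export
run_enrichment_grid <- function(assignment, gene_sets, annotation,
                                selected_regions) {
  classes <- c(list(PositiveT = assignment$transcript[assignment$positive_t],
                    NegativeT = assignment$transcript[assignment$negative_t]),
               gene_sets)
  overt <- assignment$transcript[assignment$over_t]
  rows <- list()
  for (rg in selected_regions) {
    uni <- intersect(annotation$transcript[annotation$region == rg],
                     assignment$transcript)
    for (cls in names(classes)) {
      K <- length(intersect(classes[[cls]], uni))
      n <- length(intersect(overt, uni))
      if (!length(uni) || K == 0 || n == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          region = rg, class = cls, N = length(uni), K = K, n = n, k = NA_integer_,
          expected = NA_real_, fold = NA_real_, signed_fold = NA_real_,
          pvalue = NA_real_, direction = NA_character_, nc = TRUE,
          stringsAsFactors = FALSE)
      } else {
        r <- hypergeom_enrichment(uni, classes[[cls]], overt, region = rg)
        r$class <- cls; r$nc <- FALSE
        rows[[length(rows) + 1]] <-
          r[c("region", "class", "N", "K", "n", "k", "expected",
              "fold", "signed_fold", "pvalue", "direction", "nc")]
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_grid", "data.frame")
  out
}

#' @export
print.enrichment_grid <- function(x, ...) {
  if (all(c("region", "class", "nc") %in% names(x)))
    cat("Enrichment grid:", length(unique(x$region)), "regions x",
        length(unique(x$class)), "classes;",
        sum(x$nc), "cells not computable\n")
  NextMethod()
}
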