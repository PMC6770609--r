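# Genome partition into chromosomal regions (arms / whole acrocentric
# chromosomes) and synthetic transcript annotation.

# hg38 chromosome lengths and approximate centromere midpoints (bp).
# Acrocentric autosomes (13, 14, 15, 21, 22) and Y are treated as single
# whole-chromosome regions; everything else splits into p and q arms.
.hg38 <- data.frame(
  chrom = c(as.character(1:22), "X", "Y"),
  length = c(248956422, 242193529, 198295559, 190214555, 181538259,
             170805979, 159345973, 145138636, 138394717, 133797422,
             135086622, 133275309, 114364328, 107043718, 101991189,
             90338345, 83257441, 80373285, 58617616, 64444167,
             46709983, 50818468, 156040895, 57227415),
  centromere = c(123400000, 93900000, 90900000, 50000000, 48800000,
                 59800000, 60100000, 45200000, 43000000, 39800000,
                 53400000, 35500000, NA, NA, NA,
                 36800000, 25100000, 18500000, 26200000, 28100000,
                 NA, NA, 61000000, NA),
  stringsAsFactors = FALSE
)
.acrocentric <- c("13", "14", "15", "21", "22")

#' Build a chromosomal region catalog
#'
#' Partitions the genome into the regions over which arm-level copy-number
#' calls, transcript densities and the NCDI are computed. The default
#' `"hg42"` layout yields 42 regions: p and q arms of the 17 non-acrocentric
#' autosomes, the 5 acrocentric autosomes (13, 14, 15, 21, 22) as whole
#' chromosomes, Xp, Xq, and Y as a whole chromosome. Coordinates are 0-based
#' half-open.
#'
#' @param layout layout id; `"hg42"` is the only built-in layout.
#' @param regions optional data frame with columns `region`, `chrom`,
#'   `start`, `end`, `kind` (`"arm"` or `"whole"`) overriding `layout`;
#'   used for toy genomes in tests and simulations.
#' @return a `region_catalog`: data frame with columns `region`, `chrom`,
#'   `start`, `end`, `kind`.
#' @examples
#' nrow(region_catalog())  # 42
#' @export
region_catalog <- function(layout = "hg42", regions = NULL) {
  if (!is.null(regions)) {
    req <- c("region", "chrom", "start", "end", "kind")
    if (!all(req %in% names(regions)))
      stop_config("custom region table needs columns: ", paste(req, collapse = ", "))
    cat <- regions[req]
  } else if (identical(layout, "hg42")) {
    rows <- lapply(seq_len(nrow(.hg38)), function(i) {
      chrom <- .hg38$chrom[i]; len <- .hg38$length[i]; cen <- .hg38$centromere[i]
      if (chrom %in% .acrocentric || chrom == "Y") {
        data.frame(region = chrom, chrom = chrom, start = 0, end = len,
                   kind = "whole", stringsAsFactors = FALSE)
      } else {
        data.frame(region = paste0(chrom, c("p", "q")), chrom = chrom,
                   start = c(0, cen), end = c(cen, len),
                   kind = "arm", stringsAsFactors = FALSE)
      }
    })
    cat <- do.call(rbind, rows)
  } else {
    stop_config("unknown region layout: ", layout)
  }
  cat$chrom <- as.character(cat$chrom)
  cat$region <- as.character(cat$region)
  if (anyDuplicated(cat$region)) stop_config("region ids must be unique")
  if (any(cat$end <= cat$start)) stop_config("regions must have positive length")
  for (ch in unique(cat$chrom)) {
    r <- cat[cat$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop_config("regions overlap on chromosome ", ch)
  }
  rownames(cat) <- NULL
  class(cat) <- c("region_catalog", "data.frame")
  cat
}

#' @export
print.region_catalog <- function(x, ...) {
  cat("Region catalog:", nrow(x), "regions on",
      length(unique(x$chrom)), "chromosomes\n")
  if ("X_n" %in% names(x)) cat("Transcript totals X_n:", sum(x$X_n), "transcripts\n")
  NextMethod()
}

#' Build the genome model for a synthetic cohort
#'
#' Creates the region catalog for the configured layout and places
#' `n_transcripts_per_region` transcripts uniformly inside each region, with
#' log-normal transcript lengths and a biotype drawn from protein-coding,
#' lincRNA and other non-coding categories. Deterministic given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `catalog` (a `region_catalog` with an `X_n`
#'   transcript-total column) and `annotation` (data frame: `transcript`,
#'   `gene`, `chrom`, `start`, `end`, `length`, `biotype`, `region`).
#' @export
build_genome_model <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cat <- region_catalog(layout = config$region_layout, regions = config$regions)
  ntr <- check_count(config$n_transcripts_per_region, "n_transcripts_per_region", min = 1L)
  set.seed(config$seed)
  ann <- do.call(rbind, lapply(seq_len(nrow(cat)), function(i) {
    n <- ntr
    start <- sort(floor(stats::runif(n, cat$start[i], cat$end[i])))
    len <- pmax(200L, round(stats::rlnorm(n, meanlog = log(1500), sdlog = 0.8)))
    len <- pmin(len, cat$end[i] - start)  # keep transcripts inside the region
    biotype <- sample(c("protein_coding", "lincRNA", "other_noncoding"),
                      n, replace = TRUE, prob = c(0.55, 0.2, 0.25))
    data.frame(
      transcript = sprintf("T_%s_%04d", cat$region[i], seq_len(n)),
      gene = sprintf("G_%s_%04d", cat$region[i], seq_len(n)),
      chrom = cat$chrom[i], start = start, end = start + len,
      length = len, biotype = biotype, region = cat$region[i],
      stringsAsFactors = FALSE)
  }))
  rownames(ann) <- NULL
  cat$X_n <- as.integer(table(factor(ann$region, levels = cat$region)))
  list(catalog = cat, annotation = ann)
}
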