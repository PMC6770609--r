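# Plain-text readers/writers for the pipeline's interchange formats.

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits the SEG-like segment table, the count matrix, transcript
#' annotation, sample metadata, region catalog, ground truth and one
#' one-id-per-line file per gene set.
#'
#' @param cohort a `bcng_cohort` from [simulate_cohort()].
#' @param outdir output directory (created if missing).
#' @return named character vector of written file paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  counts <- data.frame(transcript = rownames(cohort$counts),
                       cohort$counts, check.names = FALSE)
  files <- c(segments = write_tsv(cohort$segments, p("segments.seg.tsv")),
             counts = write_tsv(counts, p("counts.tsv")),
             annotation = write_tsv(cohort$annotation, p("annotation.tsv")),
             metadata = write_tsv(cohort$metadata, p("metadata.tsv")),
             catalog = write_tsv(as.data.frame(cohort$catalog), p("catalog.tsv")),
             truth = write_tsv(cohort$truth, p("truth.tsv")),
             events = write_tsv(cohort$events, p("truth_events.tsv")))
  for (nm in names(cohort$gene_sets)) {
    f <- p(paste0("geneset_", nm, ".txt"))
    writeLines(cohort$gene_sets[[nm]], f)
    files[paste0("geneset_", nm)] <- f
  }
  invisible(files)
}

#' Read a SEG-like segment table
#'
#' Expects tab-separated columns `sample`, `chrom`, `start`, `end`, `cn`
#' (0-based half-open coordinates, integer copy number).
#'
#' @param path file path.
#' @return data frame of segments.
#' @export
read_seg <- function(path) {
  seg <- read_tsv(path)
  req <- c("sample", "chrom", "start", "end", "cn")
  if (!all(req %in% names(seg)))
    stop("SEG file needs columns: ", paste(req, collapse = ", "))
  seg$chrom <- as.character(seg$chrom)
  seg
}

#' Read a count matrix written by [write_cohort()]
#'
#' @param path file path (first column `transcript`, one column per sample).
#' @return integer matrix, transcripts x samples.
#' @export
read_counts <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a region catalog from a cytoband-style TSV
#'
#' @param path file path with columns `region`, `chrom`, `start`, `end`,
#'   `kind`.
#' @return a `region_catalog`.
#' @export
read_catalog <- function(path) {
  region_catalog(regions = read_tsv(path))
}

#' Read a one-id-per-line gene-set file
#'
#' @param path file path.
#' @return character vector of ids.
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}
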