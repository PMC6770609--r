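`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("bcngdose_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_config(name, " must be numeric in [0, 1]")
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_config(name, " must be a single integer >= ", min)
  invisible(as.integer(x))
}

#' Write a data frame as a tab-separated file
#'
#' Plain TSV with a header row, no quoting, no row names. Used for every
#' intermediate table the pipeline emits so that stage outputs stay diffable.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated file written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
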