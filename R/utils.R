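#' Derive a deterministic substream seed for a pipeline stage
#'
#' Every stochastic stage draws from its own substream so that stages can be
#' rerun independently while a single integer seed fixes the whole run.
#' The substream seed is a deterministic function of the global seed and the
#' stage name, kept within the 32-bit integer range.
#'
#' @param seed global integer seed.
#' @param stage character stage name (e.g. `"est"`, `"rnaseq"`).
#' @return an integer seed for `set.seed()`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer((abs(seed) %% 1000003) * 2011 + h) %% 2147483647L
}

#' Read a tab-separated table
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table (header row, UTF-8, LF)
#'
#' @param x data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
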