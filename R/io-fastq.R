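#' Read-quality filter configuration
#'
#' Holds the thresholds of the transcriptome read filter: a read is discarded
#' when more than `max_low_quality_fraction` of its bases fall below Phred
#' `low_quality_threshold` (default: more than 10% below Q20) or more than
#' `max_n_fraction` of its bases are `N` (default 5%). "More than" is a strict
#' inequality, so boundary reads are kept.
#'
#' @param max_low_quality_fraction Maximum tolerated fraction of low-quality
#'   bases (default 0.10).
#' @param low_quality_threshold Phred score below which a base counts as
#'   low-quality (default 20).
#' @param max_n_fraction Maximum tolerated fraction of `N` bases (default 0.05).
#' @return A list of class `read_filter_config`.
#' @export
read_filter_config <- function(max_low_quality_fraction = 0.10,
                               low_quality_threshold = 20,
                               max_n_fraction = 0.05) {
  check_fraction(max_low_quality_fraction, "max_low_quality_fraction")
  check_fraction(max_n_fraction, "max_n_fraction")
  if (!is.numeric(low_quality_threshold) || low_quality_threshold < 0) {
    stop("`low_quality_threshold` must be a Phred score >= 0", call. = FALSE)
  }
  structure(
    list(max_low_quality_fraction = max_low_quality_fraction,
         low_quality_threshold = low_quality_threshold,
         max_n_fraction = max_n_fraction),
    class = "read_filter_config"
  )
}

#' Filter reads on low-quality and N-base fractions
#'
#' Discards a read iff its fraction of bases with Phred score strictly below
#' `cfg$low_quality_threshold` exceeds `cfg$max_low_quality_fraction`, or its
#' fraction of `N` bases exceeds `cfg$max_n_fraction` (both comparisons
#' strict). Kept reads preserve input order; the operation is idempotent.
#'
#' @param reads A [read_set].
#' @param cfg A [read_filter_config].
#' @return A list with `kept` (a [read_set]) and `n_discarded`.
#' @export
filter_reads <- function(reads, cfg = read_filter_config()) {
  stopifnot(inherits(reads, "read_set"), inherits(cfg, "read_filter_config"))
  if (nrow(reads) == 0L) return(list(kept = reads, n_discarded = 0L))
  len <- nchar(reads$bases)
  low_frac <- mapply(function(q, n) sum(q < cfg$low_quality_threshold) / n,
                     reads$quals, len)
  n_frac <- vapply(seq_len(nrow(reads)), function(i) {
    lengths(regmatches(reads$bases[i], gregexpr("N", reads$bases[i], fixed = TRUE))) / len[i]
  }, numeric(1))
  drop <- low_frac > cfg$max_low_quality_fraction | n_frac > cfg$max_n_fraction
  kept <- reads[!drop, , drop = FALSE]
  class(kept) <- c("read_set", "data.frame")
  list(kept = kept, n_discarded = sum(drop))
}

#' Read FASTQ (Phred+33)
#'
#' The quality encoding is fixed to Phred+33; there is no autodetection.
#'
#' @param path Path to a FASTQ file.
#' @return A [read_set].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  if (length(seqs) == 0L) return(read_set(character(), character(), list()))
  quals <- lapply(as.character(S4Vectors::mcols(seqs)$qualities),
                  function(q) utf8ToInt(q) - 33L)
  read_set(id = names(seqs), bases = as.character(seqs), quals = quals)
}

#' Write FASTQ (Phred+33)
#'
#' @param x A [read_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "read_set"))
  qstr <- vapply(x$quals, function(q) intToUtf8(q + 33L), character(1))
  writeLines(as.vector(rbind(paste0("@", x$id), x$bases, "+", qstr)), path)
  invisible(path)
}
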