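#' Read protein FASTA with pipe-delimited metadata headers
#'
#' Headers carry record metadata in a fixed dialect:
#' `>id|organism|taxon_group` with an optional fourth `|enzyme_label` field.
#' Sequences are upper-cased; a terminal `*` is stripped and flagged in the
#' `had_stop` column. Unknown taxon groups map to `"other"` with a warning;
#' a malformed header or an empty sequence is an error naming the offending
#' line or record.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_set].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(seqs)
  header_lines <- grep("^>", readLines(path, warn = FALSE))

  if (length(seqs) == 0L) {
    return(protein_set(character(), character(), character(), character()))
  }

  fields <- strsplit(headers, "|", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad)) {
    stop(sprintf(
      "malformed FASTA header at line %d: \"%s\" (expected id|organism|taxon_group[|enzyme_label])",
      header_lines[bad[1L]], headers[bad[1L]]), call. = FALSE)
  }
  get_field <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, character(1))

  residues <- as.character(seqs)
  empty <- !nzchar(sub("\\*$", "", toupper(residues)))
  if (any(empty)) {
    stop(sprintf("empty sequence for FASTA record \"%s\" (header line %d)",
                 get_field(1)[empty][1L], header_lines[empty][1L]), call. = FALSE)
  }

  protein_set(
    id = get_field(1), organism = get_field(2), taxon_group = get_field(3),
    residues = residues, enzyme_label = get_field(4)
  )
}

#' Write a protein set as FASTA
#'
#' Emits the same pipe-delimited header dialect [read_fasta] consumes, one
#' sequence per line (no wrapping), so output is byte-stable for equal inputs.
#' Records flagged `had_stop` regain their terminal `*`.
#'
#' @param x A [protein_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "protein_set"))
  hdr <- paste0(">", x$id, "|", x$organism, "|", x$taxon_group,
                ifelse(is.na(x$enzyme_label), "", paste0("|", x$enzyme_label)))
  seq <- paste0(x$residues, ifelse(x$had_stop, "*", ""))
  writeLines(as.vector(rbind(hdr, seq)), path)
  invisible(path)
}
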