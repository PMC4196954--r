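#' Protein record collections
#'
#' A `protein_set` is the package's unit of sequence data: a data frame with
#' one row per protein and columns `id`, `organism`, `taxon_group`,
#' `enzyme_label`, `residues` and `had_stop`. Residues are upper-case strings
#' over the 20 standard amino-acid letters plus `X`; a terminal `*` (stop) is
#' stripped from `residues` and recorded in the logical `had_stop` column so
#' that motif and alignment computations never see it.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param organism Character vector of organism names (recycled if length 1).
#' @param taxon_group Character vector drawn from the closed vocabulary
#'   (`archaea`, `proteobacteria`, `cyanobacteria`, `rhodophyta`,
#'   `chlorophyta_plants`, `ochrophyta`, `cryptophyta`, `glaucophyta`,
#'   `other`); unknown values are mapped to `"other"` with a warning.
#' @param residues Character vector of amino-acid sequences (may carry a
#'   terminal `*`).
#' @param enzyme_label Optional character vector of enzyme labels (e.g.
#'   `"PEPC"`, `"MDH-NADP"`); `NA` where unknown.
#'
#' @return A data frame of class `protein_set`.
#' @export
protein_set <- function(id, organism, taxon_group, residues, enzyme_label = NA_character_) {
  n <- length(id)
  organism <- rep_len(as.character(organism), n)
  taxon_group <- rep_len(as.character(taxon_group), n)
  enzyme_label <- rep_len(as.character(enzyme_label), n)
  residues <- as.character(residues)
  if (length(residues) != n) stop("`residues` must match `id` in length", call. = FALSE)
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(id[duplicated(id)]), collapse = ", ")), call. = FALSE)
  }

  unknown <- !(taxon_group %in% TAXON_GROUPS)
  if (any(unknown)) {
    warning(sprintf("unknown taxon_group(s) mapped to \"other\": %s",
                    paste(unique(taxon_group[unknown]), collapse = ", ")),
            call. = FALSE)
    taxon_group[unknown] <- "other"
  }

  residues <- toupper(residues)
  had_stop <- endsWith(residues, "*")
  residues <- sub("\\*$", "", residues)

  empty <- !nzchar(residues)
  if (any(empty)) {
    stop(sprintf("empty sequence for record(s): %s",
                 paste(id[empty], collapse = ", ")), call. = FALSE)
  }
  bad <- vapply(strsplit(residues, ""), function(ch) {
    w <- which(!(ch %in% AA_ALPHABET))
    if (length(w)) w[1L] else 0L
  }, integer(1))
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal residue character in record \"%s\" at position %d",
                 id[i], bad[i]), call. = FALSE)
  }

  out <- data.frame(
    id = as.character(id), organism = organism, taxon_group = taxon_group,
    enzyme_label = enzyme_label, residues = residues, had_stop = had_stop,
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_set", "data.frame")
  out
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("<protein_set> %d sequence(s), %d organism(s)\n",
              nrow(x), length(unique(x$organism))))
  if (nrow(x)) {
    show <- utils::head(x, 6L)
    show$residues <- ifelse(nchar(show$residues) > 24,
                            paste0(substr(show$residues, 1, 21), "..."),
                            show$residues)
    print.data.frame(show, row.names = FALSE)
    if (nrow(x) > 6L) cat(sprintf("... and %d more\n", nrow(x) - 6L))
  }
  invisible(x)
}

rbind_protein_sets <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  if (anyDuplicated(out$id)) stop("duplicate ids when combining protein sets", call. = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Short-read collections
#'
#' A `read_set` holds short sequencing reads: a data frame with columns `id`,
#' `bases` (strings over `A`,`C`,`G`,`T`,`N`) and `quals`, a list column of
#' integer per-base Phred scores. Every read's quality vector must match its
#' base string in length.
#'
#' @param id Character vector of read identifiers.
#' @param bases Character vector of base strings.
#' @param quals List of integer vectors of per-base Phred scores.
#'
#' @return A data frame of class `read_set`.
#' @export
read_set <- function(id, bases, quals) {
  bases <- toupper(as.character(bases))
  if (!is.list(quals)) quals <- as.list(quals)
  if (length(id) != length(bases) || length(bases) != length(quals)) {
    stop("id, bases and quals must have equal length", call. = FALSE)
  }
  nb <- nchar(bases)
  nq <- lengths(quals)
  if (any(nb == 0L)) {
    stop(sprintf("zero-length read(s): %s", paste(id[nb == 0L], collapse = ", ")),
         call. = FALSE)
  }
  mism <- nb != nq
  if (any(mism)) {
    stop(sprintf("bases/quality length mismatch for read \"%s\" (%d vs %d)",
                 id[which(mism)[1L]], nb[which(mism)[1L]], nq[which(mism)[1L]]),
         call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", bases))) {
    stop("bases may only contain A, C, G, T, N", call. = FALSE)
  }
  neg <- vapply(quals, function(q) any(q < 0L), logical(1))
  if (any(neg)) stop("Phred scores must be >= 0", call. = FALSE)
  out <- data.frame(id = as.character(id), bases = bases, stringsAsFactors = FALSE)
  out$quals <- lapply(quals, as.integer)
  class(out) <- c("read_set", "data.frame")
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d read(s)", nrow(x)))
  if (nrow(x)) cat(sprintf(", lengths %d-%d", min(nchar(x$bases)), max(nchar(x$bases))))
  cat("\n")
  invisible(x)
}
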