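#' Scoring schemes for global alignment
#'
#' Either a full substitution matrix over the amino-acid alphabet or a simple
#' match/mismatch pair, plus affine gap penalties. A gap of length `L` costs
#' `gap_open + L * gap_extend` (subtracted), so `gap_open = 0` gives linear
#' gap costs. `X` scores 0 against everything.
#'
#' @param matrix Optional symmetric substitution matrix with residue letters
#'   as dimnames (e.g. `BLOSUM62`); rows/columns beyond the package alphabet
#'   are ignored.
#' @param match,mismatch Scores used to build a matrix when `matrix` is `NULL`
#'   (defaults +1/-1).
#' @param gap_open Gap opening penalty (>= 0, subtracted; default 0).
#' @param gap_extend Per-residue gap extension penalty (>= 0; default 2).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, match = 1, mismatch = -1,
                           gap_open = 0, gap_extend = 2) {
  if (gap_open < 0 || gap_extend < 0) {
    stop("gap penalties must be >= 0 (they are applied as subtractions)", call. = FALSE)
  }
  if (is.null(matrix)) {
    sub <- base::matrix(mismatch, 21L, 21L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    diag(sub) <- match
  } else {
    common <- intersect(AA_ALPHABET, rownames(matrix))
    sub <- base::matrix(0, 21L, 21L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    sub[common, common] <- matrix[common, common]
    if (!isTRUE(all.equal(sub, t(sub)))) stop("substitution matrix must be symmetric", call. = FALSE)
  }
  sub["X", ] <- 0
  sub[, "X"] <- 0
  structure(list(sub = sub, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Default protein scoring scheme: BLOSUM62, gap open 11, extend 1
#'
#' The community-standard protein scheme; `X` is overridden to score 0
#' against every residue.
#'
#' @return A `scoring_scheme`.
#' @export
default_scoring_scheme <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  scoring_scheme(matrix = e$BLOSUM62, gap_open = 11, gap_extend = 1)
}

residues_to_idx <- function(x, what = "sequence") {
  ch <- strsplit(x, "")[[1]]
  idx <- match(ch, AA_ALPHABET)
  if (anyNA(idx)) {
    stop(sprintf("illegal residue character '%s' at position %d of %s",
                 ch[which(is.na(idx))[1]], which(is.na(idx))[1], what), call. = FALSE)
  }
  idx
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gap costs (Gotoh). The score is the maximum
#' achievable under the scheme; traceback tie-breaking is fixed (diagonal,
#' then gap in `b`, then gap in `a`) so results are byte-stable. Identity is
#' the fraction of matching residues over columns where both sequences have a
#' residue, which excludes terminal (and all other) gap columns from the
#' denominator.
#'
#' @param a,b Residue strings (non-empty; no gaps).
#' @param s A [scoring_scheme] (default [default_scoring_scheme()]).
#' @return A list of class `alignment_result` with `aligned_a`, `aligned_b`,
#'   `score`, `identity` and `position_map` (integer vector of length
#'   `nchar(a)` mapping each position of `a` to its aligned position in `b`,
#'   `NA` where `b` has a gap).
#' @export
global_align <- function(a, b, s = default_scoring_scheme()) {
  stopifnot(inherits(s, "scoring_scheme"))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  ai <- residues_to_idx(a, "`a`")
  bi <- residues_to_idx(b, "`b`")
  res <- nw_align_cpp(ai, bi, s$sub, s$gap_open, s$gap_extend)
  ops <- res$ops  # 1 = diagonal, 2 = gap in b, 3 = gap in a

  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  ia <- ib <- 0L
  la <- lb <- character(length(ops))
  pos_map <- rep(NA_integer_, length(ach))
  for (k in seq_along(ops)) {
    if (ops[k] == 1L) {
      ia <- ia + 1L; ib <- ib + 1L
      la[k] <- ach[ia]; lb[k] <- bch[ib]
      pos_map[ia] <- ib
    } else if (ops[k] == 2L) {
      ia <- ia + 1L
      la[k] <- ach[ia]; lb[k] <- "-"
    } else {
      ib <- ib + 1L
      la[k] <- "-"; lb[k] <- bch[ib]
    }
  }
  both <- ops == 1L
  identity <- if (any(both)) mean(la[both] == lb[both]) else 0
  structure(
    list(aligned_a = paste(la, collapse = ""), aligned_b = paste(lb, collapse = ""),
         score = res$score, identity = identity, position_map = pos_map),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %.6g, identity %.3f\n", x$score, x$identity))
  cat(" a: ", x$aligned_a, "\n b: ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Map a reference position onto a query sequence
#'
#' Locates the query column aligned to `ref_pos` of `ref` in the optimal
#' global alignment. When the query has a gap at that column the position is
#' undefined (`NA`) and the residue is reported as `"-"`.
#'
#' @param ref,query Protein records (single rows of a [protein_set]) or plain
#'   residue strings.
#' @param ref_pos 1-based position in the reference.
#' @param s A [scoring_scheme].
#' @return A list with `query_pos` (integer or `NA`) and `query_residue`
#'   (letter or `"-"`).
#' @export
map_reference_position <- function(ref, query, ref_pos, s = default_scoring_scheme()) {
  ref_seq <- if (is.character(ref)) ref else ref$residues
  query_seq <- if (is.character(query)) query else query$residues
  stopifnot(length(ref_seq) == 1L, length(query_seq) == 1L)
  if (ref_pos < 1 || ref_pos > nchar(ref_seq)) {
    stop(sprintf("ref_pos %d out of range 1..%d", ref_pos, nchar(ref_seq)), call. = FALSE)
  }
  aln <- global_align(ref_seq, query_seq, s)
  qp <- aln$position_map[ref_pos]
  list(
    query_pos = qp,
    query_residue = if (is.na(qp)) "-" else substr(query_seq, qp, qp),
    alignment = aln
  )
}

#' Pairwise distance matrix from global-alignment identities
#'
#' Distance is `1 - identity` under the optimal global alignment of each
#' pair; the matrix is symmetric with a zero diagonal.
#'
#' @param records A [protein_set] with >= 2 unique ids.
#' @param s A [scoring_scheme].
#' @return A symmetric numeric matrix with record ids as dimnames.
#' @export
pairwise_distance_matrix <- function(records, s = default_scoring_scheme()) {
  stopifnot(inherits(records, "protein_set"))
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records", call. = FALSE)
  if (anyDuplicated(records$id)) stop("duplicate record ids", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- global_align(records$residues[i], records$residues[j], s)
      d[i, j] <- d[j, i] <- 1 - aln$identity
    }
  }
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(d, path) {
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(formatC(rownames(d)[i], width = -10),
                       sprintf("%.6f", d[i, ])), collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
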