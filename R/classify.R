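#' Type a PEPC by its C-terminal tetrapeptide
#'
#' Bacterial-type PEPC (BTPC) ends in `(R/K)NTG`; plant-type PEPC (PTPC)
#' ends in `QNTG`. Exactly the last four residues are examined (after the
#' terminal stop, if any, has been stripped); anything else is
#' `unclassified` — cryptophyte and archaeal PEPCs, for example, carry
#' neither motif.
#'
#' @param rec A single-row [protein_set] or a residue string.
#' @return A list with `pepc_type` (`BTPC`, `PTPC` or `unclassified`) and
#'   `terminal_tetrapeptide`.
#' @export
classify_pepc_terminus <- function(rec) {
  seq <- if (is.character(rec)) sub("\\*$", "", toupper(rec)) else rec$residues
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n < 4L) stop("sequence shorter than 4 residues; no C-terminal tetrapeptide", call. = FALSE)
  tetra <- substr(seq, n - 3L, n)
  type <- if (tetra %in% c("RNTG", "KNTG")) "BTPC"
          else if (tetra == "QNTG") "PTPC"
          else "unclassified"
  list(pepc_type = type, terminal_tetrapeptide = tetra)
}

#' Diagnostic-site specification for C4-type PEPC calling
#'
#' Defines the reference coordinate system for the C4-diagnostic residue:
#' C4-type PEPCs carry a serine at the position homologous to reference
#' position 774, non-photosynthetic ones an alanine. The bundled default
#' reference is a synthetic construct (see [default_pepc_reference()]); any
#' real reference sequence and numbering can be supplied instead.
#'
#' @param reference A single-row [protein_set] used as the coordinate
#'   reference.
#' @param reference_position 1-based diagnostic position (default 774).
#' @param c4_residues Residues calling `C4_type` (default `"S"`).
#' @param non_c4_residues Residues calling `non_C4` (default `"A"`).
#' @param window Half-width `k` of an optional search window: when the exact
#'   mapped column is a gap, the nearest mapped residue within `k` reference
#'   positions is reported instead. Default 0 (strict, deterministic).
#' @return A list of class `diagnostic_site_spec`.
#' @export
diagnostic_site_spec <- function(reference = default_pepc_reference(),
                                 reference_position = 774L,
                                 c4_residues = "S", non_c4_residues = "A",
                                 window = 0L) {
  stopifnot(inherits(reference, "protein_set"), nrow(reference) == 1L)
  reference_position <- as.integer(reference_position)
  if (reference_position < 1L || reference_position > nchar(reference$residues)) {
    stop("reference_position outside the reference sequence", call. = FALSE)
  }
  if (length(intersect(c4_residues, non_c4_residues))) {
    stop("c4_residues and non_c4_residues must be disjoint", call. = FALSE)
  }
  structure(
    list(reference = reference, reference_position = reference_position,
         c4_residues = c4_residues, non_c4_residues = non_c4_residues,
         window = as.integer(window)),
    class = "diagnostic_site_spec"
  )
}

#' Bundled synthetic PEPC coordinate reference
#'
#' A deterministic synthetic 960-residue PEPC-like sequence carrying a serine
#' at position 774 and a `QNTG` terminus. It is a stand-in coordinate system
#' — not a real PEPC — generated from a fixed internal seed; supply your own
#' reference through [diagnostic_site_spec()] to use a published numbering.
#'
#' @return A single-row [protein_set].
#' @export
default_pepc_reference <- function() {
  with_seed(774001L, {
    ch <- sample(BACKGROUND_AA, 960L, replace = TRUE)
    ch[774L] <- "S"
    ch[957:960] <- c("Q", "N", "T", "G")
    protein_set("PEPC_ref_synthetic", "synthetic construct", "other",
                paste(ch, collapse = ""), enzyme_label = "PEPC")
  })
}

#' Call the C4-diagnostic site of a PEPC
#'
#' Maps the reference diagnostic position onto the query via optimal global
#' alignment and classifies the observed residue: member of `c4_residues`
#' gives `C4_type`, of `non_c4_residues` gives `non_C4`, any other residue
#' gives `other`, and a gap (deletion spanning the site) gives
#' `undetermined`. With `spec$window > 0` the nearest mapped in-window
#' residue substitutes for a gapped exact column.
#'
#' @param rec A single-row [protein_set] or residue string.
#' @param spec A [diagnostic_site_spec].
#' @param s A [scoring_scheme].
#' @return A list with `c4_status`, `diagnostic_residue` (letter or `"-"`)
#'   and `diagnostic_query_pos` (integer or `NA`).
#' @export
call_c4_site <- function(rec, spec = diagnostic_site_spec(), s = default_scoring_scheme()) {
  stopifnot(inherits(spec, "diagnostic_site_spec"))
  query_seq <- if (is.character(rec)) sub("\\*$", "", toupper(rec)) else rec$residues
  m <- map_reference_position(spec$reference, query_seq, spec$reference_position, s)
  qp <- m$query_pos
  residue <- m$query_residue
  if (is.na(qp) && spec$window > 0L) {
    pm <- m$alignment$position_map
    for (off in seq_len(spec$window)) {
      for (p in c(spec$reference_position - off, spec$reference_position + off)) {
        if (p >= 1L && p <= length(pm) && !is.na(pm[p])) {
          qp <- pm[p]
          residue <- substr(query_seq, qp, qp)
          break
        }
      }
      if (!is.na(qp)) break
    }
  }
  status <- if (is.na(qp)) "undetermined"
            else if (residue %in% spec$c4_residues) "C4_type"
            else if (residue %in% spec$non_c4_residues) "non_C4"
            else "other"
  list(c4_status = status, diagnostic_residue = residue, diagnostic_query_pos = qp)
}

#' Full PEPC classification: terminus type plus C4 site
#'
#' The two rules are independent: a BTPC can carry the C4-type site (as
#' Phaeophyceae BTPCs do) and a PTPC the non-C4 one, so every combination of
#' `pepc_type` and `c4_status` can occur.
#'
#' @inheritParams call_c4_site
#' @return A list of class `pepc_call` with `pepc_type`,
#'   `terminal_tetrapeptide`, `c4_status`, `diagnostic_residue`,
#'   `diagnostic_query_pos`.
#' @export
classify_pepc <- function(rec, spec = diagnostic_site_spec(), s = default_scoring_scheme()) {
  term <- classify_pepc_terminus(rec)
  site <- call_c4_site(rec, spec, s)
  structure(c(term, site), class = "pepc_call")
}

#' @export
print.pepc_call <- function(x, ...) {
  cat(sprintf("<pepc_call> %s (%s), %s (%s at %s)\n",
              x$pepc_type, x$terminal_tetrapeptide, x$c4_status,
              x$diagnostic_residue,
              if (is.na(x$diagnostic_query_pos)) "NA" else x$diagnostic_query_pos))
  invisible(x)
}

#' N-terminal signature specification
#'
#' An exact-string or simple-regular-expression motif searched inside a
#' 1-based inclusive N-terminal window.
#'
#' @param name Signature name.
#' @param pattern Non-empty motif pattern (regular expression over residues).
#' @param window_start,window_end Window bounds (inclusive; start <= end).
#' @return A list of class `signature_spec`.
#' @export
signature_spec <- function(name, pattern, window_start = 1L, window_end = 150L) {
  if (!nzchar(pattern)) stop("signature pattern must be non-empty", call. = FALSE)
  if (window_start > window_end) stop("window_start must be <= window_end", call. = FALSE)
  ok <- tryCatch({ grepl(pattern, "AAAA"); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop(sprintf("malformed signature pattern for \"%s\"", name), call. = FALSE)
  structure(list(name = name, pattern = pattern,
                 window_start = as.integer(window_start),
                 window_end = as.integer(window_end)),
            class = "signature_spec")
}

#' Default PPDK / PEPS signatures
#'
#' Exact-string stand-ins for the N-terminal nucleotide-binding-domain
#' signatures that separate genuine PPDK from PEPS and other PEP-utilizing
#' enzymes. These defaults are synthetic motifs matched to the package's
#' sequence generator; for real data, supply signatures transcribed from a
#' curated alignment or a domain database via [signature_spec()].
#'
#' @return A list of [signature_spec] objects.
#' @name default_signatures
NULL

#' @rdname default_signatures
#' @export
default_ppdk_signatures <- function() {
  list(signature_spec("PPDK_nbd_synthetic", "GGKGANLAEM", 1L, 150L))
}

#' @rdname default_signatures
#' @export
default_peps_signatures <- function() {
  list(signature_spec("PEPS_nterm_synthetic", "RGANASHMGE", 1L, 150L))
}

match_signatures <- function(seq, sigs, class) {
  out <- list()
  for (sig in sigs) {
    end <- min(sig$window_end, nchar(seq))
    if (sig$window_start > end) next
    win <- substr(seq, sig$window_start, end)
    m <- gregexpr(sig$pattern, win)[[1]]
    if (m[1] != -1L) {
      out[[length(out) + 1L]] <- data.frame(
        name = sig$name, class = class,
        position = as.integer(m) + sig$window_start - 1L,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(name = character(), class = character(), position = integer(),
                  stringsAsFactors = FALSE)
}

#' Discriminate PPDK from PEPS by N-terminal signatures
#'
#' Searches each signature's N-terminal window. A sequence matching only
#' PPDK-class signatures is called `PPDK`; only PEPS-class signatures,
#' `PEPS_like`; matching neither — or both classes, conservatively — is
#' `ambiguous`. This implements the re-annotation rule under which published
#' "PPDK" sequences lacking the N-terminal nucleotide-binding domain are
#' PEP-utilizing enzymes such as PEP synthetase rather than true PPDK.
#'
#' @param rec A single-row [protein_set] or residue string.
#' @param ppdk_sigs,peps_sigs Lists of [signature_spec] (non-empty).
#' @return A list of class `ppdk_call` with `verdict` and
#'   `matched_signatures` (data frame of name, class, position).
#' @export
classify_ppdk_peps <- function(rec, ppdk_sigs = default_ppdk_signatures(),
                               peps_sigs = default_peps_signatures()) {
  if (!length(ppdk_sigs) || !length(peps_sigs)) {
    stop("signature lists must be non-empty", call. = FALSE)
  }
  seq <- if (is.character(rec)) sub("\\*$", "", toupper(rec)) else rec$residues
  stopifnot(length(seq) == 1L)
  hits <- rbind(match_signatures(seq, ppdk_sigs, "PPDK"),
                match_signatures(seq, peps_sigs, "PEPS"))
  has_ppdk <- any(hits$class == "PPDK")
  has_peps <- any(hits$class == "PEPS")
  verdict <- if (has_ppdk && !has_peps) "PPDK"
             else if (has_peps && !has_ppdk) "PEPS_like"
             else "ambiguous"
  structure(list(verdict = verdict, matched_signatures = hits), class = "ppdk_call")
}

#' @export
print.ppdk_call <- function(x, ...) {
  cat(sprintf("<ppdk_call> %s (%d signature match(es))\n",
              x$verdict, nrow(x$matched_signatures)))
  invisible(x)
}

#' Classification report over a protein set
#'
#' Runs the PEPC terminus, C4-site and PPDK/PEPS classifiers over every
#' sequence and returns one row per sequence, in the layout the TSV report
#' uses.
#'
#' @param proteins A [protein_set].
#' @param spec A [diagnostic_site_spec].
#' @param s A [scoring_scheme].
#' @param ppdk_sigs,peps_sigs Signature lists for [classify_ppdk_peps].
#' @return A data frame with columns `id`, `organism`, `taxon_group`,
#'   `pepc_type`, `tetrapeptide`, `c4_status`, `residue`, `ppdk_verdict`.
#' @export
classification_report <- function(proteins, spec = diagnostic_site_spec(),
                                  s = default_scoring_scheme(),
                                  ppdk_sigs = default_ppdk_signatures(),
                                  peps_sigs = default_peps_signatures()) {
  stopifnot(inherits(proteins, "protein_set"))
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    rec <- proteins[i, , drop = FALSE]
    class(rec) <- c("protein_set", "data.frame")
    pc <- classify_pepc(rec, spec, s)
    pv <- classify_ppdk_peps(rec, ppdk_sigs, peps_sigs)
    data.frame(
      id = rec$id, organism = rec$organism, taxon_group = rec$taxon_group,
      pepc_type = pc$pepc_type, tetrapeptide = pc$terminal_tetrapeptide,
      c4_status = pc$c4_status, residue = pc$diagnostic_residue,
      ppdk_verdict = pv$verdict, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
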