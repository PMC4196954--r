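#' Reference panels for enzyme-family assignment
#'
#' A reference panel is a labeled [protein_set] standing in for a full
#' protein database: queries are assigned to the enzyme family (or
#' cofactor/compartment variant) of their best-matching reference by global
#' alignment identity.
#'
#' @param records A [protein_set] in which every record has `enzyme_label`
#'   set.
#' @return The records, classed `reference_panel`.
#' @export
reference_panel <- function(records) {
  stopifnot(inherits(records, "protein_set"))
  if (nrow(records) == 0L) stop("reference panel must be non-empty", call. = FALSE)
  if (anyNA(records$enzyme_label)) {
    stop("every panel record needs an enzyme_label", call. = FALSE)
  }
  class(records) <- c("reference_panel", class(records))
  records
}

# Fixed seeds behind the bundled synthetic panel; exported through
# default_panel_seed() so simulated query families can share an ancestor
# with their panel reference.
panel_seeds <- function() {
  stats::setNames(9001L + seq_along(ENZYME_VARIANTS), ENZYME_VARIANTS)
}

#' Seed of a bundled panel reference
#'
#' @param label An enzyme-variant label (e.g. `"PK"`, `"MDH-NADP"`).
#' @return The integer seed whose [motif_plant_spec] ancestor is the bundled
#'   panel sequence for that label.
#' @export
default_panel_seed <- function(label) {
  seeds <- panel_seeds()
  if (!label %in% names(seeds)) stop(sprintf("unknown label \"%s\"", label), call. = FALSE)
  unname(seeds[label])
}

#' Bundled synthetic reference panel
#'
#' One deterministic synthetic ancestor per enzyme variant (PEPC, PPDK, PEPS,
#' ALT, PK, PCK, AST-cyt, AST-mit, MDH-NAD, MDH-NADP, ME-NAD, ME-NADP), all
#' of the same length. The panel is synthetic — variants are independent
#' random ancestors, not real homologs — and exists so the assignment,
#' inventory and completeness machinery can run with known ground truth;
#' supply curated sequences via [reference_panel()] for real analyses.
#'
#' @param length Reference length in residues (default 300).
#' @return A `reference_panel`.
#' @export
default_reference_panel <- function(length = 300L) {
  sets <- lapply(ENZYME_VARIANTS, function(lab) {
    fam <- sub("-.*$", "", lab)
    gen_protein_family(
      motif_plant_spec(fam, length = length, seed = default_panel_seed(lab)),
      n = 1L, organism = "synthetic reference", taxon_group = "other",
      enzyme_label = lab, id_prefix = paste0("ref_", lab)
    )
  })
  reference_panel(do.call(rbind_protein_sets, sets))
}

#' Assign a query sequence to an enzyme family
#'
#' The query is globally aligned against every panel record; the best label
#' is the one with maximum identity (ties broken by higher raw score, then by
#' lexicographic reference id). Queries whose best identity falls below
#' `min_identity` are `unassigned`.
#'
#' @param query A single-row [protein_set] or residue string.
#' @param panel A [reference_panel].
#' @param s A [scoring_scheme].
#' @param min_identity Assignment threshold on identity (default 0.35).
#' @return A list with `label` (or `"unassigned"`), `best_identity`,
#'   `best_ref_id`.
#' @export
assign_family <- function(query, panel = default_reference_panel(),
                          s = default_scoring_scheme(), min_identity = 0.35) {
  stopifnot(inherits(panel, "reference_panel"))
  qseq <- if (is.character(query)) toupper(query) else query$residues
  if (!length(qseq) || !nzchar(qseq)) stop("empty query sequence", call. = FALSE)
  ids <- numeric(nrow(panel))
  scores <- numeric(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    aln <- global_align(qseq, panel$residues[i], s)
    ids[i] <- aln$identity
    scores[i] <- aln$score
  }
  ord <- order(-ids, -scores, panel$id)
  best <- ord[1L]
  list(
    label = if (ids[best] < min_identity) "unassigned" else panel$enzyme_label[best],
    best_identity = ids[best],
    best_ref_id = panel$id[best]
  )
}

#' Assign every sequence of a protein set
#'
#' @param queries A [protein_set].
#' @inheritParams assign_family
#' @return A data frame with one row per query: `id`, `organism`, `label`,
#'   `best_identity`, `best_ref_id`.
#' @export
assign_families <- function(queries, panel = default_reference_panel(),
                            s = default_scoring_scheme(), min_identity = 0.35) {
  stopifnot(inherits(queries, "protein_set"))
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    a <- assign_family(queries$residues[i], panel, s, min_identity)
    data.frame(id = queries$id[i], organism = queries$organism[i],
               label = a$label, best_identity = a$best_identity,
               best_ref_id = a$best_ref_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build an organism-by-enzyme inventory from assignments
#'
#' Counts (organism, label) pairs; `unassigned` rows are excluded, duplicate
#' pairs accumulate. All enzyme-variant columns of the controlled vocabulary
#' are present (zero where unobserved) and organisms are ordered by
#' (taxonomy, name).
#'
#' @param assignments Data frame with columns `organism` and `label` (e.g.
#'   from [assign_families()]).
#' @param taxonomy Optional named character vector organism -> taxonomy.
#' @return An `inventory_matrix`.
#' @export
build_inventory <- function(assignments, taxonomy = NULL) {
  stopifnot(is.data.frame(assignments), all(c("organism", "label") %in% names(assignments)))
  a <- assignments[assignments$label != "unassigned", , drop = FALSE]
  bad <- setdiff(unique(a$label), ENZYME_VARIANTS)
  if (length(bad)) {
    stop(sprintf("label(s) outside the controlled vocabulary: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  orgs <- sort(unique(a$organism))
  if (!is.null(taxonomy)) {
    taxv <- unname(taxonomy[orgs]); taxv[is.na(taxv)] <- ""
    orgs <- orgs[order(taxv, orgs)]
  }
  m <- matrix(0L, nrow = length(orgs), ncol = length(ENZYME_VARIANTS),
              dimnames = list(orgs, ENZYME_VARIANTS))
  if (nrow(a)) {
    tab <- table(a$organism, a$label)
    m[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  inventory_matrix(m, taxonomy = taxonomy)
}

#' C4-subtype definitions
#'
#' A subtype is defined by its required enzyme-variant set; PEPC and PPDK,
#' the two enzymes shared by every C4 variant, must belong to every
#' definition.
#'
#' @param name Subtype name (`NADP_ME`, `NAD_ME` or `PCK`).
#' @param required Character vector of required enzyme-variant labels.
#' @return A list of class `subtype_definition`.
#' @export
subtype_definition <- function(name, required) {
  name <- match.arg(name, c("NADP_ME", "NAD_ME", "PCK"))
  bad <- setdiff(required, ENZYME_VARIANTS)
  if (length(bad)) {
    stop(sprintf("unknown enzyme label(s) in subtype \"%s\": %s",
                 name, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!all(c("PEPC", "PPDK") %in% required)) {
    stop("every C4 subtype requires the two shared enzymes PEPC and PPDK", call. = FALSE)
  }
  structure(list(name = name, required = required), class = "subtype_definition")
}

#' Default C4-subtype definitions
#'
#' Standard C4 biochemistry with the two shared enzymes plus
#' subtype-specific ones: NADP-ME needs the NADP-dependent malate
#' dehydrogenase and malic enzyme; NAD-ME the NAD-dependent pair plus both
#' aminotransferase compartments and ALT; PCK the carboxykinase with
#' cytosolic AST. Fully overridable — supply your own list of
#' [subtype_definition] where a different scheme is wanted.
#'
#' @return A named list of [subtype_definition].
#' @export
default_subtype_definitions <- function() {
  list(
    NADP_ME = subtype_definition("NADP_ME", c("PEPC", "PPDK", "MDH-NADP", "ME-NADP")),
    NAD_ME = subtype_definition("NAD_ME", c("PEPC", "PPDK", "AST-cyt", "AST-mit",
                                            "MDH-NAD", "ME-NAD", "ALT")),
    PCK = subtype_definition("PCK", c("PEPC", "PPDK", "PCK", "AST-cyt"))
  )
}

#' Assess C4-subtype gene-complement completeness
#'
#' For every organism and subtype, the missing set is the required labels
#' with count zero in the inventory; an organism is `complete` for a subtype
#' iff nothing is missing. An inventory that does not resolve cofactor
#' variants (plain `MDH`/`ME` columns only) can therefore never be complete
#' for NADP-ME or NAD-ME.
#'
#' @param inv An `inventory_matrix`.
#' @param defs A list of [subtype_definition] (default
#'   [default_subtype_definitions()]).
#' @return A data frame of class `completeness_report` with columns
#'   `organism`, `subtype`, `status`, `missing` (comma-separated labels).
#' @export
assess_subtypes <- function(inv, defs = default_subtype_definitions()) {
  stopifnot(inherits(inv, "inventory_matrix"))
  stopifnot(all(vapply(defs, inherits, logical(1), "subtype_definition")))
  orgs <- rownames(inv)
  rows <- list()
  for (org in orgs) {
    for (d in defs) {
      counts <- vapply(d$required, function(lab) {
        if (lab %in% colnames(inv)) inv[org, lab] else 0L
      }, integer(1))
      missing <- d$required[counts == 0L]
      rows[[length(rows) + 1L]] <- data.frame(
        organism = org, subtype = d$name,
        status = if (length(missing)) "incomplete" else "complete",
        missing = paste(missing, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(organism = character(), subtype = character(),
                         status = character(), missing = character(),
                         stringsAsFactors = FALSE)
  class(out) <- c("completeness_report", "data.frame")
  out
}
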