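#' Specification for a simulated protein family with planted motifs
#'
#' Describes a family of related sequences grown from one random (or given)
#' ancestor, with classification features planted at fixed positions: an
#' exact C-terminal tetrapeptide, a diagnostic residue at a given position,
#' and/or an N-terminal signature motif. Planted positions are never touched
#' by mutation, so the planted ground truth survives generation verbatim.
#'
#' @param family Enzyme family, one of `PEPC`, `PPDK`, `PEPS`, `ALT`, `AST`,
#'   `MDH`, `ME`, `PK`, `PCK`.
#' @param length Sequence length in residues (default 300).
#' @param planted_terminal Optional 4-mer written over the last four residues.
#' @param diagnostic_residue,diagnostic_position Optional single letter
#'   planted at `diagnostic_position`.
#' @param signature,signature_position Optional exact motif string written at
#'   `signature_position` (1-based).
#' @param mutation_rate Per-site substitution probability in `[0, 1)` applied
#'   independently to every non-planted site of every sequence.
#' @param base Optional ancestor residue string (length must equal `length`);
#'   drawn uniformly over the 20 standard residues when `NULL`.
#' @param seed Integer seed; the whole family is a pure function of the spec.
#' @return A list of class `motif_plant_spec`.
#' @export
motif_plant_spec <- function(family, length = 300L, planted_terminal = NULL,
                             diagnostic_residue = NULL, diagnostic_position = NULL,
                             signature = NULL, signature_position = NULL,
                             mutation_rate = 0, base = NULL, seed = 1L) {
  family <- match.arg(family, ENZYME_FAMILIES)
  length <- as.integer(length)
  if (length < 4L) stop("`length` must be >= 4", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate >= 1) {
    stop("`mutation_rate` must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(base) && nchar(base) != length) {
    stop("`base` must have exactly `length` residues", call. = FALSE)
  }
  planted <- integer()
  if (!is.null(planted_terminal)) {
    if (nchar(planted_terminal) != 4L) stop("`planted_terminal` must be a 4-mer", call. = FALSE)
    planted <- c(planted, (length - 3L):length)
  }
  if (!is.null(diagnostic_residue)) {
    if (is.null(diagnostic_position)) stop("`diagnostic_position` required with `diagnostic_residue`", call. = FALSE)
    if (diagnostic_position < 1L || diagnostic_position > length) {
      stop("`diagnostic_position` out of range", call. = FALSE)
    }
    dpos <- as.integer(diagnostic_position)
    if (dpos %in% planted) stop("planted features overlap", call. = FALSE)
    planted <- c(planted, dpos)
  }
  if (!is.null(signature)) {
    if (is.null(signature_position)) stop("`signature_position` required with `signature`", call. = FALSE)
    spos <- as.integer(signature_position)
    send <- spos + nchar(signature) - 1L
    if (spos < 1L || send > length) stop("signature does not fit in sequence", call. = FALSE)
    if (any(spos:send %in% planted)) stop("planted features overlap", call. = FALSE)
    planted <- c(planted, spos:send)
  }
  structure(
    list(family = family, length = length, planted_terminal = planted_terminal,
         diagnostic_residue = diagnostic_residue,
         diagnostic_position = if (is.null(diagnostic_position)) NULL else as.integer(diagnostic_position),
         signature = signature,
         signature_position = if (is.null(signature_position)) NULL else as.integer(signature_position),
         mutation_rate = mutation_rate, base = base, seed = as.integer(seed),
         planted_sites = sort(planted)),
    class = "motif_plant_spec"
  )
}

# Substitute each selected site with a uniformly chosen *different* residue.
mutate_residues <- function(ch, rate, protected = integer()) {
  if (rate <= 0) return(ch)
  hit <- which(stats::runif(length(ch)) < rate)
  hit <- setdiff(hit, protected)
  for (i in hit) {
    ch[i] <- sample(setdiff(BACKGROUND_AA, ch[i]), 1L)
  }
  ch
}

#' Generate a protein family with planted classification features
#'
#' Grows `n` sequences from the spec's ancestor: non-planted sites are
#' mutated i.i.d. at `spec$mutation_rate`, then the planted terminal
#' tetrapeptide, diagnostic residue and signature are written in verbatim.
#' The ancestor and all mutations derive from `spec$seed`, so the same spec
#' always yields byte-identical output.
#'
#' @param spec A [motif_plant_spec].
#' @param n Number of sequences (>= 1).
#' @param organism,taxon_group,enzyme_label Metadata stamped on the records;
#'   `enzyme_label` defaults to the spec's family.
#' @param id_prefix Prefix for the generated ids (default the family name).
#' @return A [protein_set] of `n` records.
#' @export
gen_protein_family <- function(spec, n, organism = paste0("synthetic_", spec$family),
                               taxon_group = "other", enzyme_label = spec$family,
                               id_prefix = spec$family) {
  stopifnot(inherits(spec, "motif_plant_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  with_seed(spec$seed, {
    anc <- if (is.null(spec$base)) {
      sample(BACKGROUND_AA, spec$length, replace = TRUE)
    } else {
      strsplit(toupper(spec$base), "")[[1]]
    }
    seqs <- character(n)
    for (k in seq_len(n)) {
      ch <- mutate_residues(anc, spec$mutation_rate, spec$planted_sites)
      if (!is.null(spec$planted_terminal)) {
        ch[(spec$length - 3L):spec$length] <- strsplit(spec$planted_terminal, "")[[1]]
      }
      if (!is.null(spec$diagnostic_residue)) {
        ch[spec$diagnostic_position] <- spec$diagnostic_residue
      }
      if (!is.null(spec$signature)) {
        sl <- nchar(spec$signature)
        ch[spec$signature_position:(spec$signature_position + sl - 1L)] <-
          strsplit(spec$signature, "")[[1]]
      }
      seqs[k] <- paste(ch, collapse = "")
    }
    protein_set(
      id = sprintf("%s_%03d", id_prefix, seq_len(n)),
      organism = organism, taxon_group = taxon_group,
      residues = seqs, enzyme_label = enzyme_label
    )
  })
}

#' Generate reads with controlled quality and N composition
#'
#' Every read carries exactly `round(length * low_q_fraction)` bases with
#' Phred score below 20 (Q15 versus Q35 elsewhere) and exactly
#' `round(length * n_fraction)` `N` bases, at seed-randomized positions.
#'
#' @param n Number of reads.
#' @param length Read length in bases (> 0).
#' @param low_q_fraction,n_fraction Target fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [read_set].
#' @export
gen_reads <- function(n, length, low_q_fraction, n_fraction, seed = 1L) {
  n <- as.integer(n); length <- as.integer(length)
  if (length < 1L) stop("`length` must be > 0", call. = FALSE)
  check_fraction(low_q_fraction, "low_q_fraction")
  check_fraction(n_fraction, "n_fraction")
  k_low <- round(length * low_q_fraction)
  k_n <- round(length * n_fraction)
  with_seed(seed, {
    bases <- character(n)
    quals <- vector("list", n)
    for (i in seq_len(n)) {
      b <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
      q <- rep(35L, length)
      if (k_low > 0) q[sample.int(length, k_low)] <- 15L
      if (k_n > 0) b[sample.int(length, k_n)] <- "N"
      bases[i] <- paste(b, collapse = "")
      quals[[i]] <- q
    }
    read_set(sprintf("read_%04d", seq_len(n)), bases, quals)
  })
}

#' Specification for synthetic tree samples around a base topology
#'
#' A synthetic twin of a posterior tree sample: each emitted tree equals the
#' base topology, except that with probability `perturbation_prob` it
#' receives one random nearest-neighbour-interchange (NNI) rearrangement.
#'
#' @param base_topology Newick string or `phylo` with >= 4 leaves.
#' @param n_samples Number of trees to emit (>= 0).
#' @param perturbation_prob Per-tree probability of one random NNI.
#' @param seed Integer seed.
#' @return A list of class `tree_sim_spec`.
#' @export
tree_sim_spec <- function(base_topology, n_samples, perturbation_prob = 0.05, seed = 1L) {
  if (is.character(base_topology)) {
    base_topology <- tryCatch(ape::read.tree(text = base_topology),
                              error = function(e) NULL)
    if (is.null(base_topology)) stop("malformed base_topology Newick", call. = FALSE)
  }
  stopifnot(inherits(base_topology, "phylo"))
  if (length(base_topology$tip.label) < 4L) stop("base_topology needs >= 4 leaves", call. = FALSE)
  check_fraction(perturbation_prob, "perturbation_prob")
  structure(
    list(base_topology = ape::unroot(base_topology),
         n_samples = as.integer(n_samples),
         perturbation_prob = perturbation_prob, seed = as.integer(seed)),
    class = "tree_sim_spec"
  )
}

#' Generate tree samples by NNI perturbation of a base topology
#'
#' @param spec A [tree_sim_spec].
#' @return A [tree_sample_set] of `spec$n_samples` trees sharing the base
#'   topology's leaf set.
#' @export
gen_tree_samples <- function(spec) {
  stopifnot(inherits(spec, "tree_sim_spec"))
  if (spec$n_samples == 0L) return(tree_sample_set(list()))
  with_seed(spec$seed, {
    perturb <- stats::runif(spec$n_samples) < spec$perturbation_prob
    trees <- vector("list", spec$n_samples)
    for (i in seq_len(spec$n_samples)) {
      trees[[i]] <- if (perturb[i]) phangorn::rNNI(spec$base_topology, 1L) else spec$base_topology
    }
    tree_sample_set(trees)
  })
}

#' Simulate a mixed prokaryote/eukaryote family with a known donor lineage
#'
#' Builds a scenario for origin-assignment recovery tests: one root sequence
#' diverges into the three prokaryote groups (archaea, proteobacteria,
#' cyanobacteria), and the eukaryotic sequences descend from the ancestral
#' sequence of the `donor` group. Per-branch divergence `d` (substitutions
#' per site) is applied as an independent per-site substitution probability
#' `1 - exp(-d)` (each hit replaces the residue with a different one), so
#' `divergence = 0` leaves the eukaryotic sequences identical to the donor
#' ancestor. The true donor is recorded in the `donor` attribute.
#'
#' @param n_euk Number of eukaryotic sequences (default 4).
#' @param donor Donor lineage: `archaea`, `proteobacteria` or `cyanobacteria`.
#' @param n_per_prok_group Sequences per prokaryote group (default 3).
#' @param divergence Donor-to-eukaryote branch length in substitutions/site.
#' @param seed Integer seed.
#' @param length Sequence length (default 300).
#' @param euk_group Taxon group stamped on the eukaryotic records
#'   (default `rhodophyta`).
#' @param group_divergence Root-to-group branch length (default 0.6).
#' @param within_divergence Group-ancestor-to-member branch length
#'   (default 0.05).
#' @return A [protein_set] with attribute `donor` (the true donor group).
#' @export
gen_origin_scenario <- function(n_euk = 4L, donor = "proteobacteria",
                                n_per_prok_group = 3L, divergence = 0.2,
                                seed = 1L, length = 300L,
                                euk_group = "rhodophyta",
                                group_divergence = 0.6, within_divergence = 0.05) {
  donor <- match.arg(donor, PROKARYOTE_GROUPS)
  if (divergence < 0) stop("`divergence` must be >= 0", call. = FALSE)
  if (exp(-divergence) < 0.10) {
    warning("divergence so high that expected identity to the donor ancestor is < 10%; the origin signal is saturated",
            call. = FALSE)
  }
  p_site <- function(d) 1 - exp(-d)
  with_seed(seed, {
    root <- sample(BACKGROUND_AA, length, replace = TRUE)
    ids <- organisms <- groups <- seqs <- character()
    donor_anc <- NULL
    for (g in PROKARYOTE_GROUPS) {
      anc <- mutate_residues(root, p_site(group_divergence))
      if (g == donor) donor_anc <- anc
      for (k in seq_len(n_per_prok_group)) {
        member <- mutate_residues(anc, p_site(within_divergence))
        ids <- c(ids, sprintf("%s_%02d", g, k))
        organisms <- c(organisms, sprintf("synthetic %s %d", g, k))
        groups <- c(groups, g)
        seqs <- c(seqs, paste(member, collapse = ""))
      }
    }
    for (k in seq_len(n_euk)) {
      member <- mutate_residues(donor_anc, p_site(divergence))
      ids <- c(ids, sprintf("euk_%02d", k))
      organisms <- c(organisms, sprintf("synthetic eukaryote %d", k))
      groups <- c(groups, euk_group)
      seqs <- c(seqs, paste(member, collapse = ""))
    }
    out <- protein_set(ids, organisms, groups, seqs)
    attr(out, "donor") <- donor
    out
  })
}
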