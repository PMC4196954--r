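#' Build a fully-simulated pipeline configuration
#'
#' Returns a run configuration in which every input is produced by the
#' package's seeded generators, so a run is self-contained and byte-stable
#' under a fixed seed. Any element can be replaced by file-based input
#' (`proteins$fasta`, `reads$fastq`, `trees$newick_a`/`newick_b`) before
#' validation.
#'
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param outdir Output directory (created if needed).
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = file.path(tempdir(), "c4kit_run")) {
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    outdir = outdir,
    proteins = list(simulate = list(
      list(family = "PEPC", planted_terminal = "KNTG", diagnostic = "S", n = 4,
           organism = "synthetic phaeophyte", taxon_group = "ochrophyta"),
      list(family = "PEPC", planted_terminal = "QNTG", diagnostic = "A", n = 4,
           organism = "synthetic rhodophyte", taxon_group = "rhodophyta"),
      list(family = "PPDK", signature = "PPDK", n = 3,
           organism = "synthetic phaeophyte", taxon_group = "ochrophyta"),
      list(family = "PEPS", signature = "PEPS", n = 3,
           organism = "synthetic cyanobacterium", taxon_group = "cyanobacteria"),
      list(family = "PK", n = 3, organism = "synthetic phaeophyte",
           taxon_group = "ochrophyta")
    ), mutation_rate = 0.05),
    reads = list(simulate = list(n = 50, length = 100,
                                 low_q_fraction = 0.05, n_fraction = 0.02)),
    read_filter = list(),
    trees = list(simulate = list(n_taxa = 8, n_samples = 500, perturbation_prob = 0.05)),
    schedule = list(generations = 5e6, sample_every = 100, include_initial = TRUE,
                    burnin_fraction = 0.25),
    origin = list(simulate = list(donor = "proteobacteria", n_euk = 4,
                                  n_per_prok_group = 3, divergence = 0.2)),
    min_identity = 0.35
  ), class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  for (slot in c("proteins", "reads", "trees")) {
    files <- cfg[[slot]][setdiff(names(cfg[[slot]]), c("simulate", "mutation_rate"))]
    for (f in unlist(files)) {
      if (!file.exists(f)) {
        stop(sprintf("config validation: %s input file not found: %s", slot, f),
             call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

stage_log <- function(manifest, stage, fmt, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
  message(line)
  c(manifest, line)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates simulate -> read QC -> classification -> family assignment ->
#' inventory/completeness -> tree summarization -> origin call, writing every
#' table under `cfg$outdir` and returning a manifest of paths, seeds, stage
#' counts and a config hash. Outputs are deterministic given the config.
#'
#' @param cfg A `run_config` from [pipeline_config()] (possibly edited).
#' @return A list of class `run_manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log <- character()
  seed <- cfg$seed

  cfg_path <- file.path(cfg$outdir, "config.json")
  jsonlite::write_json(cfg[setdiff(names(cfg), "outdir")], cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  config_hash <- unname(tools::md5sum(cfg_path))
  paths$config <- cfg_path

  ## --- proteins -------------------------------------------------------------
  # Simulated families grow from the bundled panel ancestors so that family
  # assignment downstream sees genuine homology.
  panel <- default_reference_panel()
  if (!is.null(cfg$proteins$fasta)) {
    proteins <- read_fasta(cfg$proteins$fasta)
  } else {
    rate <- cfg$proteins$mutation_rate %||% 0.05
    sets <- list()
    for (k in seq_along(cfg$proteins$simulate)) {
      fs <- cfg$proteins$simulate[[k]]
      base <- panel$residues[match(fs$family, panel$enzyme_label)]
      len <- if (!is.na(base)) nchar(base) else 300L
      spec <- motif_plant_spec(
        fs$family,
        length = len,
        base = if (is.na(base)) NULL else base,
        planted_terminal = fs$planted_terminal,
        diagnostic_residue = fs$diagnostic,
        diagnostic_position = if (is.null(fs$diagnostic)) NULL else len %/% 2L,
        signature = if (identical(fs$signature, "PPDK")) default_ppdk_signatures()[[1]]$pattern
                    else if (identical(fs$signature, "PEPS")) default_peps_signatures()[[1]]$pattern
                    else fs$signature,
        signature_position = if (is.null(fs$signature)) NULL else 40L,
        mutation_rate = rate,
        seed = seed + 100L + k
      )
      sets[[k]] <- gen_protein_family(
        spec, fs$n, organism = fs$organism %||% paste0("synthetic_", fs$family),
        taxon_group = fs$taxon_group %||% "other",
        id_prefix = sprintf("%s_s%02d", fs$family, k)
      )
    }
    proteins <- do.call(rbind_protein_sets, sets)
  }
  paths$proteins <- file.path(cfg$outdir, "proteins.fasta")
  write_fasta(proteins, paths$proteins)
  log <- stage_log(log, "proteins", "%d sequence(s) in", nrow(proteins))

  ## --- read QC --------------------------------------------------------------
  reads <- if (!is.null(cfg$reads$fastq)) {
    read_fastq(cfg$reads$fastq)
  } else {
    rs <- cfg$reads$simulate
    gen_reads(rs$n, rs$length, rs$low_q_fraction, rs$n_fraction, seed = seed + 200L)
  }
  fcfg <- do.call(read_filter_config, cfg$read_filter %||% list())
  flt <- filter_reads(reads, fcfg)
  paths$reads_kept <- file.path(cfg$outdir, "reads_kept.fastq")
  write_fastq(flt$kept, paths$reads_kept)
  log <- stage_log(log, "qc", "%d read(s) in, %d kept, %d discarded",
                   nrow(reads), nrow(flt$kept), flt$n_discarded)

  ## --- classification -------------------------------------------------------
  # The diagnostic-site spec is anchored on the panel's own PEPC ancestor at
  # its midpoint, matching where the simulated families plant the residue.
  pepc_row <- panel[panel$enzyme_label == "PEPC", , drop = FALSE]
  class(pepc_row) <- c("protein_set", "data.frame")
  site_spec <- diagnostic_site_spec(reference = pepc_row,
                                    reference_position = nchar(pepc_row$residues) %/% 2L)
  report <- classification_report(proteins, spec = site_spec)
  paths$classification <- file.path(cfg$outdir, "classification.tsv")
  write_tsv(report, paths$classification)
  log <- stage_log(log, "classify", "%d sequence(s) classified", nrow(report))

  ## --- inventory ------------------------------------------------------------
  assignments <- assign_families(proteins, panel, min_identity = cfg$min_identity %||% 0.35)
  inv <- build_inventory(assignments)
  comp <- assess_subtypes(inv)
  paths$assignments <- file.path(cfg$outdir, "assignments.tsv")
  paths$inventory <- file.path(cfg$outdir, "inventory.tsv")
  paths$completeness <- file.path(cfg$outdir, "completeness.tsv")
  write_tsv(assignments, paths$assignments)
  write_inventory(inv, paths$inventory)
  write_tsv(as.data.frame(comp), paths$completeness)
  log <- stage_log(log, "inventory", "%d assignment(s), %d unassigned, %d organism(s)",
                   nrow(assignments), sum(assignments$label == "unassigned"), nrow(inv))

  ## --- trees ----------------------------------------------------------------
  if (!is.null(cfg$trees$newick_a)) {
    run_a <- read_newick_samples(cfg$trees$newick_a)
    run_b <- if (!is.null(cfg$trees$newick_b)) read_newick_samples(cfg$trees$newick_b) else NULL
  } else {
    ts <- cfg$trees$simulate
    base <- with_seed(seed + 300L, ape::rtree(ts$n_taxa, rooted = FALSE, br = NULL))
    base$tip.label <- sprintf("t%02d", seq_len(ts$n_taxa))
    run_a <- gen_tree_samples(tree_sim_spec(base, ts$n_samples, ts$perturbation_prob,
                                            seed = seed + 301L))
    run_b <- gen_tree_samples(tree_sim_spec(base, ts$n_samples, ts$perturbation_prob,
                                            seed = seed + 302L))
  }
  sched <- do.call(run_schedule, cfg$schedule %||% list())
  post_a <- apply_burnin(run_a, sched$burnin_fraction)
  bt <- bipartition_frequencies(post_a)
  cons <- majority_rule_consensus(bt)
  paths$bipartitions <- file.path(cfg$outdir, "bipartitions.tsv")
  paths$consensus <- file.path(cfg$outdir, "consensus.nwk")
  write_tsv(as.data.frame(bt), paths$bipartitions)
  writeLines(ape::write.tree(cons$tree), paths$consensus)
  asdsf_val <- if (!is.null(run_b)) asdsf(apply_burnin(run_b, sched$burnin_fraction), post_a) else NA_real_
  paths$asdsf <- file.path(cfg$outdir, "asdsf.tsv")
  writeLines(c("metric\tvalue",
               sprintf("expected_sample_count\t%d", expected_sample_count(sched)),
               sprintf("asdsf\t%s", ifelse(is.na(asdsf_val), "NA", format(asdsf_val)))),
             paths$asdsf)
  log <- stage_log(log, "trees", "%d tree(s) in, %d after burn-in, %d split(s), ASDSF %s",
                   length(run_a$trees), length(post_a$trees), nrow(bt),
                   ifelse(is.na(asdsf_val), "NA", sprintf("%.4f", asdsf_val)))

  ## --- origin ---------------------------------------------------------------
  os <- cfg$origin$simulate
  scen <- gen_origin_scenario(os$n_euk, os$donor, os$n_per_prok_group, os$divergence,
                              seed = seed + 400L)
  labels <- stats::setNames(scen$taxon_group, scen$id)
  euk_group <- setdiff(unique(scen$taxon_group), PROKARYOTE_GROUPS)[1]
  dm <- pairwise_distance_matrix(scen)
  tr <- nj_tree(dm)
  call <- assign_origin(tr, labels, euk_group)
  paths$origin_tree <- file.path(cfg$outdir, "origin_nj.nwk")
  paths$origin <- file.path(cfg$outdir, "origin.tsv")
  writeLines(ape::write.tree(tr), paths$origin_tree)
  write_tsv(data.frame(eukaryote_group = call$eukaryote_group,
                       inferred_donor = call$inferred_donor,
                       true_donor = attr(scen, "donor"),
                       stringsAsFactors = FALSE),
            paths$origin)
  log <- stage_log(log, "origin", "donor %s inferred (truth %s)",
                   call$inferred_donor, attr(scen, "donor"))

  manifest <- structure(
    list(package_version = as.character(utils::packageVersion("c4kit")),
         seed = seed, config_hash = config_hash, outdir = cfg$outdir,
         paths = paths, log = log),
    class = "run_manifest"
  )
  paths$log <- file.path(cfg$outdir, "run.log")
  writeLines(log, paths$log)
  manifest$paths <- paths
  jsonlite::write_json(
    list(package_version = manifest$package_version, seed = seed,
         config_hash = config_hash, paths = lapply(paths, basename)),
    file.path(cfg$outdir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> c4kit %s, seed %d, outdir %s\n",
              x$package_version, x$seed, x$outdir))
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Human-readable summary report of a pipeline run
#'
#' Reads the tables a [run_pipeline()] manifest points at and renders a
#' markdown report: per-taxon-group classification tallies, the inventory
#' and subtype-completeness matrix, and the origin call. A missing table is
#' noted as a gap rather than failing.
#'
#' @param manifest A `run_manifest`.
#' @return Character vector of markdown lines (also printed), invisibly.
#' @export
summary_report <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  p <- manifest$paths
  out <- c("# c4kit run report", "",
           sprintf("seed: %d; config hash: %s", manifest$seed, manifest$config_hash), "")

  out <- c(out, "## Classification")
  if (!is.null(p$classification) && file.exists(p$classification)) {
    cl <- utils::read.delim(p$classification)
    tally <- as.data.frame(table(taxon_group = cl$taxon_group, pepc_type = cl$pepc_type))
    tally <- tally[tally$Freq > 0, , drop = FALSE]
    out <- c(out,
             sprintf("- %d sequence(s) classified", nrow(cl)),
             sprintf("- %s / %s: %d", tally$taxon_group, tally$pepc_type, tally$Freq),
             sprintf("- PPDK verdicts: %s",
                     paste(sprintf("%s=%d", names(table(cl$ppdk_verdict)),
                                   as.integer(table(cl$ppdk_verdict))), collapse = ", ")))
  } else {
    out <- c(out, "- classification table missing")
  }

  out <- c(out, "", "## Subtype completeness")
  if (!is.null(p$completeness) && file.exists(p$completeness)) {
    comp <- utils::read.delim(p$completeness)
    if (nrow(comp) == 0L) {
      out <- c(out, "- no organisms")
    } else {
      out <- c(out, sprintf("- %s / %s: %s%s", comp$organism, comp$subtype, comp$status,
                            ifelse(comp$status == "incomplete" & nzchar(comp$missing),
                                   paste0(" (missing ", comp$missing, ")"), "")))
    }
  } else {
    out <- c(out, "- completeness table missing")
  }

  out <- c(out, "", "## Trees")
  if (!is.null(p$asdsf) && file.exists(p$asdsf)) {
    tt <- utils::read.delim(p$asdsf)
    out <- c(out, sprintf("- %s: %s", tt$metric, tt$value))
  } else {
    out <- c(out, "- tree summary missing")
  }

  out <- c(out, "", "## Origin")
  if (!is.null(p$origin) && file.exists(p$origin)) {
    og <- utils::read.delim(p$origin)
    out <- c(out, sprintf("- %s <- %s (simulated truth: %s)",
                          og$eukaryote_group, og$inferred_donor, og$true_donor))
  } else {
    out <- c(out, "- origin table missing")
  }

  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
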