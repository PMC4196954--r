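#' MCMC sampling-schedule bookkeeping
#'
#' A run schedule records how a tree sample was produced: total generations,
#' the sampling stride, whether the initial state is written, and the burn-in
#' fraction. Defaults mirror the usual Bayesian set-up of 5,000,000
#' generations sampled every 100 with the initial state included and a 25%
#' burn-in.
#'
#' @param generations Total generations (default 5e6).
#' @param sample_every Sampling stride (>= 1, default 100).
#' @param include_initial Whether the initial state is among the samples
#'   (default `TRUE`).
#' @param burnin_fraction Fraction of samples discarded as burn-in, in
#'   `[0, 1)` (default 0.25).
#' @return A list of class `run_schedule`.
#' @export
run_schedule <- function(generations = 5e6, sample_every = 100,
                         include_initial = TRUE, burnin_fraction = 0.25) {
  if (sample_every < 1) stop("`sample_every` must be >= 1", call. = FALSE)
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("`burnin_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(list(generations = generations, sample_every = sample_every,
                 include_initial = include_initial,
                 burnin_fraction = burnin_fraction),
            class = "run_schedule")
}

#' Expected number of sampled trees under a schedule
#'
#' `floor(generations / sample_every)`, plus one when the initial state is
#' written: 5,000,000 generations sampled every 100 with the initial state
#' give 50,001 trees.
#'
#' @param sched A [run_schedule].
#' @return Integer sample count.
#' @export
expected_sample_count <- function(sched = run_schedule()) {
  stopifnot(inherits(sched, "run_schedule"))
  floor(sched$generations / sched$sample_every) + as.integer(isTRUE(sched$include_initial))
}

#' Discard burn-in samples
#'
#' Drops the first `floor(fraction * n)` trees; order of the rest is
#' preserved. An empty set stays empty.
#'
#' @param samples A [tree_sample_set].
#' @param fraction Burn-in fraction in `[0, 1)` (default 0.25).
#' @return A [tree_sample_set].
#' @export
apply_burnin <- function(samples, fraction = 0.25) {
  stopifnot(inherits(samples, "tree_sample_set"))
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)", call. = FALSE)
  n <- length(samples$trees)
  if (n == 0L) return(samples)
  drop <- floor(fraction * n)
  tree_sample_set(samples$trees[seq.int(drop + 1L, n)])
}

# Leaf sets under every internal node of a phylo, by one reverse-preorder
# pass over the edge matrix.
node_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  ed <- tree$edge
  for (e in rev(seq_len(nrow(ed)))) {
    p <- ed[e, 1]; ch <- ed[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Canonical nontrivial splits of one tree as strings: the side containing the
# lexicographically smallest leaf, sorted and comma-joined.  Complementary
# clades (e.g. the two children of a bifurcating root) collapse to one key.
tree_split_keys <- function(tree, leaf_set) {
  nt <- length(tree$tip.label)
  n <- length(leaf_set)
  smallest <- leaf_set[1L]
  sets <- node_tip_sets(tree)
  root <- nt + 1L
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(nt))
  keys <- character(0)
  for (nd in internal) {
    side <- sets[[nd]]
    k <- length(side)
    if (k < 2L || k > n - 2L) next
    key_side <- if (smallest %in% side) side else setdiff(leaf_set, side)
    keys <- c(keys, paste(sort(key_side), collapse = ","))
  }
  unique(keys)
}

#' Bipartition (split) frequencies of a tree sample
#'
#' Every tree contributes its nontrivial splits (an unrooted binary tree on
#' `n` leaves has `n - 3`); frequencies are counts over the number of trees.
#' Splits are keyed canonically by the sorted side containing the
#' lexicographically smallest leaf.
#'
#' @param samples A [tree_sample_set] with >= 1 tree.
#' @return A `bipartition_table`: a data frame with columns `split`,
#'   `complement`, `count`, `frequency`, ordered by decreasing frequency,
#'   with attributes `n_trees` and `leaf_set`.
#' @export
bipartition_frequencies <- function(samples) {
  stopifnot(inherits(samples, "tree_sample_set"))
  n_trees <- length(samples$trees)
  if (n_trees < 1L) stop("need at least one tree", call. = FALSE)
  leaf_set <- samples$leaf_set
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in samples$trees) {
    for (key in tree_split_keys(tr, leaf_set)) {
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  comp <- vapply(keys, function(k) {
    paste(sort(setdiff(leaf_set, strsplit(k, ",", fixed = TRUE)[[1]])), collapse = ",")
  }, character(1))
  out <- data.frame(split = keys, complement = comp, count = unname(cnt),
                    frequency = unname(cnt) / n_trees, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$split), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trees") <- n_trees
  attr(out, "leaf_set") <- leaf_set
  class(out) <- c("bipartition_table", "data.frame")
  out
}

#' @export
print.bipartition_table <- function(x, ...) {
  cat(sprintf("<bipartition_table> %d split(s) over %d tree(s)\n",
              nrow(x), attr(x, "n_trees")))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Majority-rule consensus tree
#'
#' Retains the splits with frequency strictly above `threshold` (>= 0.5,
#' which guarantees mutual compatibility), attaches their frequencies as
#' supports, and collapses everything else into polytomies. Two topologies
#' at exactly 50/50 therefore yield a star tree.
#'
#' @param table A `bipartition_table` from [bipartition_frequencies()].
#' @param threshold Retention threshold (default 0.5; must be >= 0.5).
#' @return A list of class `consensus_tree` with `tree` (a `phylo` whose
#'   node labels carry supports) and `supports` (data frame split/support).
#' @export
majority_rule_consensus <- function(table, threshold = 0.5) {
  stopifnot(inherits(table, "bipartition_table"))
  if (threshold < 0.5) {
    stop("threshold must be >= 0.5 (split compatibility is not guaranteed below)", call. = FALSE)
  }
  leaf_set <- attr(table, "leaf_set")
  keep <- table[table$frequency > threshold, , drop = FALSE]
  # Represent each retained split as the clade NOT containing the smallest
  # leaf; rooting at the smallest leaf's side turns them into nested clades.
  clades <- lapply(keep$complement, function(s) strsplit(s, ",", fixed = TRUE)[[1]])
  supports <- keep$frequency

  build <- function(members, idx) {
    # idx: indices of retained clades strictly inside `members`.
    if (length(idx)) {
      sizes <- lengths(clades[idx])
      ord <- idx[order(-sizes)]
      maximal <- ord[!vapply(seq_along(ord), function(i) {
        any(vapply(seq_len(i - 1L), function(j) {
          all(clades[[ord[i]]] %in% clades[[ord[j]]])
        }, logical(1)))
      }, logical(1))]
    } else {
      maximal <- integer(0)
    }
    covered <- unlist(clades[maximal])
    parts <- character(0)
    for (mi in maximal) {
      inner <- setdiff(idx, mi)
      inner <- inner[vapply(inner, function(j) all(clades[[j]] %in% clades[[mi]]), logical(1))]
      parts <- c(parts, sprintf("(%s)%g", build(clades[[mi]], inner), supports[mi]))
    }
    parts <- c(parts, sort(setdiff(members, covered)))
    paste(parts, collapse = ",")
  }

  newick <- sprintf("(%s);", build(leaf_set, seq_along(clades)))
  tree <- ape::read.tree(text = newick)
  structure(
    list(tree = tree,
         supports = data.frame(split = keep$split, support = keep$frequency,
                               stringsAsFactors = FALSE),
         threshold = threshold),
    class = "consensus_tree"
  )
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("<consensus_tree> %d leaves, %d supported split(s) above %.2f\n",
              length(x$tree$tip.label), nrow(x$supports), x$threshold))
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Average standard deviation of split frequencies (ASDSF)
#'
#' The stationarity diagnostic for two independent runs: over all splits
#' reaching frequency `min_freq` in at least one run, the sample standard
#' deviation of the split's two frequencies is averaged. Identical runs give
#' 0; values below 0.01 conventionally indicate that both runs sample the
#' same split distribution.
#'
#' @param run_a,run_b Two [tree_sample_set]s on the same leaf set.
#' @param min_freq Minimum split frequency for inclusion (default 0.10).
#' @return A single number (0 when no split qualifies).
#' @export
asdsf <- function(run_a, run_b, min_freq = 0.10) {
  stopifnot(inherits(run_a, "tree_sample_set"), inherits(run_b, "tree_sample_set"))
  if (!length(run_a$trees) || !length(run_b$trees)) stop("both runs must be non-empty", call. = FALSE)
  if (!identical(run_a$leaf_set, run_b$leaf_set)) stop("leaf sets differ between runs", call. = FALSE)
  ta <- bipartition_frequencies(run_a)
  tb <- bipartition_frequencies(run_b)
  fa <- stats::setNames(ta$frequency, ta$split)
  fb <- stats::setNames(tb$frequency, tb$split)
  keys <- union(names(fa)[fa >= min_freq], names(fb)[fb >= min_freq])
  if (!length(keys)) return(0)
  f1 <- ifelse(keys %in% names(fa), fa[keys], 0)
  f2 <- ifelse(keys %in% names(fb), fb[keys], 0)
  mean(abs(f1 - f2) / sqrt(2))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (exact on additive matrices) with negative
#' branch lengths clamped to zero. The matrix must be symmetric with a zero
#' diagonal and at least four taxa.
#'
#' @param dm Symmetric numeric distance matrix with taxon dimnames.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm))
  if (nrow(dm) < 4L) stop("need >= 4 taxa", call. = FALSE)
  if (!isTRUE(all.equal(dm, t(dm), check.attributes = FALSE))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix must have a zero diagonal", call. = FALSE)
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Tips under `node` in a rooted phylo.
tips_under <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  node_tip_sets(tree)[[node]]
}

#' Assign a prokaryotic donor lineage to a eukaryotic group
#'
#' Formalizes the visual sister-group reading of a gene tree: the tree is
#' midpoint-rooted (unit branch lengths are assumed when none are present),
#' and the smallest clade containing every leaf of `euk_group` plus at least
#' one prokaryote leaf is located. The inferred donor is the prokaryote
#' group present in that clade — or `"mixed"` when several are.
#'
#' @param tree A `phylo` containing >= 1 `euk_group` leaf and >= 1
#'   prokaryote leaf.
#' @param labels Named character vector mapping every leaf to its taxon
#'   group.
#' @param euk_group The eukaryotic taxon group whose origin is sought.
#' @return A list of class `origin_call` with `eukaryote_group`,
#'   `inferred_donor`, `donor_groups`, `clade_tips`, `support` (`NA` for a
#'   single tree; see [origin_support()]).
#' @export
assign_origin <- function(tree, labels, euk_group) {
  stopifnot(inherits(tree, "phylo"))
  labels <- labels[tree$tip.label]
  if (anyNA(labels)) stop("every leaf needs a taxon-group label", call. = FALSE)
  euk_tips <- names(labels)[labels == euk_group]
  prok_tips <- names(labels)[labels %in% PROKARYOTE_GROUPS]
  if (!length(euk_tips)) stop(sprintf("no leaves of group \"%s\"", euk_group), call. = FALSE)
  if (!length(prok_tips)) stop("no prokaryote leaves in tree", call. = FALSE)

  rtree <- tree
  if (is.null(rtree$edge.length)) rtree$edge.length <- rep(1, nrow(rtree$edge))
  rtree <- phangorn::midpoint(rtree)

  nt <- length(rtree$tip.label)
  node <- if (length(euk_tips) == 1L) {
    match(euk_tips, rtree$tip.label)
  } else {
    ape::getMRCA(rtree, euk_tips)
  }
  root <- nt + 1L
  parent_of <- function(nd) rtree$edge[rtree$edge[, 2] == nd, 1]
  repeat {
    clade <- tips_under(rtree, node)
    if (any(clade %in% prok_tips)) break
    if (node == root) break
    node <- parent_of(node)
  }
  donors <- sort(unique(labels[clade[clade %in% prok_tips]]))
  structure(
    list(eukaryote_group = euk_group,
         inferred_donor = if (length(donors) == 1L) unname(donors) else "mixed",
         donor_groups = unname(donors), clade_tips = clade, support = NA_real_),
    class = "origin_call"
  )
}

#' @export
print.origin_call <- function(x, ...) {
  cat(sprintf("<origin_call> %s <- %s", x$eukaryote_group, x$inferred_donor))
  if (!is.na(x$support)) cat(sprintf(" (support %.2f)", x$support))
  cat("\n")
  invisible(x)
}

#' Origin call with support over a tree sample
#'
#' Runs [assign_origin()] on every sampled tree; the reported donor is the
#' modal donor and the support is the fraction of samples agreeing with it.
#'
#' @param samples A [tree_sample_set].
#' @inheritParams assign_origin
#' @return An `origin_call` with `support` set.
#' @export
origin_support <- function(samples, labels, euk_group) {
  stopifnot(inherits(samples, "tree_sample_set"))
  if (!length(samples$trees)) stop("empty tree sample", call. = FALSE)
  calls <- vapply(samples$trees, function(tr) {
    assign_origin(tr, labels, euk_group)$inferred_donor
  }, character(1))
  tab <- sort(table(calls), decreasing = TRUE)
  donor <- names(tab)[1L]
  structure(
    list(eukaryote_group = euk_group, inferred_donor = donor,
         donor_groups = donor, clade_tips = NULL,
         support = unname(tab[1L]) / length(calls)),
    class = "origin_call"
  )
}
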