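# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Exhaustive enumeration of all global alignments (three moves per column,
# affine run costs accumulated incrementally).  Exponential: only for short
# strings.
oracle_align_score <- function(a, b, s) {
  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  sub <- s$sub
  go <- s$gap_open
  ge <- s$gap_extend
  n <- length(ach)
  m <- length(bch)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > n && j > m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= n && j <= m) rec(i + 1L, j + 1L, 1L, acc + sub[ach[i], bch[j]])
    if (i <= n) rec(i + 1L, j, 2L, acc - (if (last == 2L) ge else go + ge))
    if (j <= m) rec(i, j + 1L, 3L, acc - (if (last == 3L) ge else go + ge))
  }
  rec(1L, 1L, 0L, 0)
  best
}

# Identity oracle: fraction of equal residues between two ungapped strings of
# equal length (the generators emit fixed-length families, where the
# gap-free alignment is optimal under the default scheme).
oracle_equal_length_identity <- function(a, b) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  mean(ac == bc)
}

# Split-containment oracle: a tree contains the split A|B iff A is
# monophyletic once the tree is rooted at a leaf of B (via ape, not via the
# package's edge-walk).
tree_has_split <- function(tree, side_a) {
  other <- setdiff(tree$tip.label, side_a)
  rooted <- ape::root(tree, outgroup = other[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, side_a)
}

# Brute-force bipartition frequencies for small leaf sets: enumerate every
# nontrivial subset containing the first leaf and count containment.
oracle_split_frequencies <- function(trees, leaf_set) {
  leaf_set <- sort(leaf_set)
  n <- length(leaf_set)
  rest <- leaf_set[-1]
  out <- list()
  for (k in seq_len(n - 3L) + 1L) {          # sizes 2 .. n-2 of the key side
    combs <- utils::combn(rest, k - 1L, simplify = FALSE)
    for (cmb in combs) {
      side <- sort(c(leaf_set[1], cmb))
      cnt <- sum(vapply(trees, tree_has_split, logical(1), side_a = side))
      if (cnt > 0) out[[paste(side, collapse = ",")]] <- cnt / length(trees)
    }
  }
  out
}

random_peptide <- function(len, alphabet = c("A", "R", "N", "D", "C", "Q", "E", "G")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A one-row protein_set from a bare residue string.
as_record <- function(residues, id = "q1", organism = "test organism",
                      taxon_group = "other") {
  protein_set(id, organism, taxon_group, residues)
}
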