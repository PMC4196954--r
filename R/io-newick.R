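#' Tree-sample sets
#'
#' A `tree_sample_set` wraps an ordered collection of leaf-labeled trees that
#' share one leaf set (the posterior-sample object that burn-in, bipartition
#' frequencies, consensus and ASDSF all operate on). Order is sampling order.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @return An object of class `tree_sample_set` with elements `trees`
#'   (a `multiPhylo`) and `leaf_set` (sorted common labels).
#' @export
tree_sample_set <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) == 0L) {
    out <- list(trees = structure(list(), class = "multiPhylo"), leaf_set = character())
    class(out) <- "tree_sample_set"
    return(out)
  }
  stopifnot(all(vapply(trees, inherits, logical(1), "phylo")))
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop(sprintf("leaf set of tree %d differs from tree 1", i), call. = FALSE)
    }
  }
  out <- list(trees = structure(trees, class = "multiPhylo"), leaf_set = ref)
  class(out) <- "tree_sample_set"
  out
}

#' @export
print.tree_sample_set <- function(x, ...) {
  cat(sprintf("<tree_sample_set> %d tree(s) on %d leaves", length(x$trees),
              length(x$leaf_set)))
  if (length(x$leaf_set)) {
    cat(": ", paste(utils::head(x$leaf_set, 8L), collapse = ", "))
    if (length(x$leaf_set) > 8L) cat(", ...")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.tree_sample_set <- function(x) length(x$trees)

#' Read Newick tree samples, one tree per line
#'
#' Accepts the narrow Newick dialect the package emits: unquoted labels
#' without whitespace; quoted labels are rejected. All trees must share one
#' leaf set; the first offending sample is named otherwise.
#'
#' @param path Path to a file with one Newick string per line.
#' @return A [tree_sample_set] (empty file gives an empty set).
#' @export
read_newick_samples <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(tree_sample_set(list()))
  quoted <- grepl("'", lines, fixed = TRUE) | grepl("\"", lines, fixed = TRUE)
  if (any(quoted)) {
    stop(sprintf("quoted labels are not supported (line %d)", which(quoted)[1L]),
         call. = FALSE)
  }
  trees <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    n_open <- nchar(gsub("[^(]", "", lines[i]))
    n_close <- nchar(gsub("[^)]", "", lines[i]))
    if (n_open != n_close) {
      stop(sprintf("unbalanced parentheses in Newick string at line %d", i),
           call. = FALSE)
    }
    tr <- tryCatch(ape::read.tree(text = lines[i]), error = function(e) NULL)
    if (is.null(tr)) stop(sprintf("Newick parse error at line %d", i), call. = FALSE)
    trees[[i]] <- tr
  }
  tree_sample_set(trees)
}

#' Write a tree-sample set as Newick, one tree per line
#'
#' @param x A [tree_sample_set] (or a single `phylo`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick_samples <- function(x, path) {
  if (inherits(x, "phylo")) x <- tree_sample_set(list(x))
  stopifnot(inherits(x, "tree_sample_set"))
  if (length(x$trees) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  writeLines(vapply(x$trees, function(tr) ape::write.tree(tr), character(1)), path)
  invisible(path)
}
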