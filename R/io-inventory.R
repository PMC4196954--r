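#' Read an organism-by-enzyme gene inventory table
#'
#' The expected layout mirrors published gene-count tables: a delimited file
#' whose first two columns are `Taxonomy` and `Organism`, followed by one
#' column per enzyme family or variant holding non-negative integer counts.
#' Blank cells mean zero.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator (default tab).
#' @return An `inventory_matrix`: an integer matrix with organisms as rows and
#'   enzyme columns, with a `taxonomy` attribute (named character vector).
#' @export
read_inventory <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 3L) stop("inventory needs Taxonomy, Organism and >=1 count column", call. = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  counts[counts == "" | is.na(counts)] <- "0"
  num <- suppressWarnings(matrix(as.numeric(counts), nrow = nrow(counts),
                                 dimnames = dimnames(counts)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at row %d, column \"%s\": \"%s\" (must be a non-negative integer)",
                 bad[1, 1], colnames(counts)[bad[1, 2]], counts[bad[1, 1], bad[1, 2]]),
         call. = FALSE)
  }
  m <- matrix(as.integer(num), nrow = nrow(num), dimnames = list(df[[2]], colnames(num)))
  inventory_matrix(m, taxonomy = stats::setNames(df[[1]], df[[2]]))
}

#' Construct an inventory matrix
#'
#' @param counts Integer matrix, organisms as row names, enzyme labels as
#'   column names.
#' @param taxonomy Optional named character vector mapping organism to a
#'   taxonomy string (used for row ordering on write).
#' @return An `inventory_matrix`.
#' @export
inventory_matrix <- function(counts, taxonomy = NULL) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("inventory counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(counts, taxonomy = taxonomy, class = c("inventory_matrix", class(counts)))
}

#' Write an inventory matrix as TSV
#'
#' Rows are ordered by (taxonomy, organism); zero counts are written as
#' blanks, matching the layout [read_inventory] consumes (round-trip stable).
#'
#' @param inv An `inventory_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inv, path) {
  stopifnot(inherits(inv, "inventory_matrix"))
  tax <- attr(inv, "taxonomy")
  orgs <- rownames(inv) %||% character()
  taxv <- if (is.null(tax)) rep("", length(orgs)) else unname(tax[orgs])
  taxv[is.na(taxv)] <- ""
  ord <- order(taxv, orgs)
  cells <- matrix(as.character(unclass(inv)[ord, , drop = FALSE]), nrow = length(orgs))
  cells[cells == "0"] <- ""
  header <- paste(c("Taxonomy", "Organism", colnames(inv)), collapse = "\t")
  rows <- vapply(seq_along(orgs), function(i) {
    paste(c(taxv[ord][i], orgs[ord][i], cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
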