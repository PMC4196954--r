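#' @useDynLib c4kit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Amino-acid alphabet used throughout: 20 standard residues plus X (unknown).
AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X"
)

# Closed taxon-group vocabulary; anything else maps to "other" on input.
TAXON_GROUPS <- c(
  "archaea", "proteobacteria", "cyanobacteria",
  "rhodophyta", "chlorophyta_plants", "ochrophyta",
  "cryptophyta", "glaucophyta", "other"
)

PROKARYOTE_GROUPS <- c("archaea", "proteobacteria", "cyanobacteria")

# Background residues: uniform over the 20 standard amino acids (X excluded).
BACKGROUND_AA <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Enzyme families and the cofactor/compartment-resolved variant vocabulary.
ENZYME_FAMILIES <- c("PEPC", "PPDK", "PEPS", "ALT", "AST", "MDH", "ME", "PK", "PCK")
ENZYME_VARIANTS <- c(
  "PEPC", "PPDK", "PEPS", "ALT", "PK", "PCK",
  "AST-cyt", "AST-mit", "MDH-NAD", "MDH-NADP", "ME-NAD", "ME-NADP"
)

# Evaluate `expr` under a locally seeded RNG, restoring (or clearing) the
# caller's .Random.seed afterwards.  Every generator routes its randomness
# through this so a call is a pure function of its arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Small helper: proportion argument check.
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
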