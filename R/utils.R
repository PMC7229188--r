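#' netreconfig: dynamic network reconfiguration analysis for task fMRI
#'
#' Tools for HRF-weighted functional connectivity, single-layer and
#' multilayer modularity maximization, module-allegiance cartography
#' (system recruitment and integration), signal-detection behavioral
#' scoring, and synthetic ground-truth data generation.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats convolve cor cor.test dgamma p.adjust pnorm qnorm rbinom
#'   rnorm runif sd t.test var aggregate
#' @importFrom utils read.table write.table
NULL

# Derive a stream of child seeds from a master seed.  Keeps every seed a
# 32-bit integer so set.seed() never overflows.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Canonicalize module labels by order of first appearance
#'
#' Relabels a module assignment so labels are the integers 1, 2, ... in
#' the order modules are first encountered.  Used so that partition files
#' are reproducible regardless of the optimizer's internal labels.
#'
#' @param labels vector of module labels (any atomic type).
#' @return integer vector of the same length with contiguous labels.
#' @export
canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes
#' (Hubert & Arabie).  Used to score recovery of planted partitions.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar; 1 for identical partitions (up to relabeling),
#'   around 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Internal validation helpers ------------------------------------------------

check_square_symmetric <- function(A, tol = 1e-8, what = "matrix") {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop(what, " must be a square matrix")
  if (max(abs(A - t(A))) > tol)
    stop(what, " must be symmetric")
  invisible(TRUE)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("'", name, "' must be a probability in [0, 1]")
  invisible(TRUE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop("'", name, "' must be an integer >= ", min)
  invisible(TRUE)
}
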