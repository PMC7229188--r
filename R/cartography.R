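#' Module allegiance matrix of a partition ensemble
#'
#' `P[i, j]` is the fraction of (optimization x layer) instances in which
#' nodes `i` and `j` were assigned to the same module, averaged over all
#' `O` optimizations and `T` layers.  `P` is symmetric with unit diagonal
#' and entries in `[0, 1]`; it is the substrate of recruitment and
#' integration.
#'
#' @param ensemble a [run_ensemble()] result, a list of
#'   `multilayer_partition` objects, or a list of node x layer assignment
#'   matrices.
#' @return object of class `allegiance_matrix`: the node x node matrix
#'   `P` with attributes `n_optimizations` and `n_layers`.
#' @export
allegiance <- function(ensemble) {
  if (inherits(ensemble, "multilayer_partition")) ensemble <- list(ensemble)
  if (!length(ensemble)) stop("empty ensemble")
  mats <- lapply(ensemble, function(e) {
    if (inherits(e, "multilayer_partition")) e$assignment else as.matrix(e)
  })
  n <- nrow(mats[[1L]])
  T_ <- ncol(mats[[1L]])
  for (m in mats)
    if (nrow(m) != n || ncol(m) != T_)
      stop("all ensemble members must share node and layer dimensions")
  P <- matrix(0, n, n)
  for (m in mats) {
    for (t in seq_len(T_)) {
      g <- m[, t]
      P <- P + outer(g, g, "==")
    }
  }
  P <- P / (length(mats) * T_)
  dimnames(P) <- dimnames(mats[[1L]])[c(1L, 1L)]
  structure(P, class = c("allegiance_matrix", "matrix"),
            n_optimizations = length(mats), n_layers = T_)
}

#' @export
print.allegiance_matrix <- function(x, ...) {
  cat("Module allegiance matrix:", nrow(x), "nodes; averaged over",
      attr(x, "n_optimizations"), "optimizations x",
      attr(x, "n_layers"), "layers\n")
  cat("Off-diagonal allegiance: mean", signif(mean(x[upper.tri(x)]), 4),
      "\n")
  invisible(x)
}

#' System recruitment from an allegiance matrix
#'
#' Recruitment of a system `S` is the average allegiance among its nodes,
#' `R_S = (1 / n_S^2) * sum_{i in S} sum_{j in S} P_ij` — high when the
#' system's regions stay in a common module throughout the task blocks.
#' The double sum includes the `i = j` diagonal terms; set
#' `include_diagonal = FALSE` for the diagonal-excluded variant.
#'
#' @param P an [allegiance()] matrix (or plain symmetric matrix in
#'   `[0, 1]`).
#' @param atlas a [system_atlas()] aligned to the rows of `P`.
#' @param system system label; `NULL` returns all systems (named vector).
#' @param include_diagonal include `i = j` terms (default `TRUE`).
#' @return recruitment value(s) in `[0, 1]`.
#' @export
recruitment <- function(P, atlas, system = NULL, include_diagonal = TRUE) {
  vals <- system_block_means(P, atlas$system, include_diagonal)
  rec <- diag(vals)
  names(rec) <- rownames(vals)
  if (is.null(system)) return(rec)
  if (!system %in% names(rec)) stop("unknown system: ", system)
  rec[[system]]
}

#' Between-system integration from an allegiance matrix
#'
#' Integration of two distinct systems is the average allegiance across
#' their node pairs, `I_kl = (1 / (n_k n_l)) * sum_{i in S_k} sum_{j in
#' S_l} P_ij` — high when the systems' regions are frequently co-assigned
#' to common modules.
#'
#' @inheritParams recruitment
#' @param system_k,system_l the two distinct system labels; both `NULL`
#'   returns the full system x system matrix of block means (diagonal =
#'   recruitment).
#' @return integration value in `[0, 1]`, or the full matrix.
#' @export
integration <- function(P, atlas, system_k = NULL, system_l = NULL,
                        include_diagonal = TRUE) {
  vals <- system_block_means(P, atlas$system, include_diagonal)
  if (is.null(system_k) && is.null(system_l)) return(vals)
  if (is.null(system_k) || is.null(system_l))
    stop("supply both systems, or neither")
  if (identical(system_k, system_l))
    stop("integration needs two distinct systems; use recruitment()")
  for (s in c(system_k, system_l))
    if (!s %in% rownames(vals)) stop("unknown system: ", s)
  vals[system_k, system_l]
}

# System-block averages of P: entry (k, l) is the mean of P over
# S_k x S_l node pairs.  Diagonal exclusion only affects the (k, k)
# blocks, where the i = j terms live.
system_block_means <- function(P, labels, include_diagonal = TRUE) {
  if (length(labels) != nrow(P))
    stop("atlas has ", length(labels), " ROIs but P has ", nrow(P))
  f <- factor(labels)
  S <- stats::model.matrix(~ f - 1)  # node x system indicator
  colnames(S) <- levels(f)
  sums <- t(S) %*% P %*% S
  sizes <- colSums(S)
  denom <- outer(sizes, sizes)
  if (!include_diagonal) {
    diag(sums) <- diag(sums) - as.vector(t(S) %*% diag(P))
    diag(denom) <- sizes * (sizes - 1)
    if (any(diag(denom) == 0))
      stop("diagonal-excluded recruitment undefined for singleton systems")
  }
  sums / denom
}

#' Permutation-normalized recruitment and integration
#'
#' System sizes alone bias raw recruitment/integration.  This builds a
#' null distribution by randomly permuting the ROI-to-system
#' correspondence (system sizes preserved) `n_perm` times, recomputing
#' every coefficient for each permuted atlas, and dividing each observed
#' coefficient by its null mean.  Normalized values near 1 indicate no
#' structure beyond system size.
#'
#' @inheritParams recruitment
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `cartography_result`: long-format data.frame
#'   with columns `measure` ("recruitment" or "integration"), `system_k`,
#'   `system_l` (equal for recruitment), `raw`, `null_mean`, `normalized`,
#'   plus attributes `n_perm` and `seed`.
#' @export
permutation_normalize <- function(P, atlas, n_perm = 1000L, seed = 1L,
                                  include_diagonal = TRUE) {
  check_count(n_perm, "n_perm")
  labels <- atlas$system
  obs <- system_block_means(P, labels, include_diagonal)
  K <- nrow(obs)
  null_sum <- matrix(0, K, K, dimnames = dimnames(obs))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      perm <- sample(labels)
      null_sum <- null_sum +
        system_block_means(P, perm, include_diagonal)
    }
  })
  null_mean <- null_sum / n_perm
  if (any(null_mean == 0)) stop("zero null mean; cannot normalize")
  ratio <- obs / null_mean
  sys <- rownames(obs)
  rows <- list()
  for (k in seq_len(K)) {
    rows[[length(rows) + 1L]] <- data.frame(
      measure = "recruitment", system_k = sys[k], system_l = sys[k],
      raw = obs[k, k], null_mean = null_mean[k, k],
      normalized = ratio[k, k], stringsAsFactors = FALSE)
  }
  if (K > 1L) {
    for (k in seq_len(K - 1L)) {
      for (l in (k + 1L):K) {
        rows[[length(rows) + 1L]] <- data.frame(
          measure = "integration", system_k = sys[k], system_l = sys[l],
          raw = obs[k, l], null_mean = null_mean[k, l],
          normalized = ratio[k, l], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cartography_result", "data.frame")
  out
}

#' @export
print.cartography_result <- function(x, ...) {
  cat("Cartography result (n_perm =", attr(x, "n_perm"), "):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
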