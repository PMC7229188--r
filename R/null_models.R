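#' Degree-preserving rewired null network
#'
#' Randomizes a weighted network by Maslov-Sneppen double-edge swaps on
#' the nonzero-edge topology, with each weight riding on its edge: two
#' edges (a,b) and (c,d) are replaced by (a,d) and (c,b) when the swap
#' creates no self-loop or duplicate edge.  The node degree sequence
#' (edge counts), the multiset of edge weights and hence the total weight
#' are preserved exactly; node strengths are not, which is what destroys
#' community structure while keeping gross connectivity.
#'
#' Graphs too small or too dense to admit any swap fall back, with a
#' warning, to shuffling the weights over the fixed edge topology.
#'
#' @param A symmetric nonnegative weighted adjacency, zero diagonal.
#' @param seed integer seed.
#' @param swaps_per_edge target number of successful swaps per edge
#'   (default 10).
#' @return rewired adjacency matrix of the same dimensions.
#' @export
rewire_null <- function(A, seed = 1L, swaps_per_edge = 10) {
  check_square_symmetric(A, what = "adjacency matrix")
  n <- nrow(A)
  ut <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  n_edge <- nrow(ut)
  if (n_edge < 2L)
    stop("need at least 2 edges to rewire")
  ei <- ut[, 1L]
  ej <- ut[, 2L]
  w <- A[ut]
  with_seed(seed, {
    exists_edge <- A > 0
    target <- ceiling(swaps_per_edge * n_edge)
    max_attempts <- 40L * target
    # pre-drawn candidate edge pairs and orientation coins keep the
    # rejection loop cheap
    cand1 <- sample.int(n_edge, max_attempts, replace = TRUE)
    cand2 <- sample.int(n_edge, max_attempts, replace = TRUE)
    coins <- runif(max_attempts) < 0.5
    successes <- 0L
    attempts <- 0L
    while (successes < target && attempts < max_attempts) {
      attempts <- attempts + 1L
      e1 <- cand1[attempts]; e2 <- cand2[attempts]
      if (e1 == e2) next
      a <- ei[e1]; b <- ej[e1]
      c <- ei[e2]; d <- ej[e2]
      if (coins[attempts]) { tmp <- c; c <- d; d <- tmp }
      if (a == c || a == d || b == c || b == d) next
      if (exists_edge[(d - 1L) * n + a] || exists_edge[(b - 1L) * n + c])
        next
      exists_edge[(b - 1L) * n + a] <- exists_edge[(a - 1L) * n + b] <- FALSE
      exists_edge[(d - 1L) * n + c] <- exists_edge[(c - 1L) * n + d] <- FALSE
      exists_edge[(d - 1L) * n + a] <- exists_edge[(a - 1L) * n + d] <- TRUE
      exists_edge[(b - 1L) * n + c] <- exists_edge[(c - 1L) * n + b] <- TRUE
      ei[e1] <- min(a, d); ej[e1] <- max(a, d)
      ei[e2] <- min(c, b); ej[e2] <- max(c, b)
      successes <- successes + 1L
    }
    out <- matrix(0, n, n, dimnames = dimnames(A))
    if (successes == 0L) {
      warning("graph admits no double-edge swap; ",
              "falling back to weight shuffling on the fixed topology")
      w <- sample(w)
      ei <- ut[, 1L]
      ej <- ut[, 2L]
    }
    out[cbind(ei, ej)] <- w
    out[cbind(ej, ei)] <- w
    out
  })
}

#' Normalized modularity against rewired nulls
#'
#' Scores the observed network with best-of-restarts Louvain, builds
#' `n_null` rewired null networks, scores each with the same restart
#' protocol, and reports `Q_normalized = Q / mean(null Q)`.  Normalizing
#' by the null mean removes the dependence of raw modularity on the
#' network's total connection strength, making values comparable across
#' subjects and sessions.
#'
#' @inheritParams best_of_runs
#' @param n_null number of rewired null networks (default 100).
#' @param swaps_per_edge passed to [rewire_null()].
#' @return object of class `modularity_result`: list with `Q`,
#'   `Q_normalized`, `partition`, `null_Q` (vector of null modularities),
#'   `n_runs`, `n_null`, `gamma`, `seed`.
#' @export
normalized_modularity <- function(A, gamma = 1, n_runs = 100L,
                                  n_null = 100L, seed = 1L,
                                  swaps_per_edge = 10) {
  check_count(n_null, "n_null")
  seeds <- derive_seeds(seed, 2L * n_null + 1L)
  obs <- best_of_runs(A, gamma, n_runs, seed = seeds[1L])
  null_Q <- vapply(seq_len(n_null), function(i) {
    null_A <- rewire_null(A, seed = seeds[2L * i],
                          swaps_per_edge = swaps_per_edge)
    best_of_runs(null_A, gamma, n_runs, seed = seeds[2L * i + 1L])$Q
  }, numeric(1))
  null_mean <- mean(null_Q)
  if (null_mean == 0) stop("null modularity mean is zero; cannot normalize")
  structure(
    list(Q = obs$Q, Q_normalized = obs$Q / null_mean,
         partition = obs$partition, null_Q = null_Q,
         n_runs = as.integer(n_runs), n_null = as.integer(n_null),
         gamma = gamma, seed = seed),
    class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat("Modularity result: Q =", signif(x$Q, 5),
      " Q_normalized =", signif(x$Q_normalized, 5), "\n")
  cat("Modules:", length(unique(x$partition)),
      " (n_runs =", x$n_runs, ", n_null =", x$n_null,
      ", gamma =", x$gamma, ", seed =", x$seed, ")\n")
  invisible(x)
}

#' Write a partition as two-column delimited text
#'
#' @param partition module labels, one per node.
#' @param roi_ids node identifiers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, roi_ids, path) {
  df <- data.frame(roi_id = roi_ids,
                   module = canonicalize_labels(partition))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
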