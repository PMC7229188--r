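# Core greedy optimizer shared by single-layer and multilayer community
# detection.  Works directly on a (supra-)modularity matrix B: it seeks a
# node labeling g maximizing sum_{ij : g_i = g_j} B_ij, by randomized
# local node moves followed by community aggregation, repeated until no
# level improves (the two-phase Louvain scheme).  Single-layer modularity
# uses B = A - gamma * k k' / 2m; the multilayer quality uses the supra
# matrix with interslice couplings on the diagonal blocks' identities.
greedy_partition <- function(B, gain_tol = 1e-10, max_levels = 50L,
                             init = NULL) {
  n0 <- nrow(B)
  membership <- seq_len(n0)
  Bcur <- B
  for (level in seq_len(max_levels)) {
    comm <- greedy_one_level(Bcur, gain_tol,
                             init = if (level == 1L) init else NULL)
    n_comm <- length(unique(comm))
    if (n_comm == nrow(Bcur) && is.null(init)) break
    membership <- comm[membership]
    if (n_comm == nrow(Bcur)) break  # randomized first level, no merge
    Bcur <- aggregate_matrix(Bcur, comm)
    if (n_comm == 1L) break
    init <- NULL
  }
  canonicalize_labels(membership)
}

# One local-move phase: nodes start in their own community (or in the
# supplied initial labeling) and are swept in random order, each moving
# to the community (or to a fresh singleton) with maximal positive gain,
# until a full pass makes no move.  Restarting different runs from
# different random initial labelings lets the ensemble escape local
# optima that the deterministic singleton start always falls into.
greedy_one_level <- function(B, gain_tol, init = NULL) {
  n <- nrow(B)
  comm <- if (is.null(init)) seq_len(n) else canonicalize_labels(init)
  next_label <- n + 1L
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      w <- B[i, ]
      w[i] <- 0  # node's own contribution is constant across choices
      cs <- rowsum(w, comm)
      labels <- as.integer(rownames(cs))
      cur <- comm[i]
      stay <- cs[match(cur, labels)]
      mx <- max(cs)
      # candidate values: join an existing community (cs) or sit alone (0)
      if (max(mx, 0) > stay + gain_tol) {
        if (mx > 0) {
          best <- which(cs >= mx - gain_tol / 2)
          pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)]
                  else best
          comm[i] <- labels[pick]
        } else {
          comm[i] <- next_label
          next_label <- next_label + 1L
        }
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  canonicalize_labels(comm)
}

aggregate_matrix <- function(B, comm) {
  g <- factor(comm)
  rowsum(t(rowsum(B, g)), g)
}

#' Modularity of a partition (Newman-Girvan configuration null)
#'
#' Evaluates `Q = (1 / 2mu) * sum_ij (A_ij - gamma * k_i k_j / 2m) *
#' delta(g_i, g_j)` where `k` are weighted degrees, `m = mu` is half the
#' total edge weight and the Kronecker delta selects same-module pairs
#' (including `i = j`).  With `gamma = 1`, the all-in-one partition scores
#' exactly 0 on every graph.
#'
#' @param A symmetric nonnegative weighted adjacency matrix with zero
#'   diagonal and positive total weight.
#' @param partition module label per node.
#' @param gamma structural resolution parameter (default 1).
#' @return modularity value `Q`.
#' @examples
#' A <- two_clique_graph()
#' modularity_score(A, rep(1:2, each = 4))  # 0.5
#' @export
modularity_score <- function(A, partition, gamma = 1) {
  B <- modularity_matrix(A, gamma)
  g <- canonicalize_labels(partition)
  if (length(g) != nrow(A)) stop("partition length must match node count")
  two_m <- sum(A)
  sum(B * outer(g, g, "==")) / two_m
}

modularity_matrix <- function(A, gamma) {
  check_square_symmetric(A, what = "adjacency matrix")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  two_m <- sum(A)
  if (two_m <= 0) stop("empty graph: total edge weight is zero")
  k <- rowSums(A)
  A - gamma * outer(k, k) / two_m
}

#' Louvain community detection (single layer)
#'
#' Locally greedy two-phase modularity maximization: randomized node
#' sweeps moving each node to the neighboring module with maximal positive
#' gain, then module aggregation, repeated to convergence.  The sweep
#' order (and hence the local optimum reached) is controlled by `seed`.
#'
#' @inheritParams modularity_score
#' @param seed integer seed controlling the randomized sweep order.
#' @return list with `partition` (canonicalized integer labels) and `Q`
#'   (its modularity, consistent with [modularity_score()]).
#' @export
louvain <- function(A, gamma = 1, seed = 1L) {
  B <- modularity_matrix(A, gamma)
  membership <- with_seed(seed, {
    init <- sample.int(nrow(B), nrow(B), replace = TRUE)
    greedy_partition(B, init = init)
  })
  Q <- sum(B * outer(membership, membership, "==")) / sum(A)
  list(partition = membership, Q = Q, gamma = gamma, seed = seed)
}

#' Best-of-restarts Louvain
#'
#' Runs [louvain()] `n_runs` times with seeds derived from a master seed
#' and keeps the partition with the highest modularity (ties broken by
#' the lowest run index).  Restarting guards against poor local optima of
#' the greedy scheme.
#'
#' @inheritParams louvain
#' @param n_runs number of independent restarts (default 100).
#' @return as [louvain()], plus `n_runs` and the vector `run_Q` of all
#'   restart modularities.
#' @export
best_of_runs <- function(A, gamma = 1, n_runs = 100L, seed = 1L) {
  check_count(n_runs, "n_runs")
  seeds <- derive_seeds(seed, n_runs)
  runs <- lapply(seeds, function(s) louvain(A, gamma, seed = s))
  qs <- vapply(runs, `[[`, numeric(1), "Q")
  best <- which.max(qs)  # first maximum: lowest run index wins ties
  out <- runs[[best]]
  out$n_runs <- as.integer(n_runs)
  out$run_Q <- qs
  out$seed <- seed
  out
}

#' Two disconnected 4-cliques (reference graph)
#'
#' Unit-weight graph of two disconnected 4-node cliques; its natural
#' partition has modularity exactly 0.5 at `gamma = 1`.
#'
#' @return 8 x 8 adjacency matrix.
#' @export
two_clique_graph <- function() {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  A
}
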