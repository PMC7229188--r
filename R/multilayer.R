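#' Multilayer network of task-block connectivity layers
#'
#' Bundles an ordered stack of node-aligned connectivity matrices (one per
#' task block) with condition-dependent interslice coupling.  Every layer
#' pair is coupled on node identities (categorical coupling): the coupling
#' weight is `omega_same` when the two layers share a task condition and
#' `omega_diff` otherwise.  In an interleaved block design same-condition
#' blocks are never adjacent, so categorical (all-pairs) coupling is the
#' topology that realizes condition-dependent omegas.
#'
#' @param layers a [block_connectivity()] stack, or a list of symmetric
#'   nonnegative matrices sharing dimensions and node order.
#' @param layer_conditions condition label per layer (taken from the
#'   stack when `layers` is one).
#' @param gamma structural resolution; scalar or one value per layer
#'   (default 1).
#' @param omega_same coupling between same-condition layers (default 1).
#' @param omega_diff coupling between different-condition layers
#'   (default 0.5).
#' @return object of class `multilayer_network`.
#' @export
multilayer_network <- function(layers, layer_conditions = NULL, gamma = 1,
                               omega_same = 1, omega_diff = 0.5) {
  if (inherits(layers, "connectivity_stack")) {
    if (is.null(layer_conditions)) layer_conditions <- layers$conditions
    roi_ids <- layers$roi_ids
    layers <- layers$matrices
  } else {
    roi_ids <- rownames(layers[[1L]])
  }
  T_ <- length(layers)
  if (T_ < 1L) stop("need at least one layer")
  n <- nrow(layers[[1L]])
  for (s in seq_len(T_)) {
    check_square_symmetric(layers[[s]], what = paste0("layer ", s))
    if (nrow(layers[[s]]) != n)
      stop("all layers must share node count and ordering")
  }
  if (is.null(layer_conditions)) layer_conditions <- rep("task", T_)
  if (length(layer_conditions) != T_)
    stop("'layer_conditions' must have one label per layer")
  if (omega_same < 0 || omega_diff < 0) stop("omega values must be >= 0")
  gamma <- rep_len(gamma, T_)
  if (is.null(roi_ids)) roi_ids <- paste0("roi_", seq_len(n))
  structure(
    list(layers = lapply(layers, unclass), n_nodes = n, n_layers = T_,
         layer_conditions = as.character(layer_conditions),
         gamma = gamma, omega_same = omega_same, omega_diff = omega_diff,
         roi_ids = as.character(roi_ids)),
    class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("Multilayer network:", x$n_nodes, "nodes x", x$n_layers, "layers\n")
  cat("Conditions:", paste(unique(x$layer_conditions), collapse = ", "),
      "; omega_same =", x$omega_same, ", omega_diff =", x$omega_diff,
      ", gamma =", x$gamma[1L], "\n")
  invisible(x)
}

#' Interslice coupling for a pair of layer conditions
#'
#' @param cond_s,cond_r condition labels of the two layers.
#' @param omega_same,omega_diff coupling weights.
#' @param labels optional set of admissible condition labels; labels
#'   outside it raise an error.
#' @return `omega_same` if the conditions match, else `omega_diff`.
#' @export
omega_for_pair <- function(cond_s, cond_r, omega_same = 1,
                           omega_diff = 0.5, labels = NULL) {
  if (!is.null(labels)) {
    unknown <- setdiff(c(cond_s, cond_r), labels)
    if (length(unknown))
      stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  }
  ifelse(cond_s == cond_r, omega_same, omega_diff)
}

# Supra modularity matrix: intra-layer diagonal blocks A_s - gamma_s V_s
# (Newman-Girvan null per slice), interslice couplings omega_sr on node
# identities.  Interlayer entries carry no null-model penalty.  Also
# returns 2*mu with mu = (1/2) sum_js (k_js + c_js).
supra_modularity_matrix <- function(net) {
  n <- net$n_nodes
  T_ <- net$n_layers
  B <- matrix(0, n * T_, n * T_)
  total_strength <- 0
  for (s in seq_len(T_)) {
    idx <- ((s - 1L) * n + 1L):(s * n)
    A <- net$layers[[s]]
    B[idx, idx] <- modularity_matrix(A, net$gamma[s])
    total_strength <- total_strength + sum(A)
  }
  total_coupling <- 0
  if (T_ > 1L) {
    for (s in seq_len(T_ - 1L)) {
      for (r in (s + 1L):T_) {
        om <- omega_for_pair(net$layer_conditions[s],
                             net$layer_conditions[r],
                             net$omega_same, net$omega_diff)
        if (om > 0) {
          is_ <- ((s - 1L) * n + 1L):(s * n)
          ir_ <- ((r - 1L) * n + 1L):(r * n)
          B[cbind(is_, ir_)] <- om
          B[cbind(ir_, is_)] <- om
        }
        total_coupling <- total_coupling + 2 * n * om
      }
    }
  }
  list(B = B, two_mu = total_strength + total_coupling)
}

#' Multilayer modularity of a node-by-layer assignment
#'
#' Evaluates the multilayer quality `Q_ML = (1 / 2mu) * sum_ijsr
#' [(A_ijs - gamma_s V_ijs) delta_sr + delta_ij omega_sr] *
#' delta(g_is, g_jr)`, with the Newman-Girvan configuration null
#' `V_ijs = k_is k_js / 2 m_s` per slice and
#' `mu = (1/2) sum_js (k_js + c_js)` accumulating intra-layer strength
#' plus each node's interslice couplings.  With a single layer this
#' reduces exactly to the single-layer modularity.
#'
#' @param net a [multilayer_network()].
#' @param assignment node x layer matrix of module labels (labels are
#'   global across layers).
#' @return the quality value `Q_ML`.
#' @export
multilayer_quality <- function(net, assignment) {
  stopifnot(inherits(net, "multilayer_network"))
  if (!is.matrix(assignment) || nrow(assignment) != net$n_nodes ||
      ncol(assignment) != net$n_layers)
    stop("assignment must be a ", net$n_nodes, " x ", net$n_layers,
         " matrix")
  sm <- supra_modularity_matrix(net)
  g <- canonicalize_labels(as.vector(assignment))
  sum(sm$B * outer(g, g, "==")) / sm$two_mu
}

#' Generalized Louvain for multilayer networks
#'
#' Greedy two-phase optimization over the supra-graph whose nodes are
#' (node, layer) pairs: intra-layer edges carry `A_ijs - gamma_s V_ijs`
#' and interlayer edges carry `omega_sr` on node identities.  Module
#' labels are global across layers, so a node's assignment can persist or
#' change between blocks depending on the coupling strength.
#'
#' @inheritParams multilayer_quality
#' @param seed integer seed controlling the randomized sweep order.
#' @return object of class `multilayer_partition`: list with `assignment`
#'   (node x layer integer matrix), `Q` (consistent with
#'   [multilayer_quality()]), and `seed`.
#' @export
generalized_louvain <- function(net, seed = 1L) {
  stopifnot(inherits(net, "multilayer_network"))
  sm <- supra_modularity_matrix(net)
  g <- with_seed(seed, {
    init <- sample.int(nrow(sm$B), nrow(sm$B), replace = TRUE)
    greedy_partition(sm$B, init = init)
  })
  Q <- sum(sm$B * outer(g, g, "==")) / sm$two_mu
  assignment <- matrix(g, net$n_nodes, net$n_layers,
                       dimnames = list(net$roi_ids, NULL))
  structure(list(assignment = assignment, Q = Q, seed = seed),
            class = "multilayer_partition")
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat("Multilayer partition:", nrow(x$assignment), "nodes x",
      ncol(x$assignment), "layers; Q_ML =", signif(x$Q, 5),
      "; modules:", length(unique(as.vector(x$assignment))), "\n")
  invisible(x)
}

#' Ensemble of multilayer optimizations
#'
#' Runs [generalized_louvain()] `n_opt` times with seeds derived from a
#' master seed and keeps every partition.  The whole ensemble — not just
#' the best member — feeds the module-allegiance average, since allegiance
#' is defined over repeated optimizations.
#'
#' @inheritParams generalized_louvain
#' @param n_opt number of optimizations (default 100).
#' @return list of `multilayer_partition` objects, with class
#'   `multilayer_ensemble`.
#' @export
run_ensemble <- function(net, n_opt = 100L, seed = 1L) {
  check_count(n_opt, "n_opt")
  seeds <- derive_seeds(seed, n_opt)
  out <- lapply(seeds, function(s) generalized_louvain(net, seed = s))
  class(out) <- "multilayer_ensemble"
  out
}

#' Write a node-by-layer assignment matrix as delimited text
#'
#' @param partition a `multilayer_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(partition, path) {
  stopifnot(inherits(partition, "multilayer_partition"))
  m <- partition$assignment
  df <- data.frame(roi_id = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("roi_id", paste0("layer_", seq_len(ncol(m))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
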