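# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive quantities by brute force (explicit loops,
# exhaustive enumeration) so they share no code with the implementation.

# All set partitions of n elements as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, max_label) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (lab in seq_len(max_label + 1L))
      grow(c(labels, lab), max(max_label, lab))
    invisible(NULL)
  }
  grow(integer(0), 0L)
  out
}

# Direct double-summation evaluation of single-layer modularity.
modularity_direct <- function(A, partition, gamma = 1) {
  n <- nrow(A)
  two_m <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (partition[i] == partition[j])
        q <- q + A[i, j] - gamma * k[i] * k[j] / two_m
    }
  }
  q / two_m
}

# Exhaustive maximum modularity over every partition (n <= 8 graphs).
exhaustive_max_modularity <- function(A, gamma = 1) {
  best <- -Inf
  for (p in all_partitions(nrow(A))) {
    q <- modularity_direct(A, p, gamma)
    if (q > best) best <- q
  }
  best
}

# Brute-force multilayer quality: explicit sum over i, j, s, r following
# the quality function term by term (intra-layer modularity term on
# delta_sr, interslice coupling on delta_ij), with
# mu = (1/2) sum_js (k_js + c_js).
multilayer_quality_direct <- function(layers, conditions, assignment,
                                      gamma = 1, omega_same = 1,
                                      omega_diff = 0.5) {
  n <- nrow(layers[[1L]])
  T_ <- length(layers)
  ks <- lapply(layers, rowSums)
  ms <- vapply(layers, function(A) sum(A) / 2, numeric(1))
  total <- 0
  for (s in seq_len(T_)) {
    for (r in seq_len(T_)) {
      om <- if (conditions[s] == conditions[r]) omega_same else omega_diff
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (assignment[i, s] != assignment[j, r]) next
          if (s == r)
            total <- total + layers[[s]][i, j] -
              gamma * ks[[s]][i] * ks[[s]][j] / (2 * ms[s])
          if (i == j && s != r) total <- total + om
        }
      }
    }
  }
  c_per_node <- vapply(seq_len(T_), function(s) {
    sum(vapply(seq_len(T_), function(r) {
      if (r == s) 0
      else if (conditions[s] == conditions[r]) omega_same else omega_diff
    }, numeric(1)))
  }, numeric(1))
  two_mu <- sum(vapply(seq_len(T_), function(s) {
    sum(ks[[s]]) + n * c_per_node[s]
  }, numeric(1)))
  total / two_mu
}

# Random symmetric weighted graph with zero diagonal and no isolated node.
random_weighted_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    ut <- which(upper.tri(A))
    on <- ut[runif(length(ut)) < density]
    A[on] <- runif(length(on), 0.1, 1)
    A <- A + t(A)
    if (all(rowSums(A) > 0)) return(A)
  }
}

# Four-system atlas over n nodes (n divisible by 4).
atlas4 <- function(n = 60) {
  system_atlas(rep(paste0("system_", 1:4), each = n / 4))
}

# Scenario in which system_4 keeps its module on odd blocks but its two
# halves merge into the modules of system_1 / system_2 on even blocks.
split_system_scenario <- function(seed, n = 60, rho_within = 0.6,
                                  rho_between = 0.05) {
  atlas <- atlas4(n)
  base <- as.integer(factor(atlas$system))
  split <- base
  s4 <- which(atlas$system == "system_4")
  half <- length(s4) %/% 2
  split[s4[seq_len(half)]] <- base[which(atlas$system == "system_1")[1L]]
  split[s4[(half + 1L):length(s4)]] <-
    base[which(atlas$system == "system_2")[1L]]
  parts <- lapply(seq_len(20L), function(b) if (b %% 2 == 0) split else base)
  scenario_spec(n, atlas, planted_partitions = parts,
                rho_within = rho_within, rho_between = rho_between,
                seed = seed)
}
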