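#' Planted block covariance matrix
#'
#' Builds the compound-symmetric-by-module covariance that defines the
#' ground-truth community structure of a synthetic block: unit variances,
#' correlation `rho_within` between nodes sharing a module and
#' `rho_between` otherwise.  With `0 <= rho_between <= rho_within < 1` the
#' matrix is positive semidefinite (it is a convex combination of the
#' identity, the all-ones matrix and the module block indicator).
#'
#' @param partition vector of module labels, one per node.
#' @param rho_within correlation within a module, in `[0, 1)`.
#' @param rho_between correlation between modules, in `[0, rho_within]`.
#' @return node x node covariance (here also correlation) matrix.
#' @examples
#' S <- planted_covariance(rep(1:2, each = 3), 0.5, 0.1)
#' min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
#' @export
planted_covariance <- function(partition, rho_within, rho_between) {
  if (!is.numeric(rho_within) || !is.numeric(rho_between))
    stop("correlations must be numeric")
  if (rho_within >= 1) stop("'rho_within' must be < 1 (PSD not guaranteed)")
  if (rho_between < 0 || rho_between > rho_within)
    stop("'rho_between' must lie in [0, rho_within]")
  g <- canonicalize_labels(partition)
  same <- outer(g, g, "==")
  S <- matrix(rho_between, length(g), length(g))
  S[same] <- rho_within
  diag(S) <- 1
  S
}

#' Synthetic study scenario specification
#'
#' Describes one synthetic scanning session: a block design of alternating
#' task conditions with, per block, a planted modular covariance.  The
#' defaults emulate the block structure of a dual n-back session: 20
#' alternating 1-back/2-back blocks, each 30 s long sampled at TR = 2 s
#' (15 volumes per block).
#'
#' @param n_nodes number of ROIs.
#' @param atlas optional `system_atlas` (defaults to a single-partition
#'   atlas derived from `planted_partitions`' first block).
#' @param n_blocks number of task blocks (default 20).
#' @param samples_per_block volumes per block (default 15).
#' @param condition_sequence condition label per block; default strict
#'   alternation of `"1-back"` / `"2-back"`.
#' @param planted_partitions either one node-to-module label vector (used
#'   for every block) or a list of length `n_blocks` of such vectors.
#'   Defaults to the atlas system labels.
#' @param rho_within,rho_between within- / between-module correlation;
#'   must satisfy `0 <= rho_between <= rho_within < 1`.
#' @param noise_sd standard deviation of independent additive Gaussian
#'   noise (default 1).
#' @param tr_seconds repetition time (default 2 s).
#' @param smear_hrf if `TRUE`, the latent signal is convolved with the
#'   canonical HRF so block boundaries bleed into one another, giving the
#'   HRF-weighting stage in the connectivity module something to correct.
#'   Default `FALSE` (clean block boundaries).
#' @param seed master seed; per-block sampling streams are derived from it
#'   deterministically.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_nodes, atlas = NULL, n_blocks = 20L,
                          samples_per_block = 15L,
                          condition_sequence = NULL,
                          planted_partitions = NULL,
                          rho_within = 0.6, rho_between = 0.05,
                          noise_sd = 1, tr_seconds = 2,
                          smear_hrf = FALSE, seed = 1L) {
  check_count(n_nodes, "n_nodes")
  check_count(n_blocks, "n_blocks")
  check_count(samples_per_block, "samples_per_block")
  if (rho_within >= 1 || rho_between < 0 || rho_between > rho_within)
    stop("need 0 <= rho_between <= rho_within < 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is.null(condition_sequence))
    condition_sequence <- rep(c("1-back", "2-back"),
                              length.out = n_blocks)
  if (length(condition_sequence) != n_blocks)
    stop("'condition_sequence' length (", length(condition_sequence),
         ") must equal n_blocks (", n_blocks, ")")
  if (is.null(planted_partitions)) {
    if (is.null(atlas))
      stop("supply 'atlas' or 'planted_partitions'")
    planted_partitions <- atlas$system
  }
  if (!is.list(planted_partitions))
    planted_partitions <- rep(list(planted_partitions), n_blocks)
  if (length(planted_partitions) != n_blocks)
    stop("'planted_partitions' must have one partition per block")
  for (p in planted_partitions)
    if (length(p) != n_nodes)
      stop("each planted partition must have length n_nodes")
  if (is.null(atlas))
    atlas <- system_atlas(as.character(planted_partitions[[1L]]))
  if (nrow(atlas) != n_nodes)
    stop("atlas has ", nrow(atlas), " ROIs but n_nodes = ", n_nodes)
  structure(
    list(n_nodes = as.integer(n_nodes), atlas = atlas,
         n_blocks = as.integer(n_blocks),
         samples_per_block = as.integer(samples_per_block),
         condition_sequence = as.character(condition_sequence),
         planted_partitions = planted_partitions,
         rho_within = rho_within, rho_between = rho_between,
         noise_sd = noise_sd, tr_seconds = tr_seconds,
         smear_hrf = isTRUE(smear_hrf), seed = as.integer(seed)),
    class = "scenario_spec")
}

#' Generate a synthetic ROI time-series panel
#'
#' Draws, block by block, zero-mean multivariate Gaussian samples with the
#' block's planted covariance, adds independent Gaussian noise of sd
#' `noise_sd`, and annotates every volume with its block index and
#' condition.  Sampling is reproducible: each block gets its own RNG
#' stream derived from the scenario's master seed.
#'
#' @param spec a `scenario_spec`.
#' @return a [time_series_panel()] with `spec$n_blocks * spec$samples_per_block`
#'   volumes.  The spec's planted partitions are attached as attribute
#'   `"planted_partitions"` for downstream ground-truth checks.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_nodes
  spb <- spec$samples_per_block
  block_seeds <- derive_seeds(spec$seed, spec$n_blocks + 1L)
  blocks <- vector("list", spec$n_blocks)
  for (b in seq_len(spec$n_blocks)) {
    S <- planted_covariance(spec$planted_partitions[[b]],
                            spec$rho_within, spec$rho_between)
    L <- chol(S)  # admissible rhos make S strictly PD
    blocks[[b]] <- with_seed(block_seeds[b], {
      z <- matrix(rnorm(n * spb), n, spb)
      crossprod(L, z)
    })
  }
  signal <- do.call(cbind, blocks)
  if (spec$smear_hrf) {
    hrf <- canonical_hrf(spec$tr_seconds)
    signal <- t(apply(signal, 1L, function(row) {
      convolve(row, rev(hrf$values), type = "open")[seq_along(row)]
    }))
  }
  if (spec$noise_sd > 0) {
    signal <- signal + with_seed(block_seeds[spec$n_blocks + 1L],
      matrix(rnorm(length(signal), sd = spec$noise_sd),
             nrow(signal), ncol(signal)))
  }
  n_vol <- spec$n_blocks * spb
  ann <- data.frame(
    volume = seq_len(n_vol),
    block = rep(seq_len(spec$n_blocks), each = spb),
    condition = rep(spec$condition_sequence, each = spb),
    stringsAsFactors = FALSE)
  panel <- time_series_panel(signal, spec$tr_seconds, ann,
                             spec$atlas$roi_id)
  attr(panel, "planted_partitions") <- spec$planted_partitions
  panel
}

#' Trial-outcome specification and sampler
#'
#' `trial_spec` describes one cell of an n-back session (one subject,
#' session, condition and stimulus modality): the number of target and
#' non-target trials and the probabilities of a hit and of a false alarm.
#' `generate_trials` draws the four response categories binomially:
#' hits ~ Binomial(n_targets, hit_prob), misses are the remainder;
#' false alarms ~ Binomial(n_nontargets, fa_prob), correct rejections the
#' remainder.
#'
#' @param n_targets,n_nontargets trial counts (>= 1).
#' @param hit_prob,fa_prob probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return `trial_spec` returns a `trial_spec` object; `generate_trials` a
#'   one-row data.frame with columns `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`.
#' @export
trial_spec <- function(n_targets, n_nontargets, hit_prob, fa_prob,
                       seed = 1L) {
  check_count(n_targets, "n_targets")
  check_count(n_nontargets, "n_nontargets")
  check_probability(hit_prob, "hit_prob")
  check_probability(fa_prob, "fa_prob")
  structure(
    list(n_targets = as.integer(n_targets),
         n_nontargets = as.integer(n_nontargets),
         hit_prob = hit_prob, fa_prob = fa_prob, seed = as.integer(seed)),
    class = "trial_spec")
}

#' @rdname trial_spec
#' @param spec a `trial_spec`.
#' @export
generate_trials <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  with_seed(spec$seed, {
    hits <- rbinom(1L, spec$n_targets, spec$hit_prob)
    fas <- rbinom(1L, spec$n_nontargets, spec$fa_prob)
    data.frame(hits = hits, misses = spec$n_targets - hits,
               false_alarms = fas,
               correct_rejections = spec$n_nontargets - fas)
  })
}

#' Simulate a full study trial table
#'
#' Generates a trial-outcome table over subjects x sessions x conditions x
#' modalities, with hit probabilities improving linearly across sessions
#' (emulating training gains) and constant false-alarm probability.  Each
#' cell's counts come from [generate_trials()] with a derived seed.
#'
#' @param n_subjects number of subjects.
#' @param sessions session labels in chronological order.
#' @param conditions condition labels.
#' @param modalities stimulus modality labels.
#' @param n_targets,n_nontargets trials per cell; the defaults follow a
#'   session of 20 blocks x 12 trials with 25% targets (60 targets, 180
#'   non-targets).
#' @param hit_start,hit_end hit probability at the first and last session
#'   (linear interpolation between them).
#' @param fa_prob false-alarm probability (constant).
#' @param group group label stamped on every row.
#' @param seed master seed.
#' @return a trial table data.frame with key columns `subject`, `session`,
#'   `condition`, `modality`, `group` and count columns as in
#'   [generate_trials()].
#' @export
simulate_trial_table <- function(n_subjects = 20L,
                                 sessions = c("Naive", "Early", "Middle", "Late"),
                                 conditions = c("1-back", "2-back"),
                                 modalities = c("auditory", "visuospatial"),
                                 n_targets = 60L, n_nontargets = 180L,
                                 hit_start = 0.7, hit_end = 0.9,
                                 fa_prob = 0.05, group = "experimental",
                                 seed = 1L) {
  check_count(n_subjects, "n_subjects")
  grid <- expand.grid(modality = modalities, condition = conditions,
                      session = sessions, subject = seq_len(n_subjects),
                      stringsAsFactors = FALSE)
  hit_probs <- seq(hit_start, hit_end, length.out = length(sessions))
  names(hit_probs) <- sessions
  seeds <- derive_seeds(seed, nrow(grid))
  counts <- lapply(seq_len(nrow(grid)), function(i) {
    generate_trials(trial_spec(n_targets, n_nontargets,
                               hit_probs[[grid$session[i]]], fa_prob,
                               seed = seeds[i]))
  })
  out <- cbind(
    data.frame(subject = paste0("sub_", grid$subject),
               group = group, session = grid$session,
               condition = grid$condition, modality = grid$modality,
               stringsAsFactors = FALSE),
    do.call(rbind, counts))
  out
}

#' Write the ground-truth partitions of a scenario as delimited text
#'
#' One tab-separated file with columns `roi_id`, then one column per block
#' (`block_1`, ...) holding the planted module label of each ROI.
#'
#' @param spec a `scenario_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_planted_partitions <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- do.call(cbind, lapply(spec$planted_partitions, canonicalize_labels))
  colnames(m) <- paste0("block_", seq_len(spec$n_blocks))
  df <- data.frame(roi_id = spec$atlas$roi_id, m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
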