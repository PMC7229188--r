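#' Canonical double-gamma HRF kernel
#'
#' Samples a canonical hemodynamic response function — a gamma density
#' peaking ~5-6 s after stimulus minus a scaled, later gamma undershoot —
#' at the panel's TR.  Used to weight task volumes so that correlations
#' reflect the hemodynamically effective part of each block.
#'
#' @param tr_seconds sampling interval (TR), > 0.
#' @param peak_s shape of the response gamma (time-to-peak scale), s.
#' @param undershoot_s shape of the undershoot gamma, s.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length_s kernel support in seconds; values beyond it are 0.
#' @return object of class `hrf_kernel`: list with `values` (samples at
#'   `0, tr, 2 tr, ...` within the support, scaled to max 1), `times`, and
#'   the parameter record.
#' @examples
#' h <- canonical_hrf(2)
#' h$times[which.max(h$values)]  # peak a few seconds after onset
#' @export
canonical_hrf <- function(tr_seconds, peak_s = 6, undershoot_s = 16,
                          ratio = 6, length_s = 32) {
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("'tr_seconds' must be positive")
  times <- seq(0, length_s, by = tr_seconds)
  values <- dgamma(times, shape = peak_s, rate = 1) -
    dgamma(times, shape = undershoot_s, rate = 1) / ratio
  values <- values / max(values)
  structure(
    list(values = values, times = times,
         params = list(tr_seconds = tr_seconds, peak_s = peak_s,
                       undershoot_s = undershoot_s, ratio = ratio,
                       length_s = length_s)),
    class = "hrf_kernel")
}

#' @export
print.hrf_kernel <- function(x, ...) {
  cat("Double-gamma HRF kernel:", length(x$values), "samples at TR =",
      x$params$tr_seconds, "s; peak at t =",
      x$times[which.max(x$values)], "s\n")
  invisible(x)
}

#' HRF-convolved block weights
#'
#' Convolves a 0/1 block regressor with the HRF kernel, truncates to the
#' regressor's length and rectifies (negative values, e.g. the
#' post-block undershoot, are set to zero).  The result is the per-volume
#' weight vector used by the weighted correlation.
#'
#' @param block_regressor per-volume 0/1 vector marking task volumes.
#' @param hrf an [canonical_hrf()] kernel.
#' @return nonnegative weight vector of the same length.
#' @export
hrf_weights <- function(block_regressor, hrf) {
  stopifnot(inherits(hrf, "hrf_kernel"))
  n <- length(block_regressor)
  if (n < 1L) stop("empty regressor")
  conv <- convolve(block_regressor, rev(hrf$values), type = "open")[seq_len(n)]
  pmax(conv, 0)
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with per-observation nonnegative weights: weighted
#' means, weighted central moments, their normalized cross-product.
#' Reduces to the ordinary Pearson correlation under uniform weights and
#' is invariant to positive rescaling of the weight vector.
#'
#' @param x,y numeric vectors of equal length.
#' @param w nonnegative weights, same length, with positive total mass.
#' @return correlation in `[-1, 1]`.
#' @export
weighted_pearson <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w))
    stop("x, y and w must have equal lengths")
  if (any(w < 0)) stop("weights must be nonnegative")
  sw <- sum(w)
  if (sw <= 0) stop("zero weight mass")
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  cxy <- sum(w * (x - mx) * (y - my)) / sw
  r <- cxy / sqrt(vx * vy)
  min(1, max(-1, r))
}

# Weighted correlation matrix across the rows of X (ROI x volume), with
# explicit zero-variance reporting by ROI id.
weighted_corr_matrix <- function(X, w, roi_ids = rownames(X)) {
  sw <- sum(w)
  if (sw <= 0) stop("zero weight mass")
  mu <- as.vector(X %*% w) / sw
  Xc <- X - mu
  C <- (Xc * rep(w, each = nrow(X))) %*% t(Xc) / sw
  v <- diag(C)
  bad <- which(v <= 0)
  if (length(bad))
    stop("zero weighted variance for ROI(s): ",
         paste(roi_ids[bad], collapse = ", "))
  R <- C / sqrt(outer(v, v))
  R[R > 1] <- 1
  R[R < -1] <- -1
  R
}

# correlate -> Fisher transform -> rectify negatives -> zero diagonal.
# Correlations are capped just below |1| so Fisher z stays finite for
# numerically perfect correlations (e.g. duplicated ROI rows).
fisher_rectify <- function(R, rectify = TRUE, r_cap = 1 - 1e-12) {
  R[R > r_cap] <- r_cap
  R[R < -r_cap] <- -r_cap
  Z <- atanh(R)
  if (rectify) Z[Z < 0] <- 0
  diag(Z) <- 0
  Z <- (Z + t(Z)) / 2
  Z
}

new_connectivity_matrix <- function(weights, kind, roi_ids,
                                    condition = NA_character_,
                                    block = NA_integer_,
                                    session = NA_character_) {
  dimnames(weights) <- list(roi_ids, roi_ids)
  structure(weights, class = c("connectivity_matrix", "matrix"),
            kind = kind, condition = condition, block = block,
            session = session)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Connectivity matrix (", attr(x, "kind"), "): ", nrow(x), " x ",
      ncol(x), " ROIs", sep = "")
  if (!is.na(attr(x, "condition")))
    cat(", condition ", attr(x, "condition"), sep = "")
  if (!is.na(attr(x, "block"))) cat(", block ", attr(x, "block"), sep = "")
  cat("; mean weight ", signif(mean(x[upper.tri(x)]), 4), "\n", sep = "")
  invisible(x)
}

#' Condition-level weighted functional connectivity
#'
#' For every ROI pair, computes the HRF-weighted Pearson correlation over
#' the volumes of one task condition (or of all task blocks when
#' `condition = NULL`), Fisher z-transforms it and retains only positive
#' weights.  The per-volume weights are the block regressor of the chosen
#' condition convolved with the HRF and rectified; volumes with zero
#' weight do not contribute.
#'
#' @param panel a [time_series_panel()].
#' @param condition condition label to select, or `NULL` for all blocks.
#' @param hrf HRF kernel; default [canonical_hrf()] at the panel's TR.
#' @param rectify set negative Fisher-z weights to zero (default `TRUE`).
#' @return a `connectivity_matrix` (symmetric, zero diagonal, nonnegative
#'   when rectified).
#' @export
condition_connectivity <- function(panel, condition = NULL, hrf = NULL,
                                   rectify = TRUE) {
  stopifnot(inherits(panel, "ts_panel"))
  if (is.null(hrf)) hrf <- canonical_hrf(panel$tr_seconds)
  ann <- panel$annotations
  if (is.null(condition)) {
    mask <- !is.na(ann$block)
    cond_label <- "all-task"
  } else {
    mask <- ann$condition == condition
    if (!any(mask)) stop("condition not present in panel: ", condition)
    cond_label <- condition
  }
  regressor <- as.numeric(mask)
  w <- hrf_weights(regressor, hrf)
  usable <- mask & w > 0
  if (sum(usable) < 3L)
    stop("fewer than 3 usable volumes for condition ", cond_label)
  R <- weighted_corr_matrix(panel$signal[, usable, drop = FALSE],
                            w[usable], panel$roi_ids)
  Z <- fisher_rectify(R, rectify = rectify)
  new_connectivity_matrix(Z, "condition", panel$roi_ids,
                          condition = cond_label)
}

#' Block-wise weighted functional connectivity stack
#'
#' One connectivity matrix per task block: the block's own boxcar
#' regressor is convolved with the HRF (weights recomputed per block),
#' and the weighted correlation is taken over that block's positive-weight
#' volumes.  The resulting stack of matrices, ordered by block, is the
#' multilayer network's layer sequence.
#'
#' @inheritParams condition_connectivity
#' @return object of class `connectivity_stack`: list with `matrices`
#'   (list of `connectivity_matrix`, one per block), `conditions` (label
#'   per block) and `roi_ids`.
#' @export
block_connectivity <- function(panel, hrf = NULL, rectify = TRUE) {
  stopifnot(inherits(panel, "ts_panel"))
  if (is.null(hrf)) hrf <- canonical_hrf(panel$tr_seconds)
  ann <- panel$annotations
  blocks <- sort(unique(ann$block))
  mats <- vector("list", length(blocks))
  conds <- character(length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[i]
    mask <- ann$block == b
    conds[i] <- ann$condition[mask][1L]
    w <- hrf_weights(as.numeric(mask), hrf)
    usable <- mask & w > 0
    if (sum(usable) < 3L)
      stop("block ", b, " has fewer than 3 usable volumes")
    R <- weighted_corr_matrix(panel$signal[, usable, drop = FALSE],
                              w[usable], panel$roi_ids)
    Z <- fisher_rectify(R, rectify = rectify)
    mats[[i]] <- new_connectivity_matrix(Z, "block", panel$roi_ids,
                                         condition = conds[i],
                                         block = as.integer(b))
  }
  structure(list(matrices = mats, conditions = conds,
                 blocks = as.integer(blocks), roi_ids = panel$roi_ids),
            class = "connectivity_stack")
}

#' @export
print.connectivity_stack <- function(x, ...) {
  cat("Connectivity stack:", length(x$matrices), "block matrices,",
      length(x$roi_ids), "ROIs\n")
  cat("Conditions:", paste(unique(x$conditions), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a connectivity matrix as delimited text
#'
#' Tab-separated square matrix with ROI ids as header and first column.
#'
#' @param mat a `connectivity_matrix` (or plain matrix) to write.
#' @param path file path.
#' @return `write_connectivity` returns `path` invisibly;
#'   `read_connectivity` a `connectivity_matrix`.
#' @export
write_connectivity <- function(mat, path) {
  df <- data.frame(roi_id = rownames(mat), unclass(mat),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  if (!file.exists(path)) stop("connectivity file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df$roi_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  new_connectivity_matrix(m, "condition", ids)
}
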