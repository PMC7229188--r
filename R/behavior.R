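#' Signal-detection rates from trial counts
#'
#' `hit_rate` is the fraction of target trials answered with a button
#' press, `false_alarm_rate` the fraction of non-target trials answered
#' with one.
#'
#' @param hits,misses,false_alarms,correct_rejections nonnegative counts.
#' @return a rate in `[0, 1]`.
#' @examples
#' hit_rate(3, 1)  # 0.75
#' @export
hit_rate <- function(hits, misses) {
  if (any(hits < 0) || any(misses < 0)) stop("counts must be nonnegative")
  denom <- hits + misses
  if (any(denom < 1)) stop("hits + misses must be >= 1")
  hits / denom
}

#' @rdname hit_rate
#' @export
false_alarm_rate <- function(false_alarms, correct_rejections) {
  if (any(false_alarms < 0) || any(correct_rejections < 0))
    stop("counts must be nonnegative")
  denom <- false_alarms + correct_rejections
  if (any(denom < 1)) stop("false_alarms + correct_rejections must be >= 1")
  false_alarms / denom
}

#' Clamp extreme rates for finite d-prime
#'
#' The inverse-normal transform diverges at 0 and 1, so a rate of exactly
#' 0 is replaced by 0.01 and a rate of exactly 1 by 0.99; every interior
#' value passes through unchanged.  The clamp is idempotent.
#'
#' @param rate numeric vector of rates in `[0, 1]`.
#' @return clamped rates in `[0.01, 0.99]` (interior values untouched).
#' @export
clamp_rate <- function(rate) {
  if (any(is.na(rate)) || any(rate < 0) || any(rate > 1))
    stop("rates must lie in [0, 1]")
  rate[rate == 0] <- 0.01
  rate[rate == 1] <- 0.99
  rate
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = Z(H) - Z(F)` where `Z` is the inverse of the cumulative standard
#' Gaussian, `H` the hit rate and `F` the false-alarm rate.  Rates must
#' already be clamped away from 0 and 1 (see [clamp_rate()]).
#'
#' @param H,F rates strictly inside `(0, 1)`.
#' @return numeric d-prime value(s).
#' @examples
#' dprime(0.99, 0.01)  # ~4.653, the ceiling under 0.01/0.99 clamping
#' @export
dprime <- function(H, F) {
  if (any(H <= 0) || any(H >= 1) || any(F <= 0) || any(F >= 1))
    stop("rates must lie strictly in (0, 1); clamp first (clamp_rate)")
  qnorm(H) - qnorm(F)
}

#' Per-subject d-prime from a trial table
#'
#' Computes d-prime per (subject, session, condition, modality) row via
#' [hit_rate()], [false_alarm_rate()], [clamp_rate()] and [dprime()], then
#' averages over the two stimulus modalities to give one cumulative
#' sensitivity per subject x session x condition.
#'
#' @param table a trial table: data.frame with columns `subject`,
#'   `session`, `condition`, `modality`, `hits`, `misses`, `false_alarms`,
#'   `correct_rejections` (extra columns such as `group` are carried
#'   through).
#' @param modalities the two modality labels expected in every cell.
#' @return data.frame with one row per (subject, session, condition):
#'   carried grouping columns, per-modality d-primes (`dprime_<modality>`),
#'   and their mean in `dprime`.
#' @export
subject_dprime <- function(table,
                           modalities = c("auditory", "visuospatial")) {
  needed <- c("subject", "session", "condition", "modality",
              "hits", "misses", "false_alarms", "correct_rejections")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  H <- clamp_rate(hit_rate(table$hits, table$misses))
  F <- clamp_rate(false_alarm_rate(table$false_alarms,
                                   table$correct_rejections))
  table$H <- H
  table$F <- F
  table$dprime <- dprime(H, F)
  key_cols <- intersect(c("subject", "group", "session", "condition"),
                        names(table))
  key <- interaction(table[key_cols], drop = TRUE, lex.order = TRUE)
  pieces <- split(table, key)
  rows <- lapply(pieces, function(cell) {
    idx <- match(modalities, cell$modality)
    if (anyNA(idx)) {
      missing_mod <- modalities[is.na(idx)]
      stop("missing modality '", paste(missing_mod, collapse = "', '"),
           "' for subject=", cell$subject[1L], " session=",
           cell$session[1L], " condition=", cell$condition[1L])
    }
    out <- cell[1L, key_cols, drop = FALSE]
    dp <- cell$dprime[idx]
    for (m in seq_along(modalities))
      out[[paste0("dprime_", modalities[m])]] <- dp[m]
    out$dprime <- mean(dp)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Percent change between two values
#'
#' `100 * (after - before) / before`; the baseline must be nonzero.
#'
#' @param before,after numeric values.
#' @return percent change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("zero baseline: percent change undefined")
  100 * (after - before) / before
}

#' Cross-session d-prime change
#'
#' Summarizes training gains per condition (and group, if present) from a
#' [subject_dprime()] result.  Two aggregations are available because a
#' group-level "percent improvement" can be read two ways: percent change
#' of the group-mean d-prime (`"change_of_means"`, the default) or the
#' mean of per-subject percent changes (`"mean_of_changes"`).
#'
#' @param dtable output of [subject_dprime()].
#' @param from,to session labels for the baseline and the endpoint.
#' @param aggregate aggregation mode, see Details.
#' @return data.frame with one row per condition (x group): mean d-prime
#'   at both sessions, mean per-subject change `delta`, and
#'   `pct_improvement` under the chosen aggregation.
#' @export
dprime_change <- function(dtable, from = "Naive", to = "Late",
                          aggregate = c("change_of_means",
                                        "mean_of_changes")) {
  aggregate <- match.arg(aggregate)
  if (!all(c(from, to) %in% dtable$session))
    stop("sessions '", from, "' and '", to, "' must both be present")
  key_cols <- intersect(c("group", "condition"), names(dtable))
  before <- dtable[dtable$session == from, , drop = FALSE]
  after <- dtable[dtable$session == to, , drop = FALSE]
  merged <- merge(before, after,
                  by = c(key_cols, "subject"), suffixes = c("_before", "_after"))
  key <- interaction(merged[key_cols], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(merged, key), function(cell) {
    out <- cell[1L, key_cols, drop = FALSE]
    out$n <- nrow(cell)
    out$mean_before <- mean(cell$dprime_before)
    out$mean_after <- mean(cell$dprime_after)
    out$delta <- mean(cell$dprime_after - cell$dprime_before)
    out$pct_improvement <- switch(aggregate,
      change_of_means = percent_change(out$mean_before, out$mean_after),
      mean_of_changes = mean(percent_change(cell$dprime_before,
                                            cell$dprime_after)))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
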