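#' ROI time-series panel
#'
#' Container for a ROI-by-volume signal matrix with per-volume block and
#' condition annotations — the input to all connectivity estimation.
#'
#' @param signal numeric matrix, ROIs in rows, volumes in columns; no
#'   missing values.
#' @param tr_seconds repetition time of the acquisition, in seconds.
#' @param annotations data.frame with one row per volume and columns
#'   `volume` (1-based index), `block` (integer block index) and
#'   `condition` (condition label, e.g. `"1-back"`).
#' @param roi_ids ROI labels aligned to the rows of `signal`.
#' @return an object of class `ts_panel`.
#' @export
time_series_panel <- function(signal, tr_seconds, annotations,
                              roi_ids = rownames(signal)) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("'signal' must be a numeric matrix (ROI x volume)")
  if (anyNA(signal)) stop("'signal' contains missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0)
    stop("'tr_seconds' must be a positive number")
  if (!is.data.frame(annotations) ||
      !all(c("volume", "block", "condition") %in% names(annotations)))
    stop("'annotations' needs columns volume, block, condition")
  if (nrow(annotations) != ncol(signal))
    stop("annotation rows (", nrow(annotations),
         ") must equal number of volumes (", ncol(signal), ")")
  if (is.null(roi_ids)) roi_ids <- paste0("roi_", seq_len(nrow(signal)))
  if (length(roi_ids) != nrow(signal))
    stop("'roi_ids' must have one entry per ROI row")
  rownames(signal) <- roi_ids
  structure(
    list(signal = signal, tr_seconds = tr_seconds,
         annotations = annotations, roi_ids = as.character(roi_ids)),
    class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("ROI time-series panel:", nrow(x$signal), "ROIs x",
      ncol(x$signal), "volumes (TR =", x$tr_seconds, "s)\n")
  cat("Blocks:", length(unique(x$annotations$block)),
      " Conditions:", paste(unique(x$annotations$condition), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write / read a panel as delimited text
#'
#' The panel is stored as two tab-separated files sharing a path prefix:
#' `<prefix>_signal.tsv` (ROI rows x volume columns, with roi_id as the
#' first column) and `<prefix>_annotations.tsv` (volume, block, condition).
#'
#' @param panel a `ts_panel`.
#' @param prefix path prefix for the two output files.
#' @param tr_seconds TR to attach on read (not stored in the text files).
#' @return `write_panel` returns the two paths invisibly; `read_panel`
#'   returns a `ts_panel`.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "ts_panel"))
  sig_path <- paste0(prefix, "_signal.tsv")
  ann_path <- paste0(prefix, "_annotations.tsv")
  sig <- data.frame(roi_id = panel$roi_ids, panel$signal, check.names = FALSE)
  colnames(sig) <- c("roi_id", paste0("v", seq_len(ncol(panel$signal))))
  write.table(sig, sig_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$annotations, ann_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(signal = sig_path, annotations = ann_path))
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix, tr_seconds = 2) {
  sig_path <- paste0(prefix, "_signal.tsv")
  ann_path <- paste0(prefix, "_annotations.tsv")
  for (p in c(sig_path, ann_path))
    if (!file.exists(p)) stop("panel file not found: ", p)
  sig <- read.table(sig_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  ann <- read.table(ann_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  roi_ids <- as.character(sig$roi_id)
  mat <- as.matrix(sig[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  time_series_panel(mat, tr_seconds, ann, roi_ids)
}
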