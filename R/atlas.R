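#' System atlas: ROI to large-scale system mapping
#'
#' An atlas assigns every network node (ROI) to one large-scale system
#' (e.g. frontoparietal, default mode).  Cartography measures (recruitment,
#' integration) are averaged over these system blocks, and their
#' permutation null shuffles the ROI-to-system correspondence.  The 264-ROI
#' parcellation with 13 systems and the 300-ROI parcellation used for
#' robustness are both just instances of this table.
#'
#' @param systems character or factor vector of system labels, one per ROI,
#'   in node order.
#' @param roi_ids optional ROI identifiers (default `"roi_1"`, ...).
#' @return an object of class `system_atlas`: a data.frame with columns
#'   `roi_id` and `system`.
#' @examples
#' atlas <- system_atlas(rep(c("A", "B"), each = 3))
#' system_sizes(atlas)
#' @export
system_atlas <- function(systems, roi_ids = NULL) {
  systems <- as.character(systems)
  n <- length(systems)
  if (n < 2L) stop("an atlas needs at least 2 ROIs")
  if (anyNA(systems) || any(!nzchar(systems)))
    stop("every ROI must carry a non-empty system label")
  if (length(unique(systems)) < 2L)
    stop("an atlas needs at least 2 distinct systems")
  if (is.null(roi_ids)) roi_ids <- paste0("roi_", seq_len(n))
  if (length(roi_ids) != n) stop("roi_ids length must match systems length")
  out <- data.frame(roi_id = as.character(roi_ids), system = systems,
                    stringsAsFactors = FALSE)
  class(out) <- c("system_atlas", "data.frame")
  out
}

#' @rdname system_atlas
#' @param atlas a `system_atlas`.
#' @export
system_sizes <- function(atlas) {
  stopifnot(inherits(atlas, "system_atlas"))
  table(atlas$system)
}

#' Read / write an atlas as two-column delimited text
#'
#' The file format is tab-separated with header columns `roi_id` and
#' `system`, one row per ROI in node order.
#'
#' @param path file path.
#' @return `read_atlas` returns a `system_atlas`; `write_atlas` returns
#'   `path` invisibly.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (!all(c("roi_id", "system") %in% names(df)))
    stop("atlas file must have columns 'roi_id' and 'system': ", path)
  system_atlas(df$system, df$roi_id)
}

#' @rdname read_atlas
#' @param atlas a `system_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "system_atlas"))
  write.table(as.data.frame(atlas), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.system_atlas <- function(x, ...) {
  sz <- table(x$system)
  cat("System atlas:", nrow(x), "ROIs in", length(sz), "systems\n")
  print(sz)
  invisible(x)
}
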