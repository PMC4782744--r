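#' Labeled spectra dataset
#'
#' The central container of the pipeline: a matrix of normalized
#' intensities (channels in rows, measurement points in columns) on a
#' shared wavelength grid, with one diagnosis label per point and the
#' provenance (tooth id, point id) of each measurement. Labels are the
#' clinician's diagnosis, "healthy" or "carious"; "carious" is the
#' positive class throughout.
#'
#' Relabeling operations (see [apply_hypothesis_1()]) never overwrite
#' history: every label change is appended to `x$relabel_log` so the
#' original diagnoses stay recoverable.
#'
#' @param grid a [wavelength_grid()] (or plain numeric wavelengths).
#' @param intensities numeric matrix, `length(grid)` rows, one column per
#'   sample. All values must be finite. Normalized intensities may stray
#'   slightly outside `[0, 1]` because of noise; they are not clipped.
#' @param labels character or factor vector of per-sample diagnoses,
#'   values `"healthy"` or `"carious"`.
#' @param point_id,tooth_id optional identifier vectors; points default
#'   to `p1, p2, ...` (or the matrix column names), teeth to `"t?"`.
#' @return an object of class `"drs_dataset"`: a list with elements
#'   `grid`, `intensities`, `samples` (data frame with columns
#'   `point_id`, `tooth_id`, `label`) and `relabel_log`.
#' @export
drs_dataset <- function(grid, intensities, labels,
                        point_id = NULL, tooth_id = NULL) {
  grid <- as_grid(grid)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities) != length(grid)) {
    stop(sprintf("intensity matrix has %d rows but the grid has %d channels",
                 nrow(intensities), length(grid)), call. = FALSE)
  }
  n <- ncol(intensities)
  if (n < 1L) stop("a dataset needs at least one sample", call. = FALSE)
  if (any(!is.finite(intensities))) {
    stop("all intensities must be finite", call. = FALSE)
  }
  if (is.null(point_id)) {
    point_id <- colnames(intensities)
    if (is.null(point_id)) point_id <- paste0("p", seq_len(n))
  }
  point_id <- as.character(point_id)
  if (anyDuplicated(point_id)) {
    stop("point_id values must be unique", call. = FALSE)
  }
  if (is.null(tooth_id)) tooth_id <- rep("t?", n)
  labels <- as_label(labels, n)
  colnames(intensities) <- point_id
  structure(
    list(
      grid = grid,
      intensities = intensities,
      samples = data.frame(
        point_id = point_id,
        tooth_id = as.character(tooth_id),
        label = labels,
        stringsAsFactors = FALSE
      ),
      relabel_log = data.frame(
        point_id = character(), hypothesis = character(),
        old_label = character(), stringsAsFactors = FALSE
      )
    ),
    class = "drs_dataset"
  )
}

label_levels <- c("healthy", "carious")

as_label <- function(labels, n) {
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop(sprintf("%d labels for %d samples", length(labels), n), call. = FALSE)
  }
  bad <- setdiff(unique(labels), label_levels)
  if (length(bad)) {
    stop(sprintf("unknown label(s): %s (must be 'healthy' or 'carious')",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  factor(labels, levels = label_levels)
}

#' @export
print.drs_dataset <- function(x, ...) {
  tab <- table(x$samples$label)
  cat(sprintf(
    "<drs_dataset> %d samples (%d healthy, %d carious) x %d channels, %d teeth\n",
    nrow(x$samples), tab[["healthy"]], tab[["carious"]],
    length(x$grid), length(unique(x$samples$tooth_id))
  ))
  if (nrow(x$relabel_log)) {
    cat(sprintf("  relabel log: %d event(s)\n", nrow(x$relabel_log)))
  }
  invisible(x)
}

#' Subset a dataset by sample
#'
#' @param data a [drs_dataset()].
#' @param which logical, integer or character (point id) index of the
#'   samples to keep.
#' @return a `drs_dataset` with the selected samples; the relabel log is
#'   filtered to the surviving points.
#' @export
subset_samples <- function(data, which) {
  stopifnot(inherits(data, "drs_dataset"))
  if (is.character(which)) which <- match(which, data$samples$point_id)
  keep <- seq_len(nrow(data$samples))[which]
  if (!length(keep) || anyNA(keep)) {
    stop("sample subset is empty or names unknown", call. = FALSE)
  }
  out <- data
  out$intensities <- data$intensities[, keep, drop = FALSE]
  out$samples <- data$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out$relabel_log <- data$relabel_log[
    data$relabel_log$point_id %in% out$samples$point_id, , drop = FALSE]
  rownames(out$relabel_log) <- NULL
  out
}

#' @rdname drs_dataset
#' @param x a `drs_dataset`.
#' @export
sample_labels <- function(x) {
  stopifnot(inherits(x, "drs_dataset"))
  stats::setNames(x$samples$label, x$samples$point_id)
}

# intensities of one or more datasets/matrices as channels x samples
as_intensity_matrix <- function(x) {
  if (inherits(x, "drs_dataset")) {
    x$intensities
  } else if (is.matrix(x)) {
    x
  } else {
    matrix(as.numeric(x), ncol = 1L)
  }
}
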