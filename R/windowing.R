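#' Construct an ROI time-series object
#'
#' Bundles one subject's parcellated BOLD signal matrix (rows = regions of
#' interest, columns = timepoints) with its diagnostic label. Patients carry
#' label 1 and controls label 0; sensitivity/specificity downstream are fixed
#' to that convention.
#'
#' @param data Numeric matrix, `n_rois x n_timepoints`. All values must be
#'   finite.
#' @param subject_id Character scalar identifying the subject.
#' @param label Integer 0 (control) or 1 (patient).
#' @param tr_seconds Optional positive repetition time in seconds (metadata
#'   only; no resampling is performed).
#' @return An object of class `roi_time_series`.
#' @export
#' @examples
#' x <- roi_time_series(matrix(rnorm(40), 4, 10), "sub-01", label = 1)
#' dim(x$data)
roi_time_series <- function(data, subject_id, label, tr_seconds = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (nrow(data) < 2L) stop("need at least 2 ROIs")
  if (ncol(data) < 1L) stop("need at least 1 timepoint")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    stop("`subject_id` must be a single string")
  }
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || !label %in% c(0L, 1L)) {
    stop("`label` must be 0 or 1")
  }
  if (!is.null(tr_seconds)) {
    stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  }
  structure(
    list(subject_id = subject_id, data = data, label = label,
         tr_seconds = tr_seconds),
    class = "roi_time_series"
  )
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat(sprintf("<roi_time_series> %s: %d ROIs x %d timepoints, label %d\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$label))
  invisible(x)
}

#' Partition an ROI time series into non-overlapping windows
#'
#' Cuts the signal matrix into `T = floor(T_total / L)` contiguous,
#' non-overlapping segments of exactly `L` timepoints each, in temporal
#' order. A trailing remainder shorter than one window is discarded (and the
#' number of dropped timepoints reported via [message()] when `quiet = FALSE`).
#'
#' @param series A [roi_time_series()] object, or a bare numeric matrix
#'   (rows = ROIs).
#' @param window_length Positive integer window size `L`. The default of 20
#'   timepoints corresponds to the 30--60 s windows generally considered to
#'   give robust dynamic-connectivity estimates at typical repetition times.
#' @param quiet Suppress the dropped-timepoints message.
#' @return An object of class `segment_set`: a list with `segments` (list of
#'   `n_rois x L` matrices), `window_length`, and `origin` (subject id).
#' @export
#' @examples
#' x <- roi_time_series(matrix(rnorm(4 * 231), 4, 231), "s1", 0)
#' length(partition(x, 20)$segments)  # 11
partition <- function(series, window_length = 20L, quiet = TRUE) {
  if (is.matrix(series)) {
    series <- roi_time_series(series, "unnamed", 0L)
  }
  stopifnot(inherits(series, "roi_time_series"))
  window_length <- as.integer(window_length)
  if (length(window_length) != 1L || is.na(window_length) || window_length <= 0L) {
    stop("`window_length` must be a positive integer")
  }
  t_total <- ncol(series$data)
  if (t_total < window_length) stop("series shorter than one window")
  n_seg <- t_total %/% window_length
  dropped <- t_total - n_seg * window_length
  if (dropped > 0L && !quiet) {
    message(sprintf("partition: discarding %d trailing timepoint(s)", dropped))
  }
  segments <- lapply(seq_len(n_seg), function(t) {
    cols <- ((t - 1L) * window_length + 1L):(t * window_length)
    series$data[, cols, drop = FALSE]
  })
  structure(
    list(segments = segments, window_length = window_length,
         origin = series$subject_id),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %s: %d windows of length %d (%d ROIs)\n",
              x$origin, length(x$segments), x$window_length,
              nrow(x$segments[[1]])))
  invisible(x)
}

#' Read a cohort from per-subject TSV files and a manifest
#'
#' The manifest is a CSV with columns `subject_id`, `path`, `label` and
#' optionally `site` and `orientation`. Each referenced file is a delimited
#' text matrix with rows = ROIs and columns = timepoints; set
#' `orientation = "time_by_roi"` in the manifest row to have the loader
#' transpose a file stored the other way (the orientation is always declared,
#' never guessed from the shape).
#'
#' @param manifest_path Path to the manifest CSV.
#' @param base_dir Directory against which relative `path` entries are
#'   resolved; defaults to the manifest's directory.
#' @return A `roi_cohort`: list with `subjects` (list of
#'   [roi_time_series()]) and `manifest` (tibble).
#' @export
read_cohort <- function(manifest_path, base_dir = dirname(manifest_path)) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns subject_id, path, label")
  }
  subjects <- purrr::pmap(manifest, function(subject_id, path, label, ...) {
    dots <- list(...)
    full <- if (startsWith(path, "/")) path else file.path(base_dir, path)
    mat <- as.matrix(utils::read.table(full, sep = "\t", header = FALSE))
    dimnames(mat) <- NULL
    orientation <- dots$orientation %||% "roi_by_time"
    if (identical(orientation, "time_by_roi")) mat <- t(mat)
    roi_time_series(mat, subject_id, label)
  })
  new_roi_cohort(subjects, manifest)
}

#' Write a cohort as per-subject TSVs plus a manifest CSV
#'
#' Inverse of [read_cohort()]; the written layout round-trips exactly.
#'
#' @param cohort A `roi_cohort`.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "roi_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rel <- vapply(cohort$subjects, function(s) {
    fn <- paste0(s$subject_id, ".tsv")
    utils::write.table(s$data, file.path(dir, fn), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    fn
  }, character(1))
  manifest <- tibble::tibble(
    subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    path = rel,
    label = vapply(cohort$subjects, `[[`, integer(1), "label")
  )
  if ("site" %in% names(cohort$manifest)) manifest$site <- cohort$manifest$site
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp)
  invisible(mp)
}

new_roi_cohort <- function(subjects, manifest) {
  structure(list(subjects = subjects, manifest = tibble::as_tibble(manifest)),
            class = "roi_cohort")
}

#' @export
print.roi_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, `[[`, integer(1), "label")
  cat(sprintf("<roi_cohort> %d subjects (%d patients / %d controls), %d ROIs\n",
              length(x$subjects), sum(labs == 1L), sum(labs == 0L),
              nrow(x$subjects[[1]]$data)))
  invisible(x)
}

#' Cohort labels as an integer vector
#' @param cohort A `roi_cohort`.
#' @return Integer vector of 0/1 labels in subject order.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, `[[`, integer(1), "label")
}

#' Subset a cohort by subject index
#' @param cohort A `roi_cohort`.
#' @param idx Integer indices of the subjects to keep.
#' @return A `roi_cohort` with the selected subjects.
#' @export
cohort_subset <- function(cohort, idx) {
  new_roi_cohort(cohort$subjects[idx], cohort$manifest[idx, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
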