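VALID_LABELS <- c("NC", "ASD", "UNKNOWN")

normalize_label <- function(x, context = "label") {
  up <- toupper(trimws(as.character(x)))
  bad <- !(up %in% VALID_LABELS)
  if (any(bad)) {
    stop(sprintf(
      "%s: invalid label(s) %s; expected NC, ASD or UNKNOWN",
      context, paste(unique(x[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  up
}

#' Construct a subject's ROI time-series object
#'
#' Wraps one subject's ROI-averaged BOLD matrix (timepoints in rows,
#' regions in columns) together with its cohort metadata.
#'
#' @param data Numeric matrix, T timepoints by R regions; all entries
#'   finite, T >= 2, R >= 2.
#' @param subject_id,site_id Character scalars.
#' @param label One of `"NC"`, `"ASD"`, `"UNKNOWN"` (case-insensitive).
#' @return An object of class `roi_timeseries` with fields `data`,
#'   `subject_id`, `site_id`, `label`.
#' @export
roi_timeseries <- function(data, subject_id, site_id = "UNKNOWN",
                           label = "UNKNOWN") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L || ncol(data) < 2L) {
    stop("time series must have at least 2 timepoints and 2 regions",
         call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("time series contains missing or non-finite values", call. = FALSE)
  }
  structure(
    list(
      data = data,
      subject_id = as.character(subject_id),
      site_id = as.character(site_id),
      label = normalize_label(label)
    ),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf(
    "<roi_timeseries> subject %s  site %s  label %s  [%d timepoints x %d regions]\n",
    x$subject_id, x$site_id, x$label, nrow(x$data), ncol(x$data)
  ))
  invisible(x)
}

#' Construct a labelled per-site feature collection
#'
#' @param site_id Character site identifier.
#' @param features Numeric matrix, one row per subject (connectome feature
#'   vectors of equal length).
#' @param labels Character vector of `"NC"`/`"ASD"` labels, one per row.
#' @param subject_ids Character vector of unique subject ids, one per row.
#' @return An object of class `site_dataset`.
#' @export
site_dataset <- function(site_id, features, labels, subject_ids) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- normalize_label(labels, context = sprintf("site %s", site_id))
  subject_ids <- as.character(subject_ids)
  if (nrow(features) != length(labels) || nrow(features) != length(subject_ids)) {
    stop("features, labels and subject_ids must agree in length", call. = FALSE)
  }
  if (anyDuplicated(subject_ids)) {
    stop(sprintf("site %s: duplicated subject ids", site_id), call. = FALSE)
  }
  if (!all(is.finite(features))) {
    stop(sprintf("site %s: non-finite feature values", site_id), call. = FALSE)
  }
  structure(
    list(
      site_id = as.character(site_id),
      features = features,
      labels = labels,
      subject_ids = subject_ids
    ),
    class = "site_dataset"
  )
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf(
    "<site_dataset> %s: %d subjects (%d NC / %d ASD), %d features\n",
    x$site_id, nrow(x$features), sum(x$labels == "NC"),
    sum(x$labels == "ASD"), ncol(x$features)
  ))
  invisible(x)
}

site_subset <- function(site, idx) {
  site_dataset(
    site$site_id,
    site$features[idx, , drop = FALSE],
    site$labels[idx],
    site$subject_ids[idx]
  )
}

class_counts <- function(site) {
  c(NC = sum(site$labels == "NC"), ASD = sum(site$labels == "ASD"))
}
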