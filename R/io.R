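#' Read a cohort manifest
#'
#' The manifest is a CSV with header `subject_id,site_id,label,path`
#' listing one ROI time-series file per subject. Labels are
#' case-insensitive `NC`/`ASD` (or `UNKNOWN`); any other string is a hard
#' error, as is a duplicated subject id. Relative `path` entries are
#' resolved against the manifest's own directory.
#'
#' @param path Path to the manifest CSV.
#' @param check_files Verify that every referenced time-series file exists?
#' @return A data.frame of class `cohort_manifest` with columns
#'   `subject_id`, `site_id`, `label`, `path`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("subject_id", "site_id", "label", "path")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("manifest missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("manifest contains no records", call. = FALSE)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) {
    stop(sprintf("duplicated subject_id in manifest: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  for (r in seq_len(nrow(df))) {
    df$label[r] <- tryCatch(
      normalize_label(df$label[r]),
      error = function(e) {
        stop(sprintf("manifest row %d (subject %s): %s",
                     r, df$subject_id[r], conditionMessage(e)), call. = FALSE)
      }
    )
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  if (check_files) {
    absent <- df$path[!file.exists(df$path)]
    if (length(absent)) {
      stop(sprintf("time-series file(s) not found: %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#'
#' @param manifest A manifest data.frame (`subject_id,site_id,label,path`).
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(
    manifest[, c("subject_id", "site_id", "label", "path")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read one subject's ROI time series
#'
#' Reads a delimited numeric matrix with rows = timepoints and columns =
#' regions (comma, tab or whitespace separated; no header by default).
#' Any non-numeric or non-finite cell and any column-count mismatch is a
#' hard error.
#'
#' @param path Path to the delimited file.
#' @param expected_R Required number of regions (columns); `NULL` skips
#'   the check.
#' @param header Does the file carry a one-line header to skip?
#' @param subject_id,site_id,label Metadata attached to the result.
#' @return An [roi_timeseries()].
#' @export
read_timeseries <- function(path, expected_R = NULL, header = FALSE,
                            subject_id = basename(path), site_id = "UNKNOWN",
                            label = "UNKNOWN") {
  if (!file.exists(path)) stop(sprintf("time-series file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("%s: empty time-series file", path), call. = FALSE)
  rows <- lapply(lines, function(l) strsplit(trimws(l), "[,\t ]+")[[1]])
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf("%s: ragged rows (column counts %s)", path,
                 paste(unique(ncols), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(expected_R) && ncols[1] != expected_R) {
    stop(sprintf("%s: expected %d regions, found %d", path, expected_R, ncols[1]),
         call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncols[1])
  for (r in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[r]]))
    bad <- which(!is.finite(vals))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric or non-finite value '%s' at row %d, column %d",
                   path, rows[[r]][bad[1]], r, bad[1]), call. = FALSE)
    }
    mat[r, ] <- vals
  }
  roi_timeseries(mat, subject_id = subject_id, site_id = site_id, label = label)
}

#' Write one subject's ROI time series
#'
#' @param ts An [roi_timeseries()].
#' @param path Output path (CSV, no header).
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Assemble a feature table
#'
#' @param features Numeric matrix, one row per subject.
#' @param subject_id,site_id,label Per-row metadata vectors.
#' @return Data.frame of class `feature_table`: metadata columns followed
#'   by `f1..fD`.
#' @export
feature_table <- function(features, subject_id, site_id, label) {
  features <- as.matrix(features)
  df <- data.frame(
    subject_id = as.character(subject_id),
    site_id = as.character(site_id),
    label = normalize_label(label),
    stringsAsFactors = FALSE
  )
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  out <- cbind(df, as.data.frame(features))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @rdname feature_table
#' @param tab A feature table.
#' @param path CSV path.
#' @export
write_features <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname feature_table
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(fcols) == 0L) stop("no feature columns f1..fD found", call. = FALSE)
  feature_table(
    as.matrix(df[, fcols, drop = FALSE]),
    subject_id = df$subject_id, site_id = df$site_id, label = df$label
  )
}

# Split a feature table into per-site site_dataset objects.
split_by_site <- function(tab) {
  fcols <- grep("^f[0-9]+$", names(tab), value = TRUE)
  sites <- split(seq_len(nrow(tab)), tab$site_id)
  lapply(sites, function(idx) {
    site_dataset(
      tab$site_id[idx[1]],
      as.matrix(tab[idx, fcols, drop = FALSE]),
      tab$label[idx],
      tab$subject_id[idx]
    )
  })
}

#' Write / read a metrics report
#'
#' Metrics reports are JSON keyed by site id, each entry holding
#' `accuracy`, `precision`, `f1` (percentages), `n` and the confusion
#' counts `tp, fp, fn, tn` (ASD is the positive class). Written with full
#' numeric precision so that write-then-read is the identity.
#'
#' @param report A named list as produced by [evaluate_target_sites()].
#' @param path JSON path; for [write_metrics()] the parent directory must
#'   exist.
#' @return [read_metrics()] returns the report list.
#' @export
write_metrics <- function(report, path) {
  if (!dir.exists(dirname(path))) {
    stop(sprintf("directory does not exist: %s", dirname(path)), call. = FALSE)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  if (!file.exists(path)) stop(sprintf("metrics file not found: %s", path), call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

#' Read a run configuration file
#'
#' Accepts YAML or JSON whose keys mirror [run_config()] arguments.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- read_config_file(path)
  do.call(run_config, vals)
}

#' Read a simulation configuration file
#'
#' @param path Config file path whose keys mirror [sim_config()] arguments.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- read_config_file(path)
  do.call(sim_config, vals)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
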