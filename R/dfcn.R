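#' Sliding-window specification
#'
#' The window length `M` and stride `s` of the sliding-window dynamic
#' functional connectivity construction. Neither value is canonical in the
#' literature; defaults (`M = 30` timepoints, `s = 1`) follow common
#' sliding-window practice and everything downstream is agnostic to them.
#'
#' @param M Window length in timepoints, at least 2.
#' @param s Stride in timepoints, at least 1.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(M = 30L, s = 1L) {
  M <- as.integer(M)
  s <- as.integer(s)
  if (is.na(M) || M < 2L) stop("window length M must be >= 2", call. = FALSE)
  if (is.na(s) || s < 1L) stop("stride s must be >= 1", call. = FALSE)
  structure(list(M = M, s = s), class = "window_spec")
}

#' Enumerate sliding windows over a series of length T
#'
#' Windows are half-open 0-based intervals `[start, end)` of length exactly
#' `M`, advancing by `s`; trailing timepoints that cannot fill a complete
#' window are dropped, giving `K = floor((T - M)/s) + 1` windows.
#'
#' @param T_len Number of timepoints in the series.
#' @param spec A [window_spec()].
#' @return Integer matrix with columns `start`, `end`, one row per window.
#' @export
#' @examples
#' enumerate_windows(5, window_spec(M = 3, s = 1))
enumerate_windows <- function(T_len, spec) {
  stopifnot(inherits(spec, "window_spec"))
  T_len <- as.integer(T_len)
  if (spec$M > T_len) {
    stop(sprintf("window longer than series (M = %d > T = %d)", spec$M, T_len),
         call. = FALSE)
  }
  K <- (T_len - spec$M) %/% spec$s + 1L
  start <- (seq_len(K) - 1L) * spec$s
  cbind(start = start, end = start + spec$M)
}

#' Pearson correlation of two regions within one window
#'
#' Computes the centred cross-product of the two in-window signals divided
#' by the product of their centred norms. A window in which either region
#' has zero variance carries no correlation evidence; the correlation is
#' then reported as 0 with a warning rather than NaN.
#'
#' @param ts An [roi_timeseries()].
#' @param window Length-2 vector `(start, end)`, half-open 0-based.
#' @param i,j Region indices (1-based columns of `ts$data`).
#' @return A correlation in `[-1, 1]`.
#' @export
pearson_window <- function(ts, window, i, j) {
  stopifnot(inherits(ts, "roi_timeseries"))
  T_len <- nrow(ts$data)
  start <- as.integer(window[[1]])
  end <- as.integer(window[[2]])
  if (start < 0L || end > T_len || end - start < 2L) {
    stop("window out of range", call. = FALSE)
  }
  rows <- (start + 1L):end
  x <- ts$data[rows, i]
  y <- ts$data[rows, j]
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2)) * sqrt(sum(yc^2))
  if (denom == 0) {
    warning(sprintf(
      "zero-variance signal in window [%d,%d) for region pair (%d,%d); correlation set to 0",
      start, end, i, j
    ), call. = FALSE)
    return(0)
  }
  r <- sum(xc * yc) / denom
  max(-1, min(1, r))
}

# Correlation matrix of one window with the zero-variance convention
# applied column-wise (constant regions get zero correlation to all others).
window_fc <- function(segment) {
  fc <- suppressWarnings(stats::cor(segment))
  if (anyNA(fc)) {
    n_const <- sum(vapply(seq_len(ncol(segment)), function(j) {
      all(segment[, j] == segment[1, j])
    }, logical(1)))
    warning(sprintf(
      "%d zero-variance region(s) in a window; their correlations set to 0",
      n_const
    ), call. = FALSE)
    fc[is.na(fc)] <- 0
    diag(fc) <- 1
  }
  fc[fc > 1] <- 1
  fc[fc < -1] <- -1
  fc
}

#' Build the dynamic functional connectivity network of one subject
#'
#' Slides overlapping windows over the BOLD series and computes a full
#' region-by-region Pearson correlation matrix (a sub-FCN) per window.
#'
#' @param ts An [roi_timeseries()].
#' @param spec A [window_spec()].
#' @return An object of class `dynamic_fcn`: list with `windows` (list of
#'   K symmetric unit-diagonal correlation matrices, ordered by window
#'   start), `intervals` (the output of [enumerate_windows()]) and `spec`.
#' @export
build_dfcn <- function(ts, spec = window_spec()) {
  stopifnot(inherits(ts, "roi_timeseries"))
  intervals <- enumerate_windows(nrow(ts$data), spec)
  windows <- lapply(seq_len(nrow(intervals)), function(k) {
    rows <- (intervals[k, "start"] + 1L):intervals[k, "end"]
    window_fc(ts$data[rows, , drop = FALSE])
  })
  structure(
    list(windows = windows, intervals = intervals, spec = spec),
    class = "dynamic_fcn"
  )
}

#' @export
print.dynamic_fcn <- function(x, ...) {
  cat(sprintf(
    "<dynamic_fcn> %d windows of length %d (stride %d), %d regions\n",
    length(x$windows), x$spec$M, x$spec$s, nrow(x$windows[[1]])
  ))
  invisible(x)
}

#' Mean connectivity matrix of a dynamic FCN
#'
#' @param dfcn A [build_dfcn()] result.
#' @return The elementwise mean of the per-window correlation matrices:
#'   symmetric, unit diagonal, entries in `[-1, 1]`.
#' @export
mean_fcn <- function(dfcn) {
  stopifnot(inherits(dfcn, "dynamic_fcn"))
  if (length(dfcn$windows) == 0L) stop("empty dynamic FCN", call. = FALSE)
  Reduce(`+`, dfcn$windows) / length(dfcn$windows)
}

#' Vectorize the upper triangle of a symmetric connectivity matrix
#'
#' Because the connectivity matrix is symmetric with unit diagonal, only
#' its off-diagonal upper triangle is informative. Elements are taken in
#' row-major order, i.e. pairs (i, j) with i < j, i ascending then j
#' ascending, giving a vector of length R(R-1)/2 (6670 for the 116-region
#' AAL parcellation).
#'
#' @param mat Symmetric numeric matrix.
#' @param tol Symmetry tolerance; larger asymmetry is an error.
#' @return Numeric vector of length `R(R-1)/2`.
#' @seealso [devectorize_upper()]
#' @export
vectorize_upper <- function(mat, tol = 1e-8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("matrix must be square", call. = FALSE)
  if (max(abs(mat - t(mat))) > tol) {
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  }
  # row-major upper triangle == column-major lower triangle of the transpose
  t(mat)[lower.tri(mat)]
}

#' Reconstruct a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()]; the diagonal is set to 1.
#'
#' @param v Numeric vector of length `R(R-1)/2` for some integer R.
#' @return Symmetric R x R matrix with unit diagonal.
#' @export
devectorize_upper <- function(v) {
  D <- length(v)
  R <- (1 + sqrt(1 + 8 * D)) / 2
  if (R != round(R)) stop("vector length is not R(R-1)/2 for integer R", call. = FALSE)
  R <- as.integer(round(R))
  mat <- matrix(0, R, R)
  mat[lower.tri(mat)] <- v
  mat <- t(mat)        # filled row-major upper triangle
  mat <- mat + t(mat)
  diag(mat) <- 1
  mat
}

#' Extract a subject's connectome feature vector
#'
#' The full feature pipeline for one subject: sliding-window dynamic FCN,
#' elementwise mean matrix, upper-triangle vectorization. Optionally
#' applies the Fisher z-transform `atanh(r)` to the vectorized
#' correlations (off by default; correlations are used untransformed).
#'
#' @param ts An [roi_timeseries()].
#' @param spec A [window_spec()].
#' @param fisher_z Apply `atanh` to the features (values clamped to
#'   `[-1 + 1e-7, 1 - 1e-7]` first)?
#' @return Numeric feature vector of length `R(R-1)/2`.
#' @export
extract_features <- function(ts, spec = window_spec(), fisher_z = FALSE) {
  v <- vectorize_upper(mean_fcn(build_dfcn(ts, spec)))
  if (fisher_z) {
    v <- atanh(pmax(pmin(v, 1 - 1e-7), -1 + 1e-7))
  }
  v
}

#' Extract features for every subject in a cohort
#'
#' @param manifest A cohort manifest from [read_manifest()].
#' @param spec A [window_spec()].
#' @param expected_R Number of regions each time-series file must have.
#' @param fisher_z Passed to [extract_features()].
#' @return A feature table (data.frame): `subject_id`, `site_id`, `label`,
#'   then columns `f1..fD` with `D = R(R-1)/2`.
#' @export
features_for_manifest <- function(manifest, spec = window_spec(),
                                  expected_R = 116L, fisher_z = FALSE) {
  feats <- lapply(seq_len(nrow(manifest)), function(r) {
    ts <- read_timeseries(manifest$path[r], expected_R = expected_R,
                          subject_id = manifest$subject_id[r],
                          site_id = manifest$site_id[r],
                          label = manifest$label[r])
    extract_features(ts, spec, fisher_z = fisher_z)
  })
  feature_table(
    do.call(rbind, feats),
    subject_id = manifest$subject_id,
    site_id = manifest$site_id,
    label = manifest$label
  )
}
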