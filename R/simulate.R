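#' Simulation configuration for the synthetic multi-site cohort
#'
#' The generator draws every subject's BOLD series from a zero-mean
#' multivariate normal whose correlation structure combines three parts:
#' a base correlation matrix shared by all sites and both groups (a random
#' low-rank factor structure, fixed by the seed), an ASD-specific additive
#' shift `delta` on a fixed seed-chosen set of connectivity edges, and a
#' site-specific additive Gaussian perturbation of every edge (SD
#' `site_effect_sd`) shared by both diagnostic groups within the site —
#' emulating scanner/protocol shifts that move a whole site together.
#' Independent Gaussian observation noise (SD `noise_sd`) is added to the
#' sampled series.
#'
#' Defaults describe the package's reference benchmark: 7 sites of 40
#' subjects (20 per group), 20 regions, 150 timepoints, a group effect of
#' 0.4 on 20 of the 190 edges, site heterogeneity SD 0.1 and observation
#' noise SD 0.3.
#'
#' @param n_sites Number of imaging sites.
#' @param subjects_per_site_per_class Subjects per site in each of NC/ASD.
#' @param R Number of regions.
#' @param T_len Timepoints per subject.
#' @param delta Correlation-scale group effect added to affected edges in
#'   the ASD target matrices; `|delta| < 1`.
#' @param n_affected_edges Number of edges carrying the group effect; at
#'   most `R(R-1)/2`.
#' @param site_effect_sd SD of the per-site edge perturbations.
#' @param noise_sd SD of the additive observation noise.
#' @param rng_seed Integer seed; all draws flow from it through named
#'   substreams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 7L, subjects_per_site_per_class = 20L,
                       R = 20L, T_len = 150L, delta = 0.4,
                       n_affected_edges = 20L, site_effect_sd = 0.1,
                       noise_sd = 0.3, rng_seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    subjects_per_site_per_class = as.integer(subjects_per_site_per_class),
    R = as.integer(R),
    T_len = as.integer(T_len),
    delta = as.numeric(delta),
    n_affected_edges = as.integer(n_affected_edges),
    site_effect_sd = as.numeric(site_effect_sd),
    noise_sd = as.numeric(noise_sd),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(cfg$n_sites >= 1L, cfg$R >= 2L, cfg$T_len >= 2L)
  if (abs(cfg$delta) >= 1) stop("|delta| must be < 1", call. = FALSE)
  if (cfg$n_affected_edges > cfg$R * (cfg$R - 1L) / 2L) {
    stop("n_affected_edges exceeds the number of edges R(R-1)/2", call. = FALSE)
  }
  if (cfg$site_effect_sd < 0 || cfg$noise_sd < 0) {
    stop("site_effect_sd and noise_sd must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Shared base correlation matrix: low-rank factor structure + noise floor,
# deterministic in the config seed.
base_correlation <- function(config) {
  with_substream(config$rng_seed, "base", {
    q <- max(2L, config$R %/% 5L)
    F_load <- matrix(stats::rnorm(config$R * q, sd = 0.6), config$R, q)
    S <- F_load %*% t(F_load) + diag(0.8, config$R)
    stats::cov2cor(S)
  })
}

# The fixed edge set (as upper-triangle vector indices) carrying the
# group effect; chosen once per seed, identical across sites.
affected_edges <- function(config) {
  n_edges <- config$R * (config$R - 1L) / 2L
  with_substream(config$rng_seed, "edges", {
    sort(sample.int(n_edges, config$n_affected_edges))
  })
}

# Clip negative eigenvalues to eps, reconstruct, re-normalize to unit
# diagonal. Deterministic.
psd_repair <- function(mat, eps = 1e-6) {
  eig <- eigen((mat + t(mat)) / 2, symmetric = TRUE)
  vals <- pmax(eig$values, eps)
  rep_mat <- eig$vectors %*% (vals * t(eig$vectors))
  d <- diag(rep_mat)
  if (any(d <= 0)) {
    stop("positive semi-definite repair failed; use a smaller delta or site_effect_sd",
         call. = FALSE)
  }
  out <- stats::cov2cor(rep_mat)
  (out + t(out)) / 2
}

#' Target correlation matrix for one (site, group) cell
#'
#' Constructs the latent correlation matrix a subject of the given site
#' and diagnostic group is drawn from: shared base + `delta` on the fixed
#' affected-edge set (ASD only) + the site's Gaussian edge offsets. The
#' raw sum is clamped to `[-0.99, 0.99]` off-diagonal and, unless
#' `repair = FALSE`, made positive semi-definite by eigenvalue clipping
#' and re-normalization to unit diagonal.
#'
#' @param config A [sim_config()].
#' @param site Site index, 1-based.
#' @param klass `"NC"` or `"ASD"`.
#' @param repair Apply the positive semi-definite repair? `FALSE` returns
#'   the raw additive construction (useful to inspect which edges differ).
#' @return Symmetric R x R correlation matrix.
#' @export
make_target_correlation <- function(config, site, klass = c("NC", "ASD"),
                                    repair = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  klass <- match.arg(klass)
  if (site < 1L || site > config$n_sites) stop("site index out of range", call. = FALSE)
  base <- base_correlation(config)
  v <- vectorize_upper(base)
  if (klass == "ASD" && config$n_affected_edges > 0L) {
    v[affected_edges(config)] <- v[affected_edges(config)] + config$delta
  }
  if (config$site_effect_sd > 0) {
    offs <- with_substream(config$rng_seed, sprintf("site%03d", site), {
      stats::rnorm(length(v), sd = config$site_effect_sd)
    })
    v <- v + offs
  }
  v <- pmax(pmin(v, 0.99), -0.99)
  target <- devectorize_upper(v)
  if (repair) target <- psd_repair(target) else target
}

#' Simulate one subject's BOLD series from a target correlation matrix
#'
#' Draws `T_len` independent timepoints from a zero-mean multivariate
#' normal with the given correlation matrix, then adds independent
#' observation noise. Uses the current RNG stream; callers seed it.
#'
#' @param target Valid correlation matrix (symmetric, unit diagonal, PSD).
#' @param T_len Number of timepoints, at least 2.
#' @param noise_sd Observation noise SD.
#' @param subject_id,site_id,label Metadata for the result.
#' @return An [roi_timeseries()].
#' @export
simulate_subject <- function(target, T_len, noise_sd = 0,
                             subject_id = "sim", site_id = "UNKNOWN",
                             label = "UNKNOWN") {
  target <- as.matrix(target)
  R <- nrow(target)
  if (T_len < 2L) stop("T_len must be >= 2", call. = FALSE)
  eig <- eigen((target + t(target)) / 2, symmetric = TRUE)
  if (min(eig$values) < -1e-8) {
    stop("target matrix is not positive semi-definite", call. = FALSE)
  }
  L <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), R)
  Z <- matrix(stats::rnorm(T_len * R), T_len, R)
  X <- Z %*% t(L)
  if (noise_sd > 0) X <- X + matrix(stats::rnorm(T_len * R, sd = noise_sd), T_len, R)
  roi_timeseries(X, subject_id = subject_id, site_id = site_id, label = label)
}

sim_site_ids <- function(config) sprintf("SITE%02d", seq_len(config$n_sites) - 1L)

#' Simulate a multi-site cohort in memory
#'
#' Generates every subject of the configured cohort (balanced NC/ASD per
#' site by construction) and returns the time series grouped by site.
#'
#' @param config A [sim_config()].
#' @return Named list (by site id) of lists of [roi_timeseries()].
#' @export
simulate_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$subjects_per_site_per_class < 1L) stop("empty cohort", call. = FALSE)
  ids <- sim_site_ids(config)
  out <- vector("list", config$n_sites)
  names(out) <- ids
  for (s in seq_len(config$n_sites)) {
    targets <- list(
      NC = make_target_correlation(config, s, "NC"),
      ASD = make_target_correlation(config, s, "ASD")
    )
    subjects <- list()
    for (klass in c("NC", "ASD")) {
      for (m in seq_len(config$subjects_per_site_per_class)) {
        sid <- sprintf("%s_%s_%02d", ids[s], klass, m)
        ts <- with_substream(config$rng_seed, paste0("subj_", sid), {
          simulate_subject(targets[[klass]], config$T_len, config$noise_sd,
                           subject_id = sid, site_id = ids[s], label = klass)
        })
        subjects[[sid]] <- ts
      }
    }
    out[[s]] <- subjects
  }
  out
}

#' Simulate a cohort and write it to disk
#'
#' Writes one time-series CSV per subject plus a cohort manifest in the
#' dialect [read_manifest()] expects. Re-running with the same config is
#' byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Writable output directory (created if absent).
#' @return The manifest (invisibly readable back from
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
simulate_cohort <- function(config, out_dir) {
  sites <- simulate_sites(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- list()
  for (site in names(sites)) {
    for (ts in sites[[site]]) {
      fn <- paste0(ts$subject_id, ".csv")
      write_timeseries(ts, file.path(out_dir, fn))
      records[[length(records) + 1L]] <- data.frame(
        subject_id = ts$subject_id, site_id = ts$site_id,
        label = ts$label, path = fn, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, records)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  read_manifest(file.path(out_dir, "manifest.csv"))
}
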