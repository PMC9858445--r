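#' Run configuration
#'
#' Collects every knob of the feature-extraction / training / evaluation
#' pipeline. Fields not fixed by the method itself (window length and
#' stride, architecture widths, optimizer settings) are artifact choices
#' with documented defaults.
#'
#' @param window_length,window_stride Sliding-window parameters (timepoints).
#' @param n_regions Number of ROIs (116 for the AAL parcellation).
#' @param encoder_widths,head_widths,embedding_dim,activation Architecture;
#'   see [encoder_spec()].
#' @param head_mode `"literal"` or `"affine"`; see [init_model()].
#' @param recon_weight Autoencoder reconstruction penalty weight (0 = off).
#' @param learning_rate SGD step size.
#' @param n_iterations Training steps (full-batch).
#' @param eval_interval Steps between meta-test monitoring evaluations.
#' @param meta_train_fraction Within-site meta-train fraction, in (0, 1).
#' @param fine_tune_shots_per_class,fine_tune_steps Target-site few-shot
#'   protocol; see [eval_protocol()].
#' @param fisher_z Apply the Fisher z-transform to features?
#' @param rng_seed Run seed; every random stage derives a named substream
#'   from it.
#' @param baseline_site Site id providing the class prototypes.
#' @param training_sites Character vector of training-site ids.
#' @param target_sites Character vector of held-out target-site ids
#'   (`NULL`: all remaining sites).
#' @return An object of class `run_config`.
#' @export
run_config <- function(window_length = 30L, window_stride = 1L,
                       n_regions = 116L,
                       encoder_widths = c(512L, 128L),
                       head_widths = integer(0),
                       embedding_dim = 64L,
                       activation = "relu",
                       head_mode = "literal",
                       recon_weight = 0,
                       learning_rate = 1e-3,
                       n_iterations = 500L,
                       eval_interval = 50L,
                       meta_train_fraction = 0.7,
                       fine_tune_shots_per_class = 5L,
                       fine_tune_steps = 50L,
                       fisher_z = FALSE,
                       rng_seed = 1L,
                       baseline_site = NULL,
                       training_sites = NULL,
                       target_sites = NULL) {
  cfg <- list(
    window_length = as.integer(window_length),
    window_stride = as.integer(window_stride),
    n_regions = as.integer(n_regions),
    encoder_widths = as.integer(encoder_widths),
    head_widths = as.integer(head_widths),
    embedding_dim = as.integer(embedding_dim),
    activation = match.arg(activation, c("relu", "tanh")),
    head_mode = match.arg(head_mode, c("literal", "affine")),
    recon_weight = as.numeric(recon_weight),
    learning_rate = as.numeric(learning_rate),
    n_iterations = as.integer(n_iterations),
    eval_interval = as.integer(eval_interval),
    meta_train_fraction = as.numeric(meta_train_fraction),
    fine_tune_shots_per_class = as.integer(fine_tune_shots_per_class),
    fine_tune_steps = as.integer(fine_tune_steps),
    fisher_z = isTRUE(fisher_z),
    rng_seed = as.integer(rng_seed),
    baseline_site = baseline_site,
    training_sites = training_sites,
    target_sites = target_sites
  )
  if (cfg$window_length < 2L) stop("window_length must be >= 2", call. = FALSE)
  if (cfg$window_stride < 1L) stop("window_stride must be >= 1", call. = FALSE)
  if (cfg$meta_train_fraction <= 0 || cfg$meta_train_fraction >= 1) {
    stop("meta_train_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Reference synthetic benchmark configuration
#'
#' The package's desk-scale reference benchmark: a 7-site cohort (20
#' regions, 150 timepoints, 20 subjects per site per group) with a 0.4
#' group effect on 20 edges and site-heterogeneity SD 0.1. Four sites
#' train, one provides the prototypes, two are held out as targets. The
#' architecture and optimizer are scaled to the 190-dimensional feature
#' vector.
#'
#' @param seed Run seed applied to both configurations.
#' @param delta,site_effect_sd Overrides of the group effect and site
#'   heterogeneity (e.g. `delta = 0` for null-calibration runs).
#' @param subjects_per_site_per_class Override of the per-site group size.
#' @return List with elements `sim` ([sim_config()]) and `run`
#'   ([run_config()]).
#' @export
benchmark_config <- function(seed = 1L, delta = 0.4, site_effect_sd = 0.1,
                             subjects_per_site_per_class = 20L) {
  sim <- sim_config(
    n_sites = 7L, subjects_per_site_per_class = subjects_per_site_per_class,
    R = 20L, T_len = 150L, delta = delta, n_affected_edges = 20L,
    site_effect_sd = site_effect_sd, noise_sd = 0.3, rng_seed = seed
  )
  run <- run_config(
    window_length = 30L, window_stride = 1L, n_regions = 20L,
    encoder_widths = c(64L, 32L), head_widths = integer(0),
    embedding_dim = 16L, activation = "relu", head_mode = "literal",
    learning_rate = 0.05, n_iterations = 300L, eval_interval = 50L,
    meta_train_fraction = 0.7, fine_tune_shots_per_class = 5L,
    fine_tune_steps = 50L, rng_seed = seed,
    baseline_site = "SITE04",
    training_sites = c("SITE00", "SITE01", "SITE02", "SITE03"),
    target_sites = c("SITE05", "SITE06")
  )
  list(sim = sim, run = run)
}

#' Extract features for an in-memory simulated cohort
#'
#' @param sites Output of [simulate_sites()].
#' @param config A [run_config()] (supplies window length/stride and the
#'   Fisher-z flag).
#' @return A [feature_table()].
#' @export
features_for_sites <- function(sites, config) {
  spec <- window_spec(config$window_length, config$window_stride)
  all_ts <- unlist(sites, recursive = FALSE, use.names = FALSE)
  feats <- t(vapply(all_ts, extract_features, spec = spec,
                    fisher_z = config$fisher_z,
                    FUN.VALUE = numeric(config$n_regions * (config$n_regions - 1L) / 2L)))
  feature_table(
    feats,
    subject_id = vapply(all_ts, `[[`, character(1), "subject_id"),
    site_id = vapply(all_ts, `[[`, character(1), "site_id"),
    label = vapply(all_ts, `[[`, character(1), "label")
  )
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> features -> train -> evaluate, entirely in memory (or via
#' files when `work_dir` is given, exercising the on-disk formats).
#' Fully reproducible from the two configs' seeds.
#'
#' @param sim A [sim_config()].
#' @param run A [run_config()].
#' @param work_dir Optional directory: the cohort is written to and read
#'   back from disk instead of being kept in memory.
#' @return List: `fit` (the [train_siamese()] result), `metrics` (the
#'   target-site report), `features` (the feature table), `meta_test`
#'   (final meta-test accuracy per training site, percent).
#' @export
run_pipeline <- function(sim, run, work_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"), inherits(run, "run_config"))
  if (is.null(work_dir)) {
    sites_ts <- simulate_sites(sim)
    tab <- features_for_sites(sites_ts, run)
  } else {
    manifest <- simulate_cohort(sim, work_dir)
    tab <- features_for_manifest(
      manifest, window_spec(run$window_length, run$window_stride),
      expected_R = run$n_regions, fisher_z = run$fisher_z
    )
  }
  by_site <- split_by_site(tab)
  baseline_id <- run$baseline_site %||% names(by_site)[1]
  training_ids <- run$training_sites %||%
    setdiff(names(by_site), baseline_id)[seq_len(max(1L, length(by_site) - 2L))]
  target_ids <- run$target_sites %||%
    setdiff(names(by_site), c(baseline_id, training_ids))
  missing_sites <- setdiff(c(baseline_id, training_ids, target_ids), names(by_site))
  if (length(missing_sites)) {
    stop(sprintf("site(s) not in cohort: %s", paste(missing_sites, collapse = ", ")),
         call. = FALSE)
  }
  fit <- train_siamese(run, by_site[training_ids], by_site[[baseline_id]])
  protocol <- eval_protocol(
    fine_tune_shots_per_class = run$fine_tune_shots_per_class,
    fine_tune_steps = run$fine_tune_steps,
    learning_rate = run$learning_rate,
    rng_seed = run$rng_seed
  )
  metrics <- if (length(target_ids)) {
    evaluate_target_sites(fit$model, by_site[target_ids], by_site[[baseline_id]],
                          protocol, training_site_ids = training_ids)
  } else {
    NULL
  }
  final_eval <- fit$meta_eval[fit$meta_eval$step == max(fit$meta_eval$step), ]
  list(
    fit = fit,
    metrics = metrics,
    features = tab,
    meta_test = stats::setNames(final_eval$accuracy, final_eval$site_id)
  )
}

#' Pooled nearest-class-mean comparator
#'
#' A deliberately simple baseline classifier used as an independent
#' reference: the training sites' samples are pooled (ignoring site
#' structure), features are z-scored with pooled statistics, and a query
#' is assigned the class whose pooled mean feature vector is nearest in
#' Euclidean distance. This mimics the failure mode of site-blind pooling
#' on heterogeneous cohorts.
#'
#' @param train_sites List of [site_dataset()]s to pool.
#' @param targets List of target [site_dataset()]s.
#' @return Metrics report in the same shape as
#'   [evaluate_target_sites()] (without fine-tuning or support sampling).
#' @export
nearest_mean_baseline <- function(train_sites, targets) {
  X <- do.call(rbind, lapply(train_sites, function(s) s$features))
  y <- unlist(lapply(train_sites, function(s) s$labels), use.names = FALSE)
  mu <- colMeans(X)
  sdv <- pmax(apply(X, 2L, stats::sd), 1e-8)
  zs <- function(M) sweep(sweep(M, 2L, mu), 2L, sdv, "/")
  Xz <- zs(X)
  m_nc <- colMeans(Xz[y == "NC", , drop = FALSE])
  m_asd <- colMeans(Xz[y == "ASD", , drop = FALSE])
  per_site <- list()
  for (site in targets) {
    Q <- zs(site$features)
    d_nc <- rowSums(sweep(Q, 2L, m_nc)^2)
    d_asd <- rowSums(sweep(Q, 2L, m_asd)^2)
    preds <- ifelse(d_nc < d_asd, "NC", "ASD")
    per_site[[site$site_id]] <- compute_metrics(preds, site$labels)
  }
  macro <- list(
    accuracy = mean(vapply(per_site, `[[`, numeric(1), "accuracy")),
    precision = mean(vapply(per_site, `[[`, numeric(1), "precision")),
    f1 = mean(vapply(per_site, `[[`, numeric(1), "f1")),
    n = sum(vapply(per_site, `[[`, numeric(1), "n"))
  )
  c(per_site, list(macro_average = macro, positive_class = "ASD"))
}

#' Baseline-site sweep
#'
#' Re-trains the model once per candidate baseline site (all other
#' candidate sites acting as training sites) and reports the final
#' meta-test accuracy per configuration — the protocol used to judge
#' which site serves best as the prototype source.
#'
#' @param run A [run_config()] (its `baseline_site`/`training_sites` are
#'   overridden per sweep arm).
#' @param by_site Named list of [site_dataset()]s to sweep over.
#' @param candidate_ids Site ids to try as baseline (default: all of
#'   `by_site`).
#' @return Data.frame: `baseline_site`, `mean_meta_test_accuracy`.
#' @export
baseline_sweep <- function(run, by_site, candidate_ids = names(by_site)) {
  rows <- lapply(candidate_ids, function(b) {
    cfg <- run
    cfg$baseline_site <- b
    cfg$training_sites <- setdiff(candidate_ids, b)
    fit <- train_siamese(cfg, by_site[cfg$training_sites], by_site[[b]])
    fin <- fit$meta_eval[fit$meta_eval$step == max(fit$meta_eval$step), ]
    data.frame(baseline_site = b,
               mean_meta_test_accuracy = mean(fin$accuracy),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
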