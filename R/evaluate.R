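#' Balance a site's classes by random down-sampling
#'
#' Removes uniformly random samples (substream `"balance"` + site id)
#' from the larger class until both classes have `min(n_NC, n_ASD)`
#' samples. A site already balanced is returned with the same subjects.
#'
#' @param site A [site_dataset()] with both classes present.
#' @param seed Run seed.
#' @return A balanced [site_dataset()].
#' @export
balance_classes <- function(site, seed = 1L) {
  stopifnot(inherits(site, "site_dataset"))
  counts <- class_counts(site)
  if (any(counts == 0L)) {
    stop(sprintf("site %s: class %s absent, cannot balance",
                 site$site_id, names(counts)[counts == 0L][1]), call. = FALSE)
  }
  n_keep <- min(counts)
  keep <- integer(0)
  for (klass in c("NC", "ASD")) {
    idx <- which(site$labels == klass)
    if (length(idx) > n_keep) {
      idx <- with_substream(seed, paste0("balance_", site$site_id, "_", klass), {
        sort(sample(idx, n_keep))
      })
    }
    keep <- c(keep, idx)
  }
  site_subset(site, sort(keep))
}

#' Few-shot evaluation protocol
#'
#' @param fine_tune_shots_per_class Labelled support samples drawn per
#'   class from each target site (0 = zero-shot). Support samples are
#'   excluded from the reported metrics.
#' @param fine_tune_steps Gradient steps of fine-tuning on the support
#'   set.
#' @param learning_rate Fine-tuning learning rate.
#' @param balance Balance target-site classes before splitting
#'   support/query?
#' @param rng_seed Run seed.
#' @return An object of class `eval_protocol` (two-way by construction:
#'   the classes are NC and ASD).
#' @export
eval_protocol <- function(fine_tune_shots_per_class = 5L,
                          fine_tune_steps = 50L, learning_rate = NULL,
                          balance = TRUE, rng_seed = 1L) {
  p <- list(
    C = 2L,
    fine_tune_shots_per_class = as.integer(fine_tune_shots_per_class),
    fine_tune_steps = as.integer(fine_tune_steps),
    learning_rate = learning_rate,
    balance = isTRUE(balance),
    rng_seed = as.integer(rng_seed)
  )
  if (p$fine_tune_shots_per_class < 0L) {
    stop("fine_tune_shots_per_class must be >= 0", call. = FALSE)
  }
  structure(p, class = "eval_protocol")
}

#' Split a target site into support and query sets
#'
#' Draws `shots` subjects per class (substream `"support"` + site id) as
#' the fine-tuning support set; all remaining subjects form the query
#' set. Support and query are disjoint by construction.
#'
#' @param site A [site_dataset()].
#' @param shots Support samples per class.
#' @param seed Run seed.
#' @return List `support`, `query` ([site_dataset()]s; `support` is
#'   `NULL` when `shots = 0`).
#' @export
sample_support <- function(site, shots, seed = 1L) {
  shots <- as.integer(shots)
  if (shots == 0L) {
    return(list(support = NULL, query = site))
  }
  sup <- integer(0)
  for (klass in c("NC", "ASD")) {
    idx <- which(site$labels == klass)
    if (length(idx) <= shots) {
      stop(sprintf(
        "site %s: %d support shots requested but class %s has only %d samples (queries would be empty)",
        site$site_id, shots, klass, length(idx)), call. = FALSE)
    }
    sup <- c(sup, with_substream(seed, paste0("support_", site$site_id, "_", klass), {
      sort(sample(idx, shots))
    }))
  }
  list(
    support = site_subset(site, sort(sup)),
    query = site_subset(site, setdiff(seq_along(site$labels), sup))
  )
}

#' Fine-tune the model on a target site's support set
#'
#' Continues gradient descent on the support set's loss against the
#' baseline prototypes (which are recomputed from the current parameters
#' at every step, exactly as in training). The input model is not
#' mutated; a fresh copy is updated and returned. With
#' `fine_tune_steps = 0` the returned parameters equal the input's.
#'
#' @param model A trained `siamese_model`.
#' @param target_support [site_dataset()] of support samples (both
#'   classes present), or `NULL` for a no-op.
#' @param baseline The baseline [site_dataset()].
#' @param protocol An [eval_protocol()].
#' @param learning_rate Step size; defaults to the protocol's, else 0.01.
#' @return The fine-tuned model.
#' @export
fine_tune <- function(model, target_support, baseline, protocol,
                      learning_rate = NULL) {
  stopifnot(inherits(model, "siamese_model"))
  lr <- learning_rate %||% protocol$learning_rate %||% 0.01
  if (is.null(target_support) || protocol$fine_tune_steps == 0L) {
    return(model)
  }
  counts <- class_counts(target_support)
  if (any(counts == 0L)) {
    stop("support set must contain both classes", call. = FALSE)
  }
  for (step in seq_len(protocol$fine_tune_steps)) {
    st <- train_step(model, list(target_support), baseline, lr)
    model <- st$model
    if (!is.finite(st$per_site[1])) {
      stop(sprintf("fine-tuning diverged at step %d", step), call. = FALSE)
    }
  }
  model
}

#' Classify a query subject by prototype matching
#'
#' The query is embedded and compared to both baseline prototypes via the
#' sigmoid-mapped L1 distance. Higher similarity means a smaller output,
#' so the predicted label is NC when the NC output is strictly smaller
#' than the ASD output; exact ties go to ASD.
#'
#' @param model A `siamese_model`.
#' @param query Feature vector of length `input_dim`.
#' @param protos Fresh [compute_prototypes()] output for this model.
#' @return `"NC"` or `"ASD"`.
#' @export
classify_query <- function(model, query, protos) {
  check_fresh(model, protos)
  e <- embed(model, query)
  out_nc <- model_sigmoid(model, l1_distance(e, protos$proto_nc))
  out_asd <- model_sigmoid(model, l1_distance(e, protos$proto_asd))
  if (out_nc < out_asd) "NC" else "ASD"
}

# Vectorized prototype-matching over a feature matrix; also returns the
# two similarity outputs per query for reporting.
classify_batch <- function(model, features, protos, detail = FALSE) {
  E <- forward_embed(model, features)
  d_nc <- rowSums(abs(sweep(E, 2L, protos$proto_nc)))
  d_asd <- rowSums(abs(sweep(E, 2L, protos$proto_asd)))
  out_nc <- model_sigmoid(model, d_nc)
  out_asd <- model_sigmoid(model, d_asd)
  preds <- ifelse(out_nc < out_asd, "NC", "ASD")
  if (detail) {
    data.frame(pred = preds, output_nc = out_nc, output_asd = out_asd,
               stringsAsFactors = FALSE)
  } else {
    preds
  }
}

#' Classification metrics with ASD as the positive class
#'
#' Accuracy, precision and F1 (reported as percentages) with the
#' diagnosis convention that ASD is the positive class. Zero
#' denominators: precision is 0 when there are no positive predictions,
#' and F1 is 0 when precision + recall is 0; both log a warning.
#'
#' @param preds,truth Character vectors of `"NC"`/`"ASD"`, equal length.
#' @return List: `accuracy`, `precision`, `f1` (percent), `n`,
#'   `confusion` (tp, fp, fn, tn).
#' @export
compute_metrics <- function(preds, truth) {
  if (length(preds) != length(truth)) {
    stop("preds and truth differ in length", call. = FALSE)
  }
  if (length(preds) == 0L) stop("no predictions to score", call. = FALSE)
  preds <- normalize_label(preds, "predictions")
  truth <- normalize_label(truth, "truth")
  tp <- sum(preds == "ASD" & truth == "ASD")
  fp <- sum(preds == "ASD" & truth == "NC")
  fn <- sum(preds == "NC" & truth == "ASD")
  tn <- sum(preds == "NC" & truth == "NC")
  n <- length(preds)
  accuracy <- (tp + tn) / n
  if (tp + fp == 0L) {
    warning("no positive predictions; precision set to 0", call. = FALSE)
    precision <- 0
  } else {
    precision <- tp / (tp + fp)
  }
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  if (precision + recall == 0) {
    warning("precision + recall is 0; F1 set to 0", call. = FALSE)
    f1 <- 0
  } else {
    f1 <- 2 * precision * recall / (precision + recall)
  }
  list(
    accuracy = accuracy * 100,
    precision = precision * 100,
    f1 = f1 * 100,
    n = n,
    confusion = list(tp = tp, fp = fp, fn = fn, tn = tn)
  )
}

#' Evaluate trained model on unseen target sites
#'
#' For each target site (all of which must be disjoint from the training
#' and baseline sites): optionally balance its classes, draw the support
#' set, fine-tune a fresh copy of the model on it against the baseline
#' prototypes, then classify the remaining query subjects by prototype
#' matching. Support subjects are audited out of the query set and never
#' scored.
#'
#' @param model A trained `siamese_model`.
#' @param targets List of target-site [site_dataset()]s.
#' @param baseline The baseline [site_dataset()].
#' @param protocol An [eval_protocol()].
#' @param training_site_ids Character vector of training-site ids used to
#'   enforce disjointness.
#' @return Metrics report: one entry per target site plus a
#'   `macro_average` row (unweighted mean of per-site accuracy, precision
#'   and F1) and a `predictions` data.frame (subject_id, site_id, truth,
#'   pred, output_nc, output_asd). The positive class is ASD.
#' @export
evaluate_target_sites <- function(model, targets, baseline, protocol,
                                  training_site_ids = character(0)) {
  target_ids <- vapply(targets, function(s) s$site_id, character(1))
  clash <- intersect(target_ids, c(training_site_ids, baseline$site_id))
  if (length(clash)) {
    stop(sprintf("target site(s) overlap training/baseline: %s",
                 paste(clash, collapse = ", ")), call. = FALSE)
  }
  per_site <- list()
  pred_rows <- list()
  for (site in targets) {
    s <- if (protocol$balance) balance_classes(site, protocol$rng_seed) else site
    sq <- sample_support(s, protocol$fine_tune_shots_per_class,
                         protocol$rng_seed)
    m_site <- fine_tune(model, sq$support, baseline, protocol)
    if (!is.null(sq$support) &&
        length(intersect(sq$support$subject_ids, sq$query$subject_ids))) {
      stop("support/query leak detected", call. = FALSE)   # defensive audit
    }
    protos <- compute_prototypes(m_site, baseline)
    det <- classify_batch(m_site, sq$query$features, protos, detail = TRUE)
    per_site[[site$site_id]] <- compute_metrics(det$pred, sq$query$labels)
    pred_rows[[site$site_id]] <- data.frame(
      subject_id = sq$query$subject_ids, site_id = site$site_id,
      truth = sq$query$labels, pred = det$pred,
      output_nc = det$output_nc, output_asd = det$output_asd,
      stringsAsFactors = FALSE
    )
  }
  macro <- list(
    accuracy = mean(vapply(per_site, `[[`, numeric(1), "accuracy")),
    precision = mean(vapply(per_site, `[[`, numeric(1), "precision")),
    f1 = mean(vapply(per_site, `[[`, numeric(1), "f1")),
    n = sum(vapply(per_site, `[[`, numeric(1), "n"))
  )
  c(per_site,
    list(macro_average = macro,
         positive_class = "ASD",
         predictions = do.call(rbind, pred_rows)))
}
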