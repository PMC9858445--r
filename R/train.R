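#' Stratified meta-train / meta-test split of one site
#'
#' Each class is shuffled (substream `"split"` combined with the site id)
#' and the first `round(fraction * n_class)` subjects go to meta-train,
#' the remainder to meta-test. Meta-test subjects are monitored during
#' training but never contribute to parameter updates.
#'
#' @param site A [site_dataset()].
#' @param fraction Meta-train fraction in (0, 1); default 0.7.
#' @param seed Run seed.
#' @return List with elements `meta_train` and `meta_test`, both
#'   [site_dataset()]s with disjoint subjects covering the input site.
#' @export
split_meta <- function(site, fraction = 0.7, seed = 1L) {
  stopifnot(inherits(site, "site_dataset"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  train_idx <- integer(0)
  for (klass in c("NC", "ASD")) {
    idx <- which(site$labels == klass)
    if (length(idx) > 0L && length(idx) < 2L) {
      stop(sprintf("site %s: class %s has fewer than 2 samples; cannot stratify",
                   site$site_id, klass), call. = FALSE)
    }
    if (length(idx) == 0L) next
    perm <- with_substream(seed, paste0("split_", site$site_id, "_", klass), {
      sample(idx)
    })
    n_train <- as.integer(floor(length(idx) * fraction + 0.5))
    train_idx <- c(train_idx, perm[seq_len(n_train)])
  }
  test_idx <- setdiff(seq_along(site$labels), train_idx)
  if (length(train_idx) == 0L || length(test_idx) == 0L) {
    stop(sprintf("site %s: split leaves an empty partition", site$site_id),
         call. = FALSE)
  }
  list(
    meta_train = site_subset(site, sort(train_idx)),
    meta_test = site_subset(site, sort(test_idx))
  )
}

#' Class prototypes from the baseline site
#'
#' The baseline site's NC and ASD samples are embedded with the current
#' model and averaged class-wise; these two mean embeddings act as the
#' one-shot class exemplars every other sample is compared against. The
#' prototypes carry the model version so downstream code can reject
#' prototypes computed under stale parameters.
#'
#' @param model A `siamese_model` with its standardizer set.
#' @param baseline A [site_dataset()] containing at least one sample per
#'   class.
#' @return List of class `prototype_pair`: `proto_nc`, `proto_asd`,
#'   `source_site`, `model_version`.
#' @export
compute_prototypes <- function(model, baseline) {
  stopifnot(inherits(model, "siamese_model"), inherits(baseline, "site_dataset"))
  counts <- class_counts(baseline)
  if (any(counts == 0L)) {
    stop(sprintf("baseline site %s lacks class %s",
                 baseline$site_id, names(counts)[counts == 0L][1]), call. = FALSE)
  }
  E <- forward_embed(model, baseline$features)
  structure(
    list(
      proto_nc = colMeans(E[baseline$labels == "NC", , drop = FALSE]),
      proto_asd = colMeans(E[baseline$labels == "ASD", , drop = FALSE]),
      source_site = baseline$site_id,
      model_version = model$version
    ),
    class = "prototype_pair"
  )
}

check_fresh <- function(model, protos) {
  if (!inherits(protos, "prototype_pair")) {
    stop("prototypes must be a prototype_pair", call. = FALSE)
  }
  if (protos$model_version != model$version) {
    stop("stale prototypes: recompute them under the current model parameters",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Pair losses (and gradients) of one batch of samples against the
# prototypes. Every sample forms two pairs: (sample, own-class prototype,
# y = 0) and (sample, other-class prototype, y = 1); the site loss is the
# mean over the 2n pairs. Gradients are returned with respect to the
# sample embeddings and both prototypes.
site_loss_internal <- function(model, E, labels, protos, with_grads = TRUE) {
  n <- nrow(E)
  d <- ncol(E)
  protom <- rbind(NC = protos$proto_nc, ASD = protos$proto_asd)
  a <- if (model$head_mode == "affine") model$head_a else 1
  loss_sum <- 0
  gE <- if (with_grads) matrix(0, n, d) else NULL
  gP <- if (with_grads) matrix(0, 2L, d, dimnames = list(c("NC", "ASD"), NULL)) else NULL
  gA <- 0
  gB <- 0
  denom <- 2 * n
  for (klass in c("NC", "ASD")) {
    diffs <- sweep(E, 2L, protom[klass, ])       # n x d, sample minus prototype
    dist <- rowSums(abs(diffs))
    out <- model_sigmoid(model, dist)
    y <- as.numeric(labels != klass)             # y = 0 for same-category pairs
    loss_sum <- loss_sum + sum(0.5 * (out - y)^2)
    if (with_grads) {
      dL_du <- (out - y) / denom * out * (1 - out)   # u = a * dist + b
      sg <- sign(diffs) * (dL_du * a)                # row-wise scaling
      gE <- gE + sg
      gP[klass, ] <- gP[klass, ] - colSums(sg)
      if (model$head_mode == "affine") {
        gA <- gA + sum(dL_du * dist)
        gB <- gB + sum(dL_du)
      }
    }
  }
  list(loss = loss_sum / denom, gE = gE, gP = gP, gA = gA, gB = gB)
}

#' Loss of one site's meta-training set against the baseline prototypes
#'
#' Each meta-training sample is paired with its own-class prototype
#' (same-category pair, y = 0) and the other-class prototype
#' (different-category pair, y = 1); the site loss is the mean pair loss
#' over all 2n pairs, so sites of different sizes weigh equally in the
#' summed total.
#'
#' @param model A `siamese_model`.
#' @param meta_train A non-empty [site_dataset()].
#' @param protos Fresh [compute_prototypes()] output for this model.
#' @return Mean pair loss (non-negative scalar).
#' @export
site_loss <- function(model, meta_train, protos) {
  stopifnot(inherits(meta_train, "site_dataset"))
  if (nrow(meta_train$features) == 0L) stop("empty meta-training set", call. = FALSE)
  check_fresh(model, protos)
  E <- forward_embed(model, meta_train$features)
  site_loss_internal(model, E, meta_train$labels, protos, with_grads = FALSE)$loss
}

#' Total loss across training sites
#'
#' The plain unweighted sum of the per-site losses (a sum, not a mean):
#' every training site contributes an independent objective and the
#' optimizer balances them jointly, which discourages overfitting to any
#' single site.
#'
#' @param per_site Numeric vector of per-site losses, length >= 1.
#' @return Their sum.
#' @export
total_loss <- function(per_site) {
  per_site <- as.numeric(per_site)
  if (length(per_site) == 0L) stop("no per-site losses given", call. = FALSE)
  sum(per_site)
}

zero_like_grads <- function(layers) {
  lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
}

add_grads <- function(acc, g) {
  for (l in seq_along(acc)) {
    acc[[l]]$W <- acc[[l]]$W + g[[l]]$W
    acc[[l]]$b <- acc[[l]]$b + g[[l]]$b
  }
  acc
}

apply_sgd <- function(layers, grads, lr) {
  for (l in seq_along(layers)) {
    layers[[l]]$W <- layers[[l]]$W - lr * grads[[l]]$W
    layers[[l]]$b <- layers[[l]]$b - lr * grads[[l]]$b
  }
  layers
}

# One full-batch gradient step over all training sites. Returns the
# updated model plus the per-site losses under the pre-step parameters.
train_step <- function(model, meta_trains, baseline, lr) {
  fw_base <- forward_embed(model, baseline$features, cache = TRUE)
  E_base <- fw_base$E
  protos <- structure(
    list(
      proto_nc = colMeans(E_base[baseline$labels == "NC", , drop = FALSE]),
      proto_asd = colMeans(E_base[baseline$labels == "ASD", , drop = FALSE]),
      source_site = baseline$site_id,
      model_version = model$version
    ),
    class = "prototype_pair"
  )
  grad_acc <- zero_like_grads(model$layers)
  dec_acc <- if (!is.null(model$dec_layers)) zero_like_grads(model$dec_layers) else NULL
  gP_total <- matrix(0, 2L, ncol(E_base), dimnames = list(c("NC", "ASD"), NULL))
  gA <- 0
  gB <- 0
  per_site <- numeric(length(meta_trains))
  names(per_site) <- vapply(meta_trains, function(s) s$site_id, character(1))
  recon_total <- 0
  for (k in seq_along(meta_trains)) {
    mt <- meta_trains[[k]]
    fw <- forward_embed(model, mt$features, cache = TRUE)
    sl <- site_loss_internal(model, fw$E, mt$labels, protos)
    per_site[k] <- sl$loss
    gP_total <- gP_total + sl$gP
    gA <- gA + sl$gA
    gB <- gB + sl$gB
    d_enc_extra <- NULL
    if (!is.null(model$dec_layers)) {
      dec <- decoder_loss_grads(model, fw)
      recon_total <- recon_total + model$recon_weight * dec$loss
      dec_acc <- add_grads(dec_acc, lapply(dec$grads, function(g) {
        list(W = model$recon_weight * g$W, b = model$recon_weight * g$b)
      }))
      d_enc_extra <- model$recon_weight * dec$dH
    }
    grad_acc <- add_grads(grad_acc, backward_embed(model, fw, sl$gE, d_enc_extra))
  }
  # prototype gradients flow back into the baseline embeddings
  dE_base <- matrix(0, nrow(E_base), ncol(E_base))
  for (klass in c("NC", "ASD")) {
    rows <- which(baseline$labels == klass)
    dE_base[rows, ] <- matrix(gP_total[klass, ] / length(rows),
                              length(rows), ncol(E_base), byrow = TRUE)
  }
  d_enc_extra_base <- NULL
  if (!is.null(model$dec_layers)) {
    dec <- decoder_loss_grads(model, fw_base)
    recon_total <- recon_total + model$recon_weight * dec$loss
    dec_acc <- add_grads(dec_acc, lapply(dec$grads, function(g) {
      list(W = model$recon_weight * g$W, b = model$recon_weight * g$b)
    }))
    d_enc_extra_base <- model$recon_weight * dec$dH
  }
  grad_acc <- add_grads(grad_acc,
                        backward_embed(model, fw_base, dE_base, d_enc_extra_base))
  model$layers <- apply_sgd(model$layers, grad_acc, lr)
  if (!is.null(model$dec_layers)) {
    model$dec_layers <- apply_sgd(model$dec_layers, dec_acc, lr)
  }
  if (model$head_mode == "affine") {
    model$head_a <- model$head_a - lr * gA
    model$head_b <- model$head_b - lr * gB
  }
  model$version <- model$version + 1L
  list(model = model, per_site = per_site, recon = recon_total)
}

#' Train the Siamese model against baseline-site prototypes
#'
#' The training objective sums one loss per training site (each the mean
#' pair loss of that site's meta-training samples against the baseline
#' prototypes) and minimizes it by full-batch gradient descent with
#' backpropagation; prototypes are recomputed from the current parameters
#' at every step. Meta-test accuracy per site is recorded every
#' `eval_interval` steps purely for monitoring — meta-test samples never
#' touch the gradients.
#'
#' @param config A [run_config()]; supplies the architecture, learning
#'   rate, iteration count, meta-train fraction and seed.
#' @param sites List of training-site [site_dataset()]s (the baseline
#'   must not be among them).
#' @param baseline The baseline [site_dataset()].
#' @return List of class `siamese_fit`: `model`, `history` (data.frame
#'   `step, site_id, loss, total`), `meta_eval` (data.frame of monitoring
#'   accuracies), `splits` (the per-site meta splits).
#' @export
train_siamese <- function(config, sites, baseline) {
  stopifnot(inherits(baseline, "site_dataset"))
  site_ids <- vapply(sites, function(s) s$site_id, character(1))
  if (baseline$site_id %in% site_ids) {
    stop("baseline site must not be among the training sites", call. = FALSE)
  }
  if (length(sites) < 1L) stop("at least one training site required", call. = FALSE)

  splits <- lapply(sites, split_meta, fraction = config$meta_train_fraction,
                   seed = config$rng_seed)
  names(splits) <- site_ids
  meta_trains <- lapply(splits, `[[`, "meta_train")

  spec <- encoder_spec(
    input_dim = ncol(baseline$features),
    encoder_widths = config$encoder_widths,
    head_widths = config$head_widths,
    embedding_dim = config$embedding_dim,
    activation = config$activation
  )
  model <- init_model(spec, seed = config$rng_seed, head_mode = config$head_mode,
                      recon_weight = config$recon_weight)
  model <- fit_standardizer(model, do.call(rbind, lapply(meta_trains,
                                                         function(s) s$features)))

  history <- vector("list", config$n_iterations)
  meta_eval <- list()
  for (step in seq_len(config$n_iterations)) {
    st <- train_step(model, meta_trains, baseline, config$learning_rate)
    model <- st$model
    tot <- total_loss(st$per_site)
    if (!is.finite(tot)) {
      stop(sprintf("training diverged at step %d (non-finite loss)", step),
           call. = FALSE)
    }
    history[[step]] <- data.frame(
      step = step, site_id = names(st$per_site),
      loss = as.numeric(st$per_site), total = tot,
      stringsAsFactors = FALSE, row.names = NULL
    )
    if (step %% config$eval_interval == 0L || step == config$n_iterations) {
      protos <- compute_prototypes(model, baseline)
      for (sid in site_ids) {
        mt <- splits[[sid]]$meta_test
        preds <- classify_batch(model, mt$features, protos)
        meta_eval[[length(meta_eval) + 1L]] <- data.frame(
          step = step, site_id = sid,
          accuracy = mean(preds == mt$labels) * 100,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(
    list(
      model = model,
      history = do.call(rbind, history),
      meta_eval = do.call(rbind, meta_eval),
      splits = splits,
      baseline_site = baseline$site_id
    ),
    class = "siamese_fit"
  )
}

#' @export
print.siamese_fit <- function(x, ...) {
  fin <- x$history[x$history$step == max(x$history$step), ]
  cat(sprintf(
    "<siamese_fit> baseline %s, %d training sites, %d steps; final total loss %.4f\n",
    x$baseline_site, length(unique(x$history$site_id)), max(x$history$step),
    fin$total[1]
  ))
  invisible(x)
}
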