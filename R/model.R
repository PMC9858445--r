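#' Encoder architecture specification
#'
#' The twin branches of the Siamese network are one shared feature
#' extractor: an autoencoder-style encoder (`encoder_widths`) followed by
#' fully connected layers (`head_widths`) ending in a linear
#' `embedding_dim` output. A mirrored decoder exists for an optional
#' reconstruction regularizer (off by default). The sizes are
#' configurable because no canonical widths exist for connectome input;
#' the defaults suit the 6670-dimensional 116-region feature vector.
#'
#' @param input_dim Feature dimension, `R(R-1)/2`.
#' @param encoder_widths Integer widths of the encoder half of the
#'   autoencoder.
#' @param head_widths Widths of additional fully connected layers between
#'   encoder output and embedding (may be empty).
#' @param embedding_dim Dimension of the embedding the L1 distance is
#'   computed in.
#' @param activation `"relu"` or `"tanh"`, applied after every layer
#'   except the final linear embedding layer.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(input_dim, encoder_widths = c(512L, 128L),
                         head_widths = integer(0), embedding_dim = 64L,
                         activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  spec <- list(
    input_dim = as.integer(input_dim),
    encoder_widths = as.integer(encoder_widths),
    head_widths = as.integer(head_widths),
    embedding_dim = as.integer(embedding_dim),
    activation = activation
  )
  if (spec$input_dim < 1L || any(spec$encoder_widths < 1L) ||
      any(spec$head_widths < 1L) || spec$embedding_dim < 1L) {
    stop("all layer widths must be >= 1", call. = FALSE)
  }
  structure(spec, class = "encoder_spec")
}

act_fun <- function(z, activation) {
  if (activation == "relu") pmax(z, 0) else tanh(z)
}

act_grad <- function(z, a, activation) {
  if (activation == "relu") (z > 0) * 1 else 1 - a^2
}

init_layer <- function(fan_in, fan_out) {
  lim <- 1 / sqrt(fan_in)
  list(
    W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
    b = rep(0, fan_out)
  )
}

#' Initialize a Siamese similarity model
#'
#' Parameters are drawn from the `"init"` substream of the given seed
#' (uniform fan-in scaling); two models initialized with the same spec
#' and seed are identical. The twin branches share these parameters by
#' construction: there is only one set.
#'
#' @param spec An [encoder_spec()].
#' @param seed Integer run seed.
#' @param head_mode `"literal"` maps the L1 distance through a plain
#'   sigmoid; `"affine"` uses `sigmoid(a * dist + b)` with `a`, `b`
#'   learned alongside the network so the output can span the full
#'   (0, 1) range.
#' @param recon_weight Weight of the autoencoder reconstruction penalty;
#'   0 (the default) disables the decoder path entirely.
#' @return An object of class `siamese_model`.
#' @export
init_model <- function(spec, seed = 1L, head_mode = c("literal", "affine"),
                       recon_weight = 0) {
  stopifnot(inherits(spec, "encoder_spec"))
  head_mode <- match.arg(head_mode)
  dims <- c(spec$input_dim, spec$encoder_widths, spec$head_widths,
            spec$embedding_dim)
  dec_dims <- if (recon_weight > 0 && length(spec$encoder_widths)) {
    c(spec$encoder_widths[length(spec$encoder_widths)],
      rev(spec$encoder_widths)[-1L], spec$input_dim)
  } else {
    NULL
  }
  model <- with_substream(seed, "init", {
    layers <- lapply(seq_len(length(dims) - 1L), function(l) {
      init_layer(dims[l], dims[l + 1L])
    })
    dec_layers <- if (!is.null(dec_dims)) {
      lapply(seq_len(length(dec_dims) - 1L), function(l) {
        init_layer(dec_dims[l], dec_dims[l + 1L])
      })
    } else {
      NULL
    }
    list(layers = layers, dec_layers = dec_layers)
  })
  structure(
    list(
      spec = spec,
      layers = model$layers,
      dec_layers = model$dec_layers,
      n_encoder_layers = length(spec$encoder_widths),
      head_mode = head_mode,
      head_a = 1,
      head_b = 0,
      recon_weight = as.numeric(recon_weight),
      standardize = NULL,
      version = 1L
    ),
    class = "siamese_model"
  )
}

#' @export
print.siamese_model <- function(x, ...) {
  dims <- c(x$spec$input_dim, x$spec$encoder_widths, x$spec$head_widths,
            x$spec$embedding_dim)
  cat(sprintf(
    "<siamese_model> %s, %s head, activation %s, version %d%s\n",
    paste(dims, collapse = "-"), x$head_mode, x$spec$activation, x$version,
    if (is.null(x$standardize)) " (standardizer unset)" else ""
  ))
  invisible(x)
}

#' Fit the feature standardizer from training data
#'
#' Embeddings are computed from per-feature z-scores; the mean/SD come
#' from the training sites only so that target-site statistics never leak
#' into the model. SDs below `1e-8` are floored to avoid division blowup
#' on constant features.
#'
#' @param model A [init_model()] result.
#' @param features Numeric matrix of training-site feature vectors (rows =
#'   subjects).
#' @return The model with standardization statistics set (a parameter
#'   change: the version is bumped).
#' @export
fit_standardizer <- function(model, features) {
  features <- as.matrix(features)
  stopifnot(ncol(features) == model$spec$input_dim)
  model$standardize <- list(
    mean = colMeans(features),
    sd = pmax(apply(features, 2L, stats::sd), 1e-8)
  )
  model$version <- model$version + 1L
  model
}

standardize_input <- function(model, X) {
  if (is.null(model$standardize)) return(X)
  sweep(sweep(X, 2L, model$standardize$mean, "-"), 2L,
        model$standardize$sd, "/")
}

# Forward pass through the shared branch. X: n x input_dim raw features.
# Returns embeddings (n x embedding_dim); with cache = TRUE also the
# per-layer activations needed for backprop.
forward_embed <- function(model, X, cache = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) != model$spec$input_dim) {
    stop(sprintf("feature dimension %d does not match model input %d",
                 ncol(X), model$spec$input_dim), call. = FALSE)
  }
  a <- standardize_input(model, X)
  acts <- list(a)
  preacts <- list()
  nl <- length(model$layers)
  for (l in seq_len(nl)) {
    z <- a %*% model$layers[[l]]$W +
      matrix(model$layers[[l]]$b, nrow(a), ncol(model$layers[[l]]$W), byrow = TRUE)
    a <- if (l < nl) act_fun(z, model$spec$activation) else z
    if (cache) {
      preacts[[l]] <- z
      acts[[l + 1L]] <- a
    }
  }
  if (cache) list(E = a, acts = acts, preacts = preacts) else a
}

# Backprop dL/dE through the shared branch; returns per-layer gradients
# (and dL/d(encoder output) so the decoder path can inject its term).
backward_embed <- function(model, fw, dE, d_enc_extra = NULL) {
  nl <- length(model$layers)
  grads <- vector("list", nl)
  delta <- dE
  for (l in rev(seq_len(nl))) {
    if (l < nl) {
      delta <- delta * act_grad(fw$preacts[[l]], fw$acts[[l + 1L]],
                                model$spec$activation)
    }
    if (!is.null(d_enc_extra) && l == model$n_encoder_layers) {
      # reconstruction gradient enters at the encoder output
      delta <- delta + d_enc_extra * act_grad(fw$preacts[[l]], fw$acts[[l + 1L]],
                                              model$spec$activation)
    }
    grads[[l]] <- list(
      W = crossprod(fw$acts[[l]], delta),
      b = colSums(delta)
    )
    if (l > 1L) delta <- delta %*% t(model$layers[[l]]$W)
  }
  grads
}

# Decoder forward/backward for the reconstruction regularizer. Input is
# the encoder-half output (activated); target is the standardized input.
decoder_loss_grads <- function(model, fw) {
  H <- fw$acts[[model$n_encoder_layers + 1L]]
  X0 <- fw$acts[[1L]]
  a <- H
  acts <- list(a)
  preacts <- list()
  nl <- length(model$dec_layers)
  for (l in seq_len(nl)) {
    z <- a %*% model$dec_layers[[l]]$W +
      matrix(model$dec_layers[[l]]$b, nrow(a), ncol(model$dec_layers[[l]]$W),
             byrow = TRUE)
    a <- if (l < nl) act_fun(z, model$spec$activation) else z
    preacts[[l]] <- z
    acts[[l + 1L]] <- a
  }
  resid <- a - X0
  loss <- mean(resid^2)
  delta <- 2 * resid / length(resid)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    if (l < nl) {
      delta <- delta * act_grad(preacts[[l]], acts[[l + 1L]],
                                model$spec$activation)
    }
    grads[[l]] <- list(W = crossprod(acts[[l]], delta), b = colSums(delta))
    delta <- delta %*% t(model$dec_layers[[l]]$W)
  }
  list(loss = loss, grads = grads, dH = delta)
}

#' Embed feature vectors with the shared branch
#'
#' Both members of any input pair pass through this same function with
#' the same parameters — parameter sharing is structural, not optional.
#'
#' @param model A `siamese_model`.
#' @param f A feature vector of length `input_dim`, or a matrix with one
#'   vector per row.
#' @return A numeric embedding vector, or a matrix of embeddings.
#' @export
embed <- function(model, f) {
  stopifnot(inherits(model, "siamese_model"))
  if (is.null(dim(f))) {
    drop(forward_embed(model, matrix(f, 1L)))
  } else {
    forward_embed(model, f)
  }
}

#' L1 distance between two embeddings
#'
#' @param e1,e2 Numeric vectors of equal length.
#' @return Sum of absolute coordinate differences (non-negative,
#'   symmetric, zero iff the embeddings coincide).
#' @export
l1_distance <- function(e1, e2) {
  if (length(e1) != length(e2)) {
    stop("embedding dimensions differ", call. = FALSE)
  }
  sum(abs(e1 - e2))
}

#' Map an embedding distance to a similarity score in (0, 1)
#'
#' Applies the logistic sigmoid to the (optionally affine-transformed)
#' distance. The sigmoid is monotone increasing in the distance, so a
#' LOWER output means MORE similar; with the default literal mapping
#' (`a = 1`, `b = 0`) the output of a non-negative distance lies in
#' `[0.5, 1)`.
#'
#' @param dist Non-negative distance.
#' @param a,b Affine head parameters; the literal mapping uses `a = 1`,
#'   `b = 0`.
#' @return Similarity score in (0, 1).
#' @export
similarity_output <- function(dist, a = 1, b = 0) {
  if (any(dist < 0)) stop("distance must be non-negative", call. = FALSE)
  1 / (1 + exp(-(a * dist + b)))
}

#' Mean-squared pair loss
#'
#' `0.5 * (output - y)^2` where `y = 0` marks a same-category pair and
#' `y = 1` a different-category pair.
#'
#' @param output Similarity score in (0, 1).
#' @param y Pair label, 0 or 1.
#' @return Non-negative loss.
#' @export
pair_loss <- function(output, y) {
  if (!all(y %in% c(0, 1))) stop("pair label y must be 0 or 1", call. = FALSE)
  0.5 * (output - y)^2
}

model_sigmoid <- function(model, dist) {
  if (model$head_mode == "affine") {
    similarity_output(dist, model$head_a, model$head_b)
  } else {
    similarity_output(dist)
  }
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file (format version 1) holding the
#' architecture spec, all parameter matrices, the head mode and affine
#' parameters, the standardization statistics and an optional config
#' hash. Numbers are written at full precision so load(save(m)) restores
#' the model exactly.
#'
#' @param model A `siamese_model`.
#' @param path Checkpoint path.
#' @param config_hash Optional opaque string recording the training
#'   configuration.
#' @export
save_model <- function(model, path, config_hash = NULL) {
  stopifnot(inherits(model, "siamese_model"))
  payload <- list(
    format = "siamfcn-checkpoint",
    format_version = 1L,
    spec = unclass(model$spec),
    layers = lapply(model$layers, function(l) {
      list(W = l$W, b = l$b)
    }),
    dec_layers = if (is.null(model$dec_layers)) NULL else {
      lapply(model$dec_layers, function(l) list(W = l$W, b = l$b))
    },
    head_mode = model$head_mode,
    head_a = model$head_a,
    head_b = model$head_b,
    recon_weight = model$recon_weight,
    standardize = model$standardize,
    version = model$version,
    config_hash = config_hash
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("checkpoint not found: %s", path), call. = FALSE)
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = TRUE)
  if (!identical(p$format, "siamfcn-checkpoint")) {
    stop("not a siamfcn checkpoint", call. = FALSE)
  }
  spec <- encoder_spec(p$spec$input_dim, p$spec$encoder_widths,
                       p$spec$head_widths %||% integer(0),
                       p$spec$embedding_dim, p$spec$activation)
  relayer <- function(ls) {
    lapply(ls, function(l) list(W = as.matrix(l$W), b = as.numeric(l$b)))
  }
  structure(
    list(
      spec = spec,
      layers = relayer(p$layers),
      dec_layers = if (length(p$dec_layers) == 0L) NULL else relayer(p$dec_layers),
      n_encoder_layers = length(spec$encoder_widths),
      head_mode = p$head_mode,
      head_a = as.numeric(p$head_a),
      head_b = as.numeric(p$head_b),
      recon_weight = as.numeric(p$recon_weight),
      standardize = if (length(p$standardize) == 0L) NULL else {
        list(mean = as.numeric(p$standardize$mean),
             sd = as.numeric(p$standardize$sd))
      },
      version = as.integer(p$version)
    ),
    class = "siamese_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
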