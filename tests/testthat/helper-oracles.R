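# Independent naive oracles and tiny fixture builders shared across tests.

# Textbook Pearson correlation with explicit loops; deliberately written
# without vectorized shortcuts so it stays independent of the package path.
naive_pearson <- function(x, y) {
  M <- length(x)
  mx <- 0
  my <- 0
  for (m in seq_len(M)) {
    mx <- mx + x[m] / M
    my <- my + y[m] / M
  }
  num <- 0
  dx <- 0
  dy <- 0
  for (m in seq_len(M)) {
    num <- num + (x[m] - mx) * (y[m] - my)
    dx <- dx + (x[m] - mx)^2
    dy <- dy + (y[m] - my)^2
  }
  num / sqrt(dx * dy)
}

# Loop-based dynamic FC: list of per-window correlation matrices.
naive_dfcn <- function(data, M, s) {
  T_len <- nrow(data)
  R <- ncol(data)
  K <- floor((T_len - M) / s) + 1
  out <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- ((k - 1) * s + 1):((k - 1) * s + M)
    fc <- diag(1, R)
    for (i in seq_len(R - 1)) {
      for (j in (i + 1):R) {
        r <- naive_pearson(data[rows, i], data[rows, j])
        fc[i, j] <- r
        fc[j, i] <- r
      }
    }
    out[[k]] <- fc
  }
  out
}

# Loop-based site loss: every sample against both prototypes, mean over
# the 2n pairs, using only the exported scalar operations.
naive_site_loss <- function(model, site, protos) {
  total <- 0
  n <- length(site$labels)
  for (i in seq_len(n)) {
    e <- embed(model, site$features[i, ])
    for (klass in c("NC", "ASD")) {
      proto <- if (klass == "NC") protos$proto_nc else protos$proto_asd
      y <- if (site$labels[i] == klass) 0 else 1
      total <- total + pair_loss(similarity_output(l1_distance(e, proto)), y)
    }
  }
  total / (2 * n)
}

# Random labelled site with standard-normal features.
random_site <- function(site_id, n_nc, n_asd, dim, seed) {
  set.seed(seed)
  n <- n_nc + n_asd
  site_dataset(
    site_id,
    matrix(rnorm(n * dim), n, dim),
    c(rep("NC", n_nc), rep("ASD", n_asd)),
    sprintf("%s_%02d", site_id, seq_len(n))
  )
}

# Small untrained model over `dim` features (single linear layer when
# widths are empty).
tiny_model <- function(dim, widths = c(8L), embedding = 4L, seed = 1L, ...) {
  init_model(
    encoder_spec(dim, encoder_widths = widths, head_widths = integer(0),
                 embedding_dim = embedding),
    seed = seed, ...
  )
}

# Desk-scale pipeline configuration for fast end-to-end tests.
tiny_benchmark <- function(seed = 1L, ...) {
  cfg <- benchmark_config(seed = seed, ...)
  cfg$sim$R <- 10L
  cfg$sim$T_len <- 60L
  cfg$sim$subjects_per_site_per_class <- 6L
  cfg$sim$n_sites <- 4L
  cfg$sim$n_affected_edges <- 10L
  cfg$run$n_regions <- 10L
  cfg$run$window_length <- 20L
  cfg$run$window_stride <- 5L
  cfg$run$encoder_widths <- c(16L)
  cfg$run$embedding_dim <- 8L
  cfg$run$n_iterations <- 60L
  cfg$run$eval_interval <- 20L
  cfg$run$fine_tune_steps <- 10L
  cfg$run$fine_tune_shots_per_class <- 2L
  cfg$run$baseline_site <- "SITE02"
  cfg$run$training_sites <- c("SITE00", "SITE01")
  cfg$run$target_sites <- "SITE03"
  cfg
}

# Memoized multi-seed benchmark runs shared by the acceptance checks.
.benchmark_cache <- new.env(parent = emptyenv())
cached_runs <- function(key, seeds, maker) {
  if (is.null(.benchmark_cache[[key]])) {
    .benchmark_cache[[key]] <- lapply(seeds, maker)
  }
  .benchmark_cache[[key]]
}
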