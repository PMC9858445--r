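test_that("twin embedding is deterministic and parameter-shared", {
  m <- tiny_model(6, seed = 3)
  set.seed(31)
  x <- rnorm(6)
  expect_identical(embed(m, x), embed(m, x))

  # both members of a pair go through the same function: a "branch" is
  # not an object that can diverge
  X <- rbind(x, x)
  E <- embed(m, X)
  expect_identical(E[1, ], E[2, ])

  m2 <- tiny_model(6, seed = 3)
  expect_identical(embed(m2, x), embed(m, x))   # seeded init reproducible
  m3 <- tiny_model(6, seed = 4)
  expect_false(identical(embed(m3, x), embed(m, x)))

  expect_error(embed(m, rnorm(5)), "dimension")
})

test_that("L1 distance is a symmetric metric on embeddings", {
  expect_equal(l1_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(l1_distance(c(1, 2), c(0, 4)), 3)
  expect_error(l1_distance(c(1, 2), c(1, 2, 3)), "dimension")

  set.seed(32)
  for (i in 1:100) {
    a <- rnorm(5); b <- rnorm(5); c <- rnorm(5)
    expect_identical(l1_distance(a, b), l1_distance(b, a))
    expect_gte(l1_distance(a, b) + l1_distance(b, c) - l1_distance(a, c), 0)
  }
})

test_that("sigmoid similarity head has the closed-form values and limits", {
  expect_equal(similarity_output(0), 0.5)
  expect_equal(similarity_output(log(3)), 0.75)
  expect_gt(similarity_output(50), 1 - 1e-10)
  expect_error(similarity_output(-0.1), "non-negative")

  # monotone: distance ordering and output ordering coincide
  d <- sort(runif(20, 0, 10))
  expect_true(all(diff(similarity_output(d)) > 0))
})

test_that("pair loss has its closed-form values and rejects bad labels", {
  expect_equal(pair_loss(0.5, 1), 0.125)
  expect_equal(pair_loss(0.5, 0), 0.125)
  expect_equal(pair_loss(0.9, 1), 0.005)
  expect_equal(pair_loss(0.3, 0), pair_loss(0.3, 0))
  expect_error(pair_loss(0.5, 0.5), "0 or 1")
})

test_that("loss is invariant to swapping the members of a pair", {
  m <- tiny_model(4, seed = 5)
  set.seed(33)
  a <- embed(m, rnorm(4))
  b <- embed(m, rnorm(4))
  expect_identical(pair_loss(similarity_output(l1_distance(a, b)), 1),
                   pair_loss(similarity_output(l1_distance(b, a)), 1))
})

# Analytic gradients recovered from one SGD step must match central
# finite differences of the objective (pair losses + optional
# reconstruction penalty, with prototypes recomputed under the perturbed
# parameters, exactly as during training).
objective_of <- function(model, sites, baseline) {
  protos <- compute_prototypes(model, baseline)
  obj <- sum(vapply(sites, function(s) site_loss(model, s, protos), numeric(1)))
  if (!is.null(model$dec_layers)) {
    for (s in c(sites, list(baseline))) {
      fw <- siamfcn:::forward_embed(model, s$features, cache = TRUE)
      obj <- obj + model$recon_weight * siamfcn:::decoder_loss_grads(model, fw)$loss
    }
  }
  obj
}

check_gradients <- function(model, sites, baseline, n_probe = 25, tol = 1e-6) {
  lr <- 1e-3
  stepped <- siamfcn:::train_step(model, sites, baseline, lr)$model
  set.seed(99)
  eps <- 1e-5
  for (probe in seq_len(n_probe)) {
    l <- sample(length(model$layers), 1)
    idx <- sample(length(model$layers[[l]]$W), 1)
    analytic <- (model$layers[[l]]$W[idx] - stepped$layers[[l]]$W[idx]) / lr
    mp <- mm <- model
    mp$layers[[l]]$W[idx] <- mp$layers[[l]]$W[idx] + eps
    mm$layers[[l]]$W[idx] <- mm$layers[[l]]$W[idx] - eps
    numeric_g <- (objective_of(mp, sites, baseline) -
                    objective_of(mm, sites, baseline)) / (2 * eps)
    expect_lt(abs(analytic - numeric_g), tol + 1e-4 * abs(numeric_g))
  }
  if (!is.null(model$dec_layers)) {
    for (probe in 1:10) {
      l <- sample(length(model$dec_layers), 1)
      idx <- sample(length(model$dec_layers[[l]]$W), 1)
      analytic <- (model$dec_layers[[l]]$W[idx] - stepped$dec_layers[[l]]$W[idx]) / lr
      mp <- mm <- model
      mp$dec_layers[[l]]$W[idx] <- mp$dec_layers[[l]]$W[idx] + eps
      mm$dec_layers[[l]]$W[idx] <- mm$dec_layers[[l]]$W[idx] - eps
      numeric_g <- (objective_of(mp, sites, baseline) -
                      objective_of(mm, sites, baseline)) / (2 * eps)
      expect_lt(abs(analytic - numeric_g), tol + 1e-4 * abs(numeric_g))
    }
  }
  if (model$head_mode == "affine") {
    for (field in c("head_a", "head_b")) {
      analytic <- (model[[field]] - stepped[[field]]) / lr
      mp <- mm <- model
      mp[[field]] <- mp[[field]] + eps
      mm[[field]] <- mm[[field]] - eps
      numeric_g <- (objective_of(mp, sites, baseline) -
                      objective_of(mm, sites, baseline)) / (2 * eps)
      expect_lt(abs(analytic - numeric_g), tol + 1e-4 * abs(numeric_g))
    }
  }
}

test_that("backpropagated gradients match finite differences", {
  dim <- 7
  sites <- list(random_site("A", 3, 3, dim, 41), random_site("B", 2, 4, dim, 42))
  baseline <- random_site("BASE", 3, 2, dim, 43)
  # tanh keeps the objective smooth at the probe points
  m <- init_model(encoder_spec(dim, c(6L), integer(0), 4L, activation = "tanh"),
                  seed = 7)
  m <- fit_standardizer(m, do.call(rbind, lapply(sites, `[[`, "features")))
  check_gradients(m, sites, baseline)
})

test_that("gradients stay exact with the affine head and reconstruction on", {
  dim <- 6
  sites <- list(random_site("A", 3, 3, dim, 44))
  baseline <- random_site("BASE", 2, 2, dim, 45)
  m <- init_model(encoder_spec(dim, c(5L, 4L), integer(0), 3L, activation = "tanh"),
                  seed = 8, head_mode = "affine", recon_weight = 0.1)
  m <- fit_standardizer(m, sites[[1]]$features)
  check_gradients(m, sites, baseline, n_probe = 20)
})

test_that("one gradient step pulls same-class pairs together only", {
  dim <- 5
  baseline <- random_site("BASE", 1, 1, dim, 46)
  m <- init_model(encoder_spec(dim, c(6L), integer(0), 3L, activation = "tanh"),
                  seed = 9)
  d_same <- function(model, x) {
    l1_distance(embed(model, x),
                embed(model, baseline$features[baseline$labels == "NC", ]))
  }
  d_diff <- function(model, x) {
    l1_distance(embed(model, x),
                embed(model, baseline$features[baseline$labels == "ASD", ]))
  }

  # generic NC sample: its same-class (y = 0) pair is pulled together
  x_site <- random_site("X", 1, 0, dim, 47)
  x <- x_site$features[1, ]
  m2 <- siamfcn:::train_step(m, list(x_site), baseline, lr = 0.01)$model
  expect_lt(d_same(m2, x), d_same(m, x))

  # NC sample coinciding with the NC exemplar: its y = 0 pair sits at the
  # loss's stationary point (zero distance), so the step is driven purely
  # by the different-class (y = 1) pair, which must not shrink
  x_at_proto <- site_dataset("XP",
                             baseline$features[baseline$labels == "NC", ,
                                               drop = FALSE],
                             "NC", "xp_01")
  xp <- x_at_proto$features[1, ]
  m3 <- siamfcn:::train_step(m, list(x_at_proto), baseline, lr = 0.01)$model
  expect_gte(d_diff(m3, xp), d_diff(m, xp))
  expect_equal(d_same(m3, xp), 0)
})

test_that("checkpoints restore the model exactly", {
  d <- withr::local_tempdir()
  m <- tiny_model(6, seed = 12, head_mode = "affine")
  m <- fit_standardizer(m, matrix(rnorm(60), 10, 6))
  p <- file.path(d, "model.json")
  save_model(m, p, config_hash = "abc123")
  back <- load_model(p)
  set.seed(34)
  X <- matrix(rnorm(30), 5, 6)
  expect_equal(embed(back, X), embed(m, X), tolerance = 1e-15)
  expect_equal(back$spec, m$spec)
  expect_equal(back$standardize, m$standardize)
  expect_equal(back$version, m$version)
  expect_error(load_model(file.path(d, "missing.json")))
})
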