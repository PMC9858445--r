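test_that("class balancing down-samples to the minority count", {
  site <- random_site("S", 12, 8, 4, 71)
  b <- balance_classes(site, seed = 1)
  expect_equal(unname(siamfcn:::class_counts(b)), c(8L, 8L))
  expect_true(all(b$subject_ids %in% site$subject_ids))

  b2 <- balance_classes(site, seed = 1)
  expect_identical(b$subject_ids, b2$subject_ids)     # seeded removal

  even <- random_site("E", 5, 5, 4, 72)
  expect_identical(balance_classes(even, seed = 1)$subject_ids,
                   even$subject_ids)

  only_nc <- random_site("N", 5, 0, 4, 73)
  expect_error(balance_classes(only_nc), "absent")
})

test_that("support sampling is disjoint from the query set", {
  site <- random_site("S", 10, 10, 4, 74)
  sq <- sample_support(site, 3, seed = 5)
  expect_equal(unname(siamfcn:::class_counts(sq$support)), c(3L, 3L))
  expect_length(intersect(sq$support$subject_ids, sq$query$subject_ids), 0L)
  expect_setequal(c(sq$support$subject_ids, sq$query$subject_ids),
                  site$subject_ids)

  z <- sample_support(site, 0)
  expect_null(z$support)
  expect_identical(z$query$subject_ids, site$subject_ids)

  expect_error(sample_support(site, 10, seed = 1), "only")
})

test_that("fine-tuning is a seeded no-op-safe parameter update", {
  cfg <- tiny_benchmark(seed = 4)
  by_site <- siamfcn:::split_by_site(
    features_for_sites(simulate_sites(cfg$sim), cfg$run))
  fit <- train_siamese(cfg$run, by_site[cfg$run$training_sites],
                       by_site[[cfg$run$baseline_site]])
  target <- by_site[["SITE03"]]
  sq <- sample_support(target, 2, seed = 1)
  base <- by_site[[cfg$run$baseline_site]]

  p0 <- eval_protocol(2, fine_tune_steps = 0)
  expect_identical(fine_tune(fit$model, sq$support, base, p0)$layers,
                   fit$model$layers)

  p <- eval_protocol(2, fine_tune_steps = 5, learning_rate = 0.01)
  m1 <- fine_tune(fit$model, sq$support, base, p)
  m2 <- fine_tune(fit$model, sq$support, base, p)
  expect_equal(m1$layers, m2$layers, tolerance = 1e-15)  # deterministic
  expect_false(identical(m1$layers, fit$model$layers))   # it did update
  expect_identical(fit$model$version + 5L, m1$version)   # input not mutated

  nc_only <- siamfcn:::site_subset(sq$support, sq$support$labels == "NC")
  expect_error(fine_tune(fit$model, nc_only, base, p), "both classes")
})

test_that("prototype matching predicts the nearer class, ties to ASD", {
  # identity embedding: one linear layer with unit weights
  m <- init_model(encoder_spec(2L, integer(0), integer(0), 2L), seed = 1)
  m$layers[[1]]$W <- diag(1, 2)
  m$layers[[1]]$b <- c(0, 0)
  base <- site_dataset("B", rbind(c(0, 0), c(1, 1)), c("NC", "ASD"),
                       c("b_nc", "b_asd"))
  protos <- compute_prototypes(m, base)
  expect_equal(classify_query(m, c(0, 0), protos), "NC")
  expect_equal(classify_query(m, c(1, 1), protos), "ASD")
  expect_equal(classify_query(m, c(0.5, 0.5), protos), "ASD")  # exact tie
})

test_that("metrics match hand values and a brute-force oracle", {
  all_ok <- compute_metrics(c("NC", "ASD", "NC", "ASD"),
                            c("NC", "ASD", "NC", "ASD"))
  expect_equal(all_ok$accuracy, 100)
  expect_equal(all_ok$precision, 100)
  expect_equal(all_ok$f1, 100)

  # tp=3 fp=1 fn=1 tn=5
  preds <- c(rep("ASD", 4), rep("NC", 6))
  truth <- c(rep("ASD", 3), "NC", "ASD", rep("NC", 5))
  mm <- compute_metrics(preds, truth)
  expect_equal(mm$accuracy, 80)
  expect_equal(mm$precision, 75)
  expect_equal(mm$f1, 75)
  expect_equal(mm$confusion, list(tp = 3L, fp = 1L, fn = 1L, tn = 5L))

  expect_warning(
    expect_warning(
      z <- compute_metrics(rep("NC", 4), c("NC", "ASD", "NC", "ASD")),
      "precision"
    ),
    "F1"
  )
  expect_equal(z$precision, 0)
  expect_equal(z$f1, 0)

  expect_error(compute_metrics(c("NC"), c("NC", "ASD")), "length")

  # randomized confusion tables against an independent tabulation
  set.seed(75)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    preds <- sample(c("NC", "ASD"), n, replace = TRUE)
    truth <- sample(c("NC", "ASD"), n, replace = TRUE)
    if (!any(preds == "ASD" & truth == "ASD")) next
    m <- suppressWarnings(compute_metrics(preds, truth))
    tab <- table(factor(preds, c("ASD", "NC")), factor(truth, c("ASD", "NC")))
    tp <- tab[1, 1]; fp <- tab[1, 2]; fn <- tab[2, 1]; tn <- tab[2, 2]
    expect_equal(m$accuracy, 100 * (tp + tn) / n)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    expect_equal(m$precision, 100 * prec)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    expect_equal(m$f1, 100 * f1)
  }
})

test_that("target-site evaluation isolates support subjects and sites", {
  cfg <- tiny_benchmark(seed = 5)
  by_site <- siamfcn:::split_by_site(
    features_for_sites(simulate_sites(cfg$sim), cfg$run))
  fit <- train_siamese(cfg$run, by_site[cfg$run$training_sites],
                       by_site[[cfg$run$baseline_site]])
  protocol <- eval_protocol(2, fine_tune_steps = 5, learning_rate = 0.01,
                            rng_seed = 5)

  expect_error(
    evaluate_target_sites(fit$model, by_site["SITE00"],
                          by_site[[cfg$run$baseline_site]], protocol,
                          training_site_ids = cfg$run$training_sites),
    "overlap"
  )

  rep1 <- evaluate_target_sites(fit$model, by_site["SITE03"],
                                by_site[[cfg$run$baseline_site]], protocol,
                                training_site_ids = cfg$run$training_sites)
  # support subjects are never scored
  target <- balance_classes(by_site[["SITE03"]], protocol$rng_seed)
  sq <- sample_support(target, 2, protocol$rng_seed)
  expect_length(intersect(rep1$predictions$subject_id,
                          sq$support$subject_ids), 0L)
  expect_equal(rep1$SITE03$n, nrow(rep1$predictions))
  expect_equal(rep1$macro_average$accuracy, rep1$SITE03$accuracy)

  rep2 <- evaluate_target_sites(fit$model, by_site["SITE03"],
                                by_site[[cfg$run$baseline_site]], protocol,
                                training_site_ids = cfg$run$training_sites)
  expect_equal(rep1, rep2, tolerance = 1e-15)     # seeded end to end
})

test_that("prototype matching beats site-blind pooling under strong heterogeneity", {
  # reproduces the comparison-protocol structure: train on 4 sites + the
  # baseline, test on 2 disjoint targets; pooling ignores site structure.
  # Heterogeneity is set high enough (edge SD 0.35) that pooled class
  # means blur across sites.
  res <- t(vapply(1:10, function(s) {
    cfg <- benchmark_config(seed = s, site_effect_sd = 0.35)
    by_site <- siamfcn:::split_by_site(
      features_for_sites(simulate_sites(cfg$sim), cfg$run))
    pooled_ids <- c(cfg$run$training_sites, cfg$run$baseline_site)
    nm <- nearest_mean_baseline(by_site[pooled_ids],
                                by_site[cfg$run$target_sites])
    fit <- train_siamese(cfg$run, by_site[cfg$run$training_sites],
                         by_site[[cfg$run$baseline_site]])
    pr <- eval_protocol(5, 50, learning_rate = cfg$run$learning_rate,
                        rng_seed = s)
    ev <- evaluate_target_sites(fit$model, by_site[cfg$run$target_sites],
                                by_site[[cfg$run$baseline_site]], pr,
                                cfg$run$training_sites)
    c(ours = ev$macro_average$accuracy, pooled = nm$macro_average$accuracy)
  }, numeric(2)))
  expect_gt(median(res[, "ours"]), median(res[, "pooled"]))
})
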