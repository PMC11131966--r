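test_that("the mixture recovers three separated blobs with a bijective mapping", {
  bl <- blob_features(seed = 1)
  fit <- fr_classify(bl$features, seed = 1)
  expect_setequal(fit$mapping, c("specialist", "niche", "essential"))
  pred <- predict(fit, bl$features)
  expect_equal(pred$assigned_type, bl$labels)
  expect_true(all(abs(rowSums(pred[, c("p_specialist", "p_niche", "p_essential")]) - 1)
                  < 1e-9))
  ## assigned type is always the posterior argmax
  post <- as.matrix(pred[, c("p_specialist", "p_niche", "p_essential")])
  expect_equal(pred$assigned_type,
               c("specialist", "niche", "essential")[max.col(post)])
  ## determinism under a fixed seed
  fit2 <- fr_classify(bl$features, seed = 1)
  expect_equal(fit$model$mean, fit2$model$mean, tolerance = 1e-12)
})

test_that("mixture fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust needs its namespace attached
  bl <- blob_features(seed = 2)
  fit <- fr_classify(bl$features, seed = 1)
  ref <- mclust::Mclust(bl$features, G = 3, modelNames = "VVV",
                        verbose = FALSE)
  ## same partition of the points (component labels may permute)
  ours <- predict(fit, bl$features)$assigned_type
  tab <- table(ours, ref$classification)
  expect_equal(sum(apply(tab, 2, max)), length(ours))
})

test_that("component-to-type mapping follows the canonical geometry", {
  cent <- rbind(c(0.02, 0.01), c(0.3, 0.02), c(0.25, 0.22))
  expect_equal(map_components_to_types(cent),
               c("specialist", "niche", "essential"))
  ## permuting components permutes the mapping consistently
  perm <- c(3, 1, 2)
  expect_equal(map_components_to_types(cent[perm, ]),
               c("specialist", "niche", "essential")[perm])
  ## collinear but distinct centroids still map bijectively
  col3 <- rbind(c(0, 0), c(0.3, 0.1), c(0.6, 0.2))
  expect_setequal(map_components_to_types(col3),
                  c("specialist", "niche", "essential"))
  expect_error(map_components_to_types(rbind(c(0, 0), c(0, 0), c(1, 1))),
               "coincident")
})

test_that("points at a component mean take that component's type", {
  bl <- blob_features(seed = 3)
  fit <- fr_classify(bl$features, seed = 1)
  pred <- predict(fit, fit$model$mean)
  expect_equal(pred$assigned_type, fit$mapping)
  ## empty input gives an empty, well-formed table
  empty <- predict(fit, bl$features[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("function_id", "assigned_type", "p_specialist",
                        "p_niche", "p_essential"))
})

test_that("the two-species example is classified by a geometry-faithful reference", {
  bl <- blob_features(seed = 4)
  fit <- fr_classify(bl$features, seed = 1)
  fx <- two_species_example()
  m <- function_metrics(fx$paired)
  pred <- predict(fit, m)
  got <- setNames(pred$assigned_type, pred$function_id)
  expect_equal(got[["red"]], "niche")
  expect_equal(got[["green"]], "essential")
  expect_equal(got[["blue"]], "specialist")
})

test_that("k-means classification is hard, pure on blobs, and duplicate-stable", {
  bl <- blob_features(seed = 5)
  fit <- fr_classify(bl$features, method = "kmeans", seed = 1)
  pred <- predict(fit, bl$features)
  expect_equal(pred$assigned_type, bl$labels)
  post <- as.matrix(pred[, 3:5])
  expect_true(all(post %in% c(0, 1)))
  ## duplicated data: identical assignment per duplicate
  dup <- rbind(bl$features, bl$features)
  pd <- predict(fit, dup)
  expect_equal(pd$assigned_type[1:60], pd$assigned_type[61:120])
  expect_error(fr_classify(matrix(c(0, 0, 0, 0, 1, 1), 3, 2, byrow = TRUE),
                           method = "kmeans"), "distinct")
})

test_that("QDA matches a literal density-evaluation oracle", {
  bl <- blob_features(seed = 6)
  fit <- fr_classify(bl$features, labels = bl$labels, method = "qda", seed = 1)
  pred <- predict(fit, bl$features)
  ## training points predicted as their own class in the separable case
  expect_equal(pred$assigned_type, bl$labels)
  ## oracle: per-class Gaussian log densities evaluated directly
  dens <- vapply(split(seq_len(60), bl$labels), function(ix) {
    mu <- colMeans(bl$features[ix, ])
    S <- stats::cov(bl$features[ix, ])
    xc <- sweep(bl$features, 2, mu)
    -0.5 * (rowSums((xc %*% solve(S)) * xc) + log(det(S))) +
      log(length(ix) / 60)
  }, numeric(60))
  oracle <- colnames(dens)[max.col(dens)]
  expect_equal(pred$assigned_type, oracle)
})

test_that("QDA boundary sits midway between symmetric equal-covariance classes", {
  set.seed(1)
  a <- cbind(rnorm(60, 0, 0.1), rnorm(60, 0, 0.1))
  b <- cbind(rnorm(60, 1, 0.1), rnorm(60, 0, 0.1))
  c3 <- cbind(rnorm(60, 0.5, 0.1), rnorm(60, 5, 0.1))
  fit <- fr_classify(rbind(a, b, c3),
                     labels = rep(c("specialist", "niche", "essential"),
                                  each = 60),
                     method = "qda", seed = 1)
  near <- predict(fit, rbind(c(0.4, 0), c(0.6, 0)))
  expect_equal(near$assigned_type, c("specialist", "niche"))
})

test_that("QDA survives a singular class covariance via the ridge fallback", {
  x <- rbind(matrix(0, 10, 2),                       # degenerate class
             cbind(rnorm(10, 1, 0.05), rnorm(10, 0, 0.05)),
             cbind(rnorm(10, 1, 0.05), rnorm(10, 1, 0.05)))
  labs <- rep(c("specialist", "niche", "essential"), each = 10)
  fit <- fr_classify(x, labels = labs, method = "qda", seed = 1)
  pred <- predict(fit, x)
  expect_equal(pred$assigned_type, labs)
})

test_that("accuracy scoring reproduces count arithmetic and exclusions", {
  mk <- function(fam, n, n_ok, truth) {
    data.frame(
      function_id = sprintf("%s_%03d", gsub("[^A-Za-z]", "", fam), seq_len(n)),
      family = fam,
      assigned_type = c(rep(truth, n_ok),
                        rep(setdiff(c("specialist", "niche", "essential"),
                                    truth)[1], n - n_ok)),
      stringsAsFactors = FALSE)
  }
  d <- rbind(mk("ABC-type transporter", 53, 26, "niche"),
             mk("ribosomal protein", 53, 44, "essential"),
             mk("PTS", 16, 11, "specialist"))
  acc <- evaluate_accuracy(d[, c("function_id", "assigned_type")],
                           d[, c("function_id", "family")])
  expect_equal(acc$n_correct, 81)
  expect_equal(acc$n_total, 122)
  expect_equal(acc$accuracy, 81 / 122, tolerance = 1e-12)
  rib <- acc$per_family[acc$per_family$family == "ribosomal protein", ]
  expect_equal(rib$accuracy, 44 / 53, tolerance = 1e-12)
  ## unknown-function families are classified but not scored
  d2 <- rbind(d, mk("S: Function Unknown", 10, 0, "niche"))
  acc2 <- evaluate_accuracy(d2[, c("function_id", "assigned_type")],
                            d2[, c("function_id", "family")])
  expect_equal(acc2$n_total, 122)
  ## all correct and empty-set behaviour
  all_ok <- mk("PTS", 5, 5, "specialist")
  expect_equal(evaluate_accuracy(all_ok[, c("function_id", "assigned_type")],
                                 all_ok[, c("function_id", "family")])$accuracy, 1)
  none <- mk("S: Function Unknown", 4, 0, "niche")
  expect_error(evaluate_accuracy(none[, c("function_id", "assigned_type")],
                                 none[, c("function_id", "family")]),
               "no annotated functions")
})

test_that("degenerate or malformed inputs are rejected", {
  same <- matrix(0.3, 10, 2)
  expect_error(fr_classify(same), "degenerate")
  expect_error(fr_classify(blob_features()$features, labels = rep("x", 60)),
               "unknown labels")
  bl <- blob_features()
  expect_error(fr_classify(bl$features, labels = bl$labels[1:10]),
               "one entry per row")
  expect_error(fr_classify(bl$features[, 1, drop = FALSE]), "two columns")
  expect_error(fr_classify(bl$features, method = "qda"), "supervised")
})
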