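make_blobs <- function(n_per, centers, sd = 0.02, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  list(x = x, y = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("codebook with k = n reproduces the inputs", {
  set.seed(21)
  x <- matrix(runif(5 * 10), 5, 10)
  cb <- build_codebook(x, k = 5, seed = 3)
  # every input is its own centroid, in some order
  d2 <- unname(as.matrix(dist(rbind(x, cb$words)))[1:5, 6:10])
  expect_equal(sort(apply(d2, 1, min)), rep(0, 5), tolerance = 1e-12)
  expect_error(build_codebook(x, k = 6), class = "shgbof_insufficient_data")
  expect_error(build_codebook(x, k = 1), class = "shgbof_invalid_parameter")
})

test_that("codebook centroids recover well-separated blob means", {
  b <- make_blobs(200, rbind(c(0, 0, 0), c(1, 1, 1)), sd = 0.05, seed = 7)
  cb <- build_codebook(b$x, k = 2, seed = 5)
  ord <- order(rowSums(cb$words))
  m1 <- colMeans(b$x[b$y == 1, ]); m2 <- colMeans(b$x[b$y == 2, ])
  tol <- 3 * 0.05 / sqrt(200)
  expect_true(all(abs(cb$words[ord[1], ] - m1) < tol))
  expect_true(all(abs(cb$words[ord[2], ] - m2) < tol))
})

test_that("codebook construction is deterministic given (inputs, k, seed)", {
  set.seed(13)
  x <- matrix(runif(300), 50, 6)
  cb1 <- build_codebook(x, k = 4, seed = 99)
  cb2 <- build_codebook(x, k = 4, seed = 99)
  expect_identical(cb1$words, cb2$words)
})

test_that("term vectors are normalized nearest-word histograms", {
  words <- diag(4)
  cb <- structure(list(words = words, k = 4L, seed = 1L),
                  class = "shg_codebook")
  # features all nearest to word 3 -> one-hot
  f <- matrix(rep(c(0.1, 0.1, 0.9, 0.1), 5), 5, 4, byrow = TRUE)
  expect_equal(term_vector(f, cb), c(0, 0, 1, 0))
  # mixed assignment sums to 1
  f2 <- rbind(f, matrix(rep(c(0.9, 0, 0, 0), 3), 3, 4, byrow = TRUE))
  tv <- term_vector(f2, cb)
  expect_equal(sum(tv), 1)
  expect_equal(tv, c(3, 0, 5, 0) / 8)
  # equidistant features go to the lowest word index
  tie <- matrix(0.5, 1, 4)
  expect_equal(term_vector(tie, cb), c(1, 0, 0, 0))
  # zero-signal image is an error
  expect_error(term_vector(matrix(0L, 128, 128), cb),
               class = "shgbof_no_signal")
})

test_that("linear SVM separates one-hot term vectors perfectly", {
  b <- make_blobs(10, rbind(c(1, 0, 0), c(0, 1, 0)), sd = 0.05, seed = 3)
  labels <- factor(c("A", "B")[b$y])
  clf <- train_classifier(b$x, labels)
  expect_equal(predict(clf, b$x), labels)
  # permuting the sample order leaves predictions unchanged
  set.seed(8); perm <- sample(nrow(b$x))
  clf2 <- train_classifier(b$x[perm, ], labels[perm])
  expect_equal(predict(clf2, b$x), predict(clf, b$x))
  expect_error(train_classifier(b$x, factor(rep("A", 20))),
               class = "shgbof_degenerate_training")
  expect_error(train_classifier(b$x, factor(c("A", rep("B", 19)))),
               class = "shgbof_degenerate_training")
})

test_that("one-vs-one ECOC handles the ternary task", {
  b <- make_blobs(12, rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  sd = 0.05, seed = 5)
  labels <- factor(c("Hyaline", "Fibrous", "Bone")[b$y],
                   levels = c("Hyaline", "Fibrous", "Bone"))
  clf <- train_classifier(b$x, labels)
  expect_length(clf$fits, 3)  # 3 pairwise learners
  expect_equal(predict(clf, b$x), labels)
})

test_that("predict_image returns a training label and flags no-signal", {
  ds <- fixture_dataset("mini2", 4, c("Cartilage", "Bone"), size = 192,
                        seed = 77)
  feats <- do.call(rbind, dataset_features(ds, 64))
  cb <- build_codebook(feats, k = 3, seed = 2)
  tv <- t(sapply(ds$images, function(im) term_vector(im, cb)))
  clf <- train_classifier(tv, ds$labels)
  lab <- predict_image(ds$images[[1]], cb, clf)
  expect_true(lab %in% levels(ds$labels))
  expect_error(predict_image(matrix(0L, 128, 128), cb, clf),
               class = "shgbof_no_signal")
})

test_that("stratified folds partition every class across runs", {
  labels <- factor(rep(c("A", "B"), c(9, 7)))
  fold <- shgbof:::make_folds(labels, 4, seed = 3)
  expect_setequal(unique(fold), 1:4)
  for (r in 1:4) {
    expect_gte(sum(fold == r & labels == "A"), 2)
    expect_gte(sum(fold == r & labels == "B"), 1)
  }
  expect_error(shgbof:::make_folds(factor(rep(c("A", "B"), c(9, 3))), 4, 1),
               class = "shgbof_fold_error")
})

test_that("evaluate_runs gives the identity matrix on separable data", {
  ds <- fixture_dataset("mini2", 4, c("Cartilage", "Bone"), size = 192,
                        seed = 77)
  feats <- fixture_features("mini2", ds, 64)
  cm <- evaluate_runs(ds, k = 3, g = 64, n_runs = 4, seed = 5,
                      features = feats)
  expect_equal(rowSums(cm$p), c(Cartilage = 1, Bone = 1))
  expect_equal(unname(diag(cm$p)), c(1, 1))
  expect_equal(cm$accuracy, 1)
})

test_that("permuted labels give chance-level accuracy", {
  ds <- fixture_dataset("mini2", 4, c("Cartilage", "Bone"), size = 192,
                        seed = 77)
  feats <- fixture_features("mini2", ds, 64)
  accs <- sapply(1:6, function(s) {
    set.seed(s)
    perm <- ds
    perm$labels <- sample(ds$labels)
    evaluate_runs(perm, k = 3, g = 64, n_runs = 4, seed = s,
                  features = feats)$accuracy
  })
  # binomial error around 0.5 with 8 test images x 6 permutations
  expect_lt(abs(mean(accs) - 0.5), 0.25)
})

test_that("evaluation is deterministic and modes differ only by vocabulary", {
  ds <- fixture_dataset("mini2", 4, c("Cartilage", "Bone"), size = 192,
                        seed = 77)
  feats <- fixture_features("mini2", ds, 64)
  a <- evaluate_runs(ds, k = 3, g = 64, n_runs = 4, seed = 11,
                     features = feats)
  b <- evaluate_runs(ds, k = 3, g = 64, n_runs = 4, seed = 11,
                     features = feats)
  expect_identical(a$p, b$p)
  expect_identical(a$per_run, b$per_run)
  p <- evaluate_runs(ds, k = 3, g = 64, n_runs = 4, seed = 11,
                     vocabulary_mode = "paper", features = feats)
  expect_equal(rowSums(p$p), c(Cartilage = 1, Bone = 1))
})

test_that("strict vocabulary mode never clusters test-fold features", {
  # instrument by replacing one image's features with a unique constant
  # vector: in strict mode no codebook word can sit near it when that image
  # is in the test fold
  ds <- fixture_dataset("mini2", 4, c("Cartilage", "Bone"), size = 192,
                        seed = 77)
  feats <- fixture_features("mini2", ds, 64)
  marker <- matrix(1000, 1, 352)
  fold <- shgbof:::make_folds(ds$labels, 4, seed = 11)
  victim <- which(fold == 1)[1]
  feats2 <- feats
  feats2[[victim]] <- marker
  labels <- ds$labels
  train_idx <- which(fold != 1)
  cb_strict <- build_codebook(do.call(rbind, feats2[train_idx]), 3,
                              seed = shgbof:::derive_seed(11, "run1"))
  expect_gt(min(sqrt(rowSums((sweep(cb_strict$words, 2,
                                    as.numeric(marker)))^2))), 100)
})

test_that("parameter_sweep is reproducible plumbing over (k, g)", {
  ds <- fixture_dataset("mini2", 4, c("Cartilage", "Bone"), size = 192,
                        seed = 77)
  sw1 <- parameter_sweep(ds, k_values = c(3, 4), g_values = 64,
                         n_runs = 4, seed = 2)
  sw2 <- parameter_sweep(ds, k_values = c(3, 4), g_values = 64,
                         n_runs = 4, seed = 2)
  expect_equal(nrow(sw1$table), 2)
  expect_identical(sw1$table, sw2$table)
  expect_named(sw1$matrices, c("k3_g64", "k4_g64"))
  expect_true(all(abs(rowSums(sw1$matrices$k3_g64$p) - 1) < 1e-6))
})
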