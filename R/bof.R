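## Bag-of-Features pipeline: k-means codebook of 352-dim patch descriptors,
## nearest-word term vectors, linear soft-margin SVM (one-vs-one ECOC for
## three classes), multi-run confusion-matrix evaluation.

# Squared Euclidean distances between rows of x and rows of centers.
cross_dist2 <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  pmax(d2, 0)
}

# k-means++ seeding (Arthur & Vassilvitskii); deterministic given the RNG
# state; refuses to seed from coincident points so initial centers are
# distinct. BLAS-backed distance updates keep this O(nk) in matrix ops.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  xx <- rowSums(x^2)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- pmax(xx - 2 * drop(x %*% centers[1, ]) + sum(centers[1, ]^2), 0)
  for (j in 2:k) {
    if (all(d2 <= 0))
      stop_shg("shgbof_insufficient_data",
               "fewer than k distinct feature vectors")
    pick <- sample.int(n, 1, prob = d2 / sum(d2))
    cj <- x[pick, ]
    centers[j, ] <- cj
    d2 <- pmin(d2, pmax(xx - 2 * drop(x %*% cj) + sum(cj^2), 0))
  }
  centers
}

# Lloyd iterations with nearest-centroid assignment (lowest index on ties)
# and empty clusters keeping their previous centroid. Deterministic given
# the initial centers; stops when assignments stabilize.
lloyd_kmeans <- function(x, centers, iter_max = 100L) {
  assign_prev <- NULL
  for (it in seq_len(iter_max)) {
    d2 <- cross_dist2(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    sums <- rowsum(x, assign)
    counts <- tabulate(assign, nrow(centers))
    occupied <- counts > 0
    centers[occupied, ] <- sums[as.character(which(occupied)), ,
                                drop = FALSE] / counts[occupied]
  }
  d2 <- cross_dist2(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  list(centers = centers, cluster = assign,
       tot_withinss = sum(d2[cbind(seq_len(nrow(x)), assign)]))
}

#' Build a visual-word codebook
#'
#' Clusters patch feature vectors with k-means (k-means++ seeding, Lloyd
#' iterations, 10 restarts, best within-cluster sum of squares kept). The
#' result is deterministic for a fixed (features, k, seed).
#'
#' @param features Numeric matrix, one feature vector per row (>= k rows).
#' @param k Codebook size (number of visual words), >= 2.
#' @param seed Integer seed controlling seeding and restarts.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return Object of class `shg_codebook`: list with `words` (k x p matrix),
#'   `k`, `seed`.
#' @export
build_codebook <- function(features, k, seed = 1L, restarts = 10L) {
  features <- as.matrix(features)
  if (k < 2) stop_shg("shgbof_invalid_parameter", "k must be >= 2")
  if (nrow(features) < k)
    stop_shg("shgbof_insufficient_data",
             "need at least k = %d feature vectors, got %d", k,
             nrow(features))
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, paste0("kmeans", r)))
    fit <- tryCatch(
      lloyd_kmeans(features, kmeanspp_init(features, k)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  if (is.null(best))
    stop_shg("shgbof_insufficient_data",
             "k-means failed on every restart (degenerate features?)")
  words <- unname(best$centers)
  structure(list(words = words, k = as.integer(k), seed = as.integer(seed)),
            class = "shg_codebook")
}

# Nearest-word index per feature row; ties break to the lowest word index
# (max.col ties.method "first" on negated distances).
assign_words <- function(features, codebook) {
  d2 <- cross_dist2(as.matrix(features), codebook$words)
  max.col(-d2, ties.method = "first")
}

#' Term vector of an image
#'
#' Assigns every signal patch of the image to its nearest visual word
#' (Euclidean distance, lowest index on ties) and returns the normalized
#' word-occurrence histogram.
#'
#' @param image Image (matrix or `shg_image`), or a precomputed feature
#'   matrix from [image_features()].
#' @param codebook `shg_codebook`.
#' @param grid_step Grid step used for patch extraction when `image` is an
#'   image.
#' @param config [glcm_config()].
#' @return Numeric vector of length k summing to 1.
#' @export
term_vector <- function(image, codebook, grid_step = 64L,
                        config = glcm_config()) {
  feats <- if (is.matrix(image) && is.double(image) &&
               ncol(image) == ncol(codebook$words)) image
           else image_features(image, grid_step, config)
  if (nrow(feats) == 0)
    stop_shg("shgbof_no_signal", "image has no signal patches")
  counts <- tabulate(assign_words(feats, codebook), codebook$k)
  counts / sum(counts)
}

## ---- linear soft-margin SVM (dual coordinate descent) ----------------------
## L2-regularized L1-loss SVM in the dual (Hsieh et al. 2008, Algorithm 3)
## with a bias handled by feature augmentation. Fixed sweep order makes the
## fit deterministic and invariant to sample permutation up to the order of
## support-vector updates; tests assert prediction invariance.

svm_fit_binary <- function(x, y, cost = 1, tol = 1e-6, max_epochs = 500L) {
  x <- cbind(x, 1)                       # bias
  n <- nrow(x)
  qii <- rowSums(x^2)
  alpha <- numeric(n)
  w <- numeric(ncol(x))
  for (ep in seq_len(max_epochs)) {
    max_pg <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * x[i, ]) - 1
      pg <- g
      if (alpha[i] <= 0) pg <- min(g, 0)
      if (alpha[i] >= cost) pg <- max(g, 0)
      if (abs(pg) > 1e-14) {
        a_new <- min(max(alpha[i] - g / qii[i], 0), cost)
        w <- w + (a_new - alpha[i]) * y[i] * x[i, ]
        alpha[i] <- a_new
      }
      max_pg <- max(max_pg, abs(pg))
    }
    if (max_pg < tol) break
  }
  w
}

svm_decision <- function(w, x) as.numeric(cbind(x, 1) %*% w)

#' Train the term-vector classifier
#'
#' Two classes: a single linear soft-margin support-vector classifier
#' (unit box constraint, term vectors used as-is). Three or more classes:
#' one-vs-one error-correcting output codes over linear SV binary learners,
#' decoded by vote with ties broken toward the lowest class index. The fit
#' is deterministic given the inputs.
#'
#' @param term_vectors Matrix, one term vector per row.
#' @param labels Factor (or character) of class labels, >= 2 classes with
#'   >= 2 samples each.
#' @param cost Soft-margin cost C (default 1).
#' @return Object of class `shg_classifier`.
#' @export
train_classifier <- function(term_vectors, labels, cost = 1) {
  x <- as.matrix(term_vectors)
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  classes <- levels(labels)
  if (length(classes) < 2)
    stop_shg("shgbof_degenerate_training", "need >= 2 classes, got %d",
             length(classes))
  if (any(table(labels) < 2))
    stop_shg("shgbof_degenerate_training",
             "every class needs >= 2 training samples")
  pairs <- utils::combn(length(classes), 2)
  fits <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sel <- labels %in% classes[c(a, b)]
    yy <- ifelse(labels[sel] == classes[a], 1, -1)
    list(a = a, b = b, w = svm_fit_binary(x[sel, , drop = FALSE], yy,
                                          cost = cost))
  })
  structure(list(classes = classes, fits = fits, cost = cost,
                 dim = ncol(x)),
            class = "shg_classifier")
}

#' @export
predict.shg_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(dim(x)) || ncol(x) != object$dim) x <- matrix(x, ncol = object$dim)
  votes <- matrix(0, nrow(x), length(object$classes))
  for (f in object$fits) {
    d <- svm_decision(f$w, x)
    winner <- ifelse(d >= 0, f$a, f$b)   # tie at 0 -> lower class index
    for (i in seq_along(winner))
      votes[i, winner[i]] <- votes[i, winner[i]] + 1
  }
  idx <- max.col(votes, ties.method = "first")
  factor(object$classes[idx], levels = object$classes)
}

#' Predict the class of one image
#'
#' @param image Image (matrix or `shg_image`).
#' @param codebook `shg_codebook` used at training time.
#' @param classifier `shg_classifier`.
#' @param grid_step,config Must match the training configuration.
#' @return Single factor level from the training category set.
#' @export
predict_image <- function(image, codebook, classifier, grid_step = 64L,
                          config = glcm_config()) {
  tv <- term_vector(image, codebook, grid_step, config)
  predict(classifier, matrix(tv, nrow = 1))[1]
}

#' Feature matrices for every image of a set
#'
#' Convenience precomputation so that codebook sizes and fold splits can be
#' varied without re-extracting features.
#'
#' @param dataset `shg_image_set`.
#' @param grid_step Grid step.
#' @param config [glcm_config()].
#' @return List of per-image feature matrices (possibly 0-row).
#' @export
dataset_features <- function(dataset, grid_step = 64L,
                             config = glcm_config()) {
  lapply(dataset$images, function(im) image_features(im, grid_step, config))
}

# Stratified fold assignment: per class, shuffle indices deterministically
# and deal them round-robin over n_runs folds.
make_folds <- function(labels, n_runs, seed) {
  fold <- integer(length(labels))
  set.seed(derive_seed(seed, "folds"))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < n_runs)
      stop_shg("shgbof_fold_error",
               "class '%s' has %d samples, fewer than n_runs = %d", cl,
               length(idx), n_runs)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_runs), length(idx))
  }
  fold
}

#' Multi-run Bag-of-Features evaluation
#'
#' Partitions the labeled set into `n_runs` stratified folds and performs
#' `n_runs` consecutive runs: in run r the r-th fold is the test set and the
#' remaining images are the training set. In `vocabulary_mode = "strict"`
#' (default) the codebook is clustered from training-fold patches only, so
#' test pixels never leak into the vocabulary; `"paper"` clusters the
#' codebook from all images, reproducing the protocol in which every image
#' contributes to vocabulary building while held-out images are still unseen
#' by the classifier. Per-run confusion matrices are row-normalized (true
#' class x predicted class) and averaged elementwise.
#'
#' Images without signal patches are excluded from a run and reported in the
#' `exclusions` attribute.
#'
#' @param dataset `shg_image_set`.
#' @param k Codebook size.
#' @param g Grid step in pixels.
#' @param n_runs Number of consecutive runs / folds (default 4).
#' @param seed Master seed (folds, k-means).
#' @param vocabulary_mode `"strict"` or `"paper"`.
#' @param config [glcm_config()].
#' @param features Optional precomputed [dataset_features()] list (must match
#'   `g` and `config`).
#' @return `shg_confusion`: list with `p` (C x C row-stochastic matrix of
#'   averaged probabilities), `classes`, `n_runs`, `accuracy` (mean of the
#'   diagonal), `per_run` (list of per-run matrices).
#' @export
evaluate_runs <- function(dataset, k = 20L, g = 64L, n_runs = 4L, seed = 1L,
                          vocabulary_mode = c("strict", "paper"),
                          config = glcm_config(), features = NULL) {
  vocabulary_mode <- match.arg(vocabulary_mode)
  labels <- dataset$labels
  classes <- levels(labels)
  if (is.null(features)) features <- dataset_features(dataset, g, config)
  usable <- vapply(features, nrow, integer(1)) > 0
  excluded <- which(!usable)
  fold <- make_folds(labels, n_runs, seed)
  per_run <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    test_idx <- which(fold == r & usable)
    train_idx <- which(fold != r & usable)
    vocab_idx <- if (vocabulary_mode == "paper") which(usable) else train_idx
    vocab_feats <- do.call(rbind, features[vocab_idx])
    cb <- build_codebook(vocab_feats, k, seed = derive_seed(seed,
                                                            paste0("run", r)))
    tv_train <- t(vapply(train_idx, function(i)
      term_vector(features[[i]], cb), numeric(k)))
    clf <- train_classifier(tv_train, labels[train_idx])
    tv_test <- t(vapply(test_idx, function(i)
      term_vector(features[[i]], cb), numeric(k)))
    pred <- predict(clf, tv_test)
    cm <- matrix(0, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
    tab <- table(factor(labels[test_idx], levels = classes),
                 factor(pred, levels = classes))
    cm[] <- as.numeric(tab)
    rs <- rowSums(cm)
    cm <- sweep(cm, 1, pmax(rs, 1), "/")
    per_run[[r]] <- cm
  }
  p <- Reduce(`+`, per_run) / n_runs
  structure(list(p = p, classes = classes, n_runs = n_runs,
                 accuracy = mean(diag(p)), per_run = per_run,
                 k = k, g = g, seed = seed,
                 vocabulary_mode = vocabulary_mode,
                 exclusions = excluded),
            class = "shg_confusion")
}

#' @export
print.shg_confusion <- function(x, ...) {
  cat(sprintf("Averaged confusion matrix (%d runs, k = %d, g = %d):\n",
              x$n_runs, x$k, x$g))
  print(round(x$p, 3))
  cat(sprintf("Mean diagonal accuracy: %.3f\n", x$accuracy))
  invisible(x)
}

#' Sweep codebook size and grid step
#'
#' Runs [evaluate_runs()] for every (k, g) combination, re-using per-g
#' feature matrices across codebook sizes.
#'
#' @param dataset `shg_image_set`.
#' @param k_values Codebook sizes (default the standard sweep 5, 10, 20,
#'   50, 100).
#' @param g_values Grid steps (default 32 and 64).
#' @param ... Passed to [evaluate_runs()] (`n_runs`, `seed`,
#'   `vocabulary_mode`, `config`).
#' @return `shg_sweep`: list with `table` (data.frame: k, g, accuracy and
#'   one column per confusion entry) and `matrices` (named list of
#'   `shg_confusion`).
#' @export
parameter_sweep <- function(dataset, k_values = c(5L, 10L, 20L, 50L, 100L),
                            g_values = c(32L, 64L),
                            config = glcm_config(), ...) {
  matrices <- list()
  rows <- list()
  for (g in g_values) {
    feats <- dataset_features(dataset, g, config)
    for (k in k_values) {
      cm <- evaluate_runs(dataset, k = k, g = g, config = config,
                          features = feats, ...)
      key <- sprintf("k%d_g%d", k, g)
      matrices[[key]] <- cm
      entries <- as.vector(t(cm$p))
      names(entries) <- as.vector(outer(cm$classes, cm$classes,
                                        function(a, b) paste(a, b, sep = "->")))
      rows[[key]] <- cbind(data.frame(k = k, g = g, accuracy = cm$accuracy),
                           as.data.frame(as.list(entries), check.names = FALSE))
    }
  }
  structure(list(table = do.call(rbind, rows), matrices = matrices),
            class = "shg_sweep")
}
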