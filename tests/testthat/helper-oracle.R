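# Independent brute-force oracle for the GLCM and the eight texture
# parameters, written as literal nested sums straight from the defining
# formulas. Deliberately slow and simple; never shares code with the
# package implementation.

oracle_offset <- function(theta, d) {
  switch(as.character(theta),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

oracle_glcm <- function(roi, theta, d = 1, levels = max(roi) + 1,
                        symmetric = TRUE) {
  off <- oracle_offset(theta, d)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(roi))) {
    for (c in seq_len(ncol(roi))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(roi) && c2 >= 1 && c2 <= ncol(roi)) {
        i <- roi[r, c] + 1; j <- roi[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
        if (symmetric) counts[j, i] <- counts[j, i] + 1
      }
    }
  }
  counts / sum(counts)
}

oracle_params <- function(p) {
  n <- nrow(p)
  # marginals of the row/column distributions, 0-based gray levels
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- 0; for (i in 1:n) mu_i <- mu_i + (i - 1) * pi_[i]
  mu_j <- 0; for (j in 1:n) mu_j <- mu_j + (j - 1) * pj_[j]
  var_i <- 0; for (i in 1:n) var_i <- var_i + (i - 1 - mu_i)^2 * pi_[i]
  var_j <- 0; for (j in 1:n) var_j <- var_j + (j - 1 - mu_j)^2 * pj_[j]
  s_i <- sqrt(var_i); s_j <- sqrt(var_j)

  cor <- 0; asm <- 0; con <- 0; idm <- 0; ent <- 0
  for (i in 1:n) for (j in 1:n) {
    v <- p[i, j]
    asm <- asm + v^2
    con <- con + ((i - 1) - (j - 1))^2 * v
    idm <- idm + v / (1 + abs((i - 1) - (j - 1)))
    if (v > 0) ent <- ent - v * log(v)
    if (s_i > 0 && s_j > 0)
      cor <- cor + ((i - 1) - mu_i) * ((j - 1) - mu_j) * v / (s_i * s_j)
  }

  pxy <- numeric(2 * n - 1)        # index i corresponds to sum i-1 in 0-based
  for (i in 1:n) for (j in 1:n)
    pxy[(i - 1) + (j - 1) + 1] <- pxy[(i - 1) + (j - 1) + 1] + p[i, j]
  sent <- 0; savg <- 0
  for (i in seq_along(pxy)) {
    if (pxy[i] > 0) sent <- sent - pxy[i] * log(pxy[i])
    savg <- savg + (i - 1) * pxy[i]
  }
  svar <- 0
  for (i in seq_along(pxy)) svar <- svar + ((i - 1) - savg)^2 * pxy[i]

  c(correlation = cor, asm = asm, contrast = con, idm = idm, entropy = ent,
    sum_entropy = sent, sum_average = savg, sum_variance = svar)
}

# Shared fixture cache so the expensive synthetic benchmark datasets are
# generated once per test session.
.fixture_env <- new.env(parent = emptyenv())

fixture_dataset <- function(key, n_per_class, classes, size = 512L,
                            seed = 20260910L) {
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- gen_dataset(n_per_class, classes, size = size,
                                       seed = seed)
  .fixture_env[[key]]
}

fixture_features <- function(key, dataset, g = 64L) {
  fk <- paste0(key, "_feats_g", g)
  if (is.null(.fixture_env[[fk]]))
    .fixture_env[[fk]] <- dataset_features(dataset, g)
  .fixture_env[[fk]]
}
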