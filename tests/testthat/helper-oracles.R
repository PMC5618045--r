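# Independent brute-force oracles used to cross-check vectorized
# implementations. Deliberately naive: explicit loops, no shared code with
# the package internals.

naive_s_index <- function(pixels, center_mask, ring_mask) {
  cs <- 0; cn <- 0; rs <- 0; rn <- 0
  for (i in seq_len(nrow(center_mask))) {
    for (j in seq_len(ncol(center_mask))) {
      red <- 255 - pixels[i, j, 3]
      if (center_mask[i, j]) { cs <- cs + red; cn <- cn + 1 }
      if (ring_mask[i, j]) { rs <- rs + red; rn <- rn + 1 }
    }
  }
  (cs / cn) / (rs / rn)
}

naive_fleiss_kappa <- function(counts) {
  n_sub <- nrow(counts); n_rat <- sum(counts[1, ])
  p_agree <- numeric(n_sub)
  for (i in seq_len(n_sub)) {
    s <- 0
    for (j in seq_len(ncol(counts))) s <- s + counts[i, j] * (counts[i, j] - 1)
    p_agree[i] <- s / (n_rat * (n_rat - 1))
  }
  tot <- sum(counts)
  pe <- 0
  for (j in seq_len(ncol(counts))) pe <- pe + (sum(counts[, j]) / tot)^2
  (mean(p_agree) - pe) / (1 - pe)
}

naive_confusion_tally <- function(truth, call, labels) {
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (k in seq_along(truth)) {
    m[match(truth[k], labels), match(call[k], labels)] <-
      m[match(truth[k], labels), match(call[k], labels)] + 1L
  }
  m
}

naive_single_point_auc <- function(truth_pos, call_pos) {
  tp <- 0; fn <- 0; tn <- 0; fp <- 0
  for (k in seq_along(truth_pos)) {
    if (truth_pos[k] && call_pos[k]) tp <- tp + 1
    if (truth_pos[k] && !call_pos[k]) fn <- fn + 1
    if (!truth_pos[k] && !call_pos[k]) tn <- tn + 1
    if (!truth_pos[k] && call_pos[k]) fp <- fp + 1
  }
  (tp / (tp + fn) + tn / (tn + fp)) / 2
}

permutation_p_value <- function(x, y, n_perm = 2000, seed = 42) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  hits <- 0
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    idx <- sample(length(pool), length(x))
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# small fast render used across tests
quick_render <- function(hbs, formulation = "MS", noise_sd = 0, seed = 1, ...) {
  render_stain(stain_render_spec(hbs, formulation, noise_sd = noise_sd,
                                 seed = seed, ...))
}
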