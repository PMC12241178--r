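# Independent brute-force oracles. These deliberately share no code with the
# package implementations they are checked against.

# Per-pair Pearson + clipped Fisher z, elementwise loops.
oracle_fisher_z <- function(x, bound = 1 - 1e-7) {
  r_n <- ncol(x)
  z <- matrix(0, r_n, r_n)
  for (i in seq_len(r_n - 1)) {
    for (j in (i + 1):r_n) {
      a <- x[, i]; b <- x[, j]
      num <- sum((a - mean(a)) * (b - mean(b)))
      den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
      r <- if (den == 0) 0 else num / den
      r <- min(max(r, -bound), bound)
      z[i, j] <- z[j, i] <- atanh(r)
    }
  }
  z
}

# ACSC by the definitional quadruple loop over subjects x subjects x
# sessions x sessions, one edge at a time.
oracle_acsc <- function(values) {
  n <- dim(values)[1]; s <- dim(values)[2]; e_t <- dim(values)[3]
  score <- numeric(e_t)
  for (e in seq_len(e_t)) {
    diag_sum <- 0; diag_n <- 0; off_sum <- 0; off_n <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        for (a in seq_len(s)) {
          for (b in seq_len(s)) {
            if (a == b) next
            d <- abs(values[i, a, e] - values[j, b, e])
            if (i == j) {
              diag_sum <- diag_sum + d; diag_n <- diag_n + 1
            } else {
              off_sum <- off_sum + d; off_n <- off_n + 1
            }
          }
        }
      }
    }
    score[e] <- off_sum / off_n - diag_sum / diag_n
  }
  score
}

# Benjamini-Hochberg by enumeration of the definition:
# q_i = min over k >= rank(i) of m * p_(k) / k, capped at 1;
# reject via the step-up rule (largest k with p_(k) <= k * alpha / m).
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (pos in seq_len(m)) {
    cand <- sapply(pos:m, function(k) m * p[o][k] / k)
    q[o[pos]] <- min(1, min(cand))
  }
  ks <- which(p[o] <= seq_len(m) * alpha / m)
  reject <- rep(FALSE, m)
  if (length(ks) > 0) reject[o[seq_len(max(ks))]] <- TRUE
  list(q = q, reject = reject)
}

# Accuracy / macro-F1 from an explicitly assembled confusion matrix.
oracle_scores <- function(predicted, truth, labels) {
  conf <- matrix(0, length(labels), length(labels))
  for (r in seq_along(truth)) {
    conf[match(truth[r], labels), match(predicted[r], labels)] <-
      conf[match(truth[r], labels), match(predicted[r], labels)] + 1
  }
  f1 <- c()
  for (c in seq_along(labels)) {
    tp <- conf[c, c]
    fp <- sum(conf[, c]) - tp
    fn <- sum(conf[c, ]) - tp
    if (tp + fp + fn == 0) next  # class absent from truth and predictions
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- c(f1, if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
  }
  list(accuracy = sum(diag(conf)) / sum(conf), f1 = mean(f1), confusion = conf)
}

# Small strong-clip-signal dataset shared by classification tests.
strong_signal_stack <- function(n_subjects = 12, n_regions = 30, seed = 101,
                                sparsity = 0.25) {
  cohort <- make_cohort(n_subjects, 0.5, seed = seed)
  truth <- make_ground_truth(n_regions, seed = seed,
                             clip_edges = 200, clip_strength = 0.35,
                             fingerprint_edges = 40)
  ds <- make_dataset(cohort, clip_catalogue(), truth, duration_scale = 0.4)
  fc_stack(ds, sparsity = sparsity)
}
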