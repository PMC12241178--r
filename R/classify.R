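# Multiclass movie-clip decoding from FC edge vectors.

#' Classifier configuration
#'
#' Linear-kernel maximum-margin classifier with one-vs-one decomposition,
#' regularisation constant 1 and no feature standardisation — the default
#' behaviour of a stock error-correcting one-vs-one SVM.
#'
#' @param kernel kernel name passed to [e1071::svm()].
#' @param cost regularisation constant C.
#' @param scale standardise features before training.
#' @return list of classifier settings.
#' @export
classifier_config <- function(kernel = "linear", cost = 1, scale = FALSE) {
  list(kernel = kernel, cost = cost, scale = scale)
}

#' Chance-level accuracy for balanced multiclass guessing
#' @param n_classes number of classes (15 movie clips).
#' @return 1 / n_classes.
#' @export
chance_accuracy <- function(n_classes = 15) 1 / n_classes

# Rows = subject x clip samples (subject-fastest), columns = selected edges.
samples_matrix <- function(stack, edges) {
  v <- stack$values
  n <- dim(v)[1L]; s <- dim(v)[2L]
  x <- matrix(v[, , edges + 1L], n * s, length(edges))
  list(x = x,
       label = rep(stack$clip_labels, each = n),
       subject = rep(stack$subjects, s))
}

train_predict <- function(stack, train_idx, test_idx, k, config) {
  e_t <- dim(stack$values)[3L]
  train <- stack_subset(stack, train_idx)
  sc <- acsc_score(train)
  k_eff <- if (identical(k, "full")) e_t else as.integer(k)
  sel <- select_top_k(sc, k_eff)
  tr <- samples_matrix(train, sel)
  v_te <- stack$values[test_idx, , sel + 1L, drop = FALSE]
  n_te <- length(test_idx); s <- dim(stack$values)[2L]
  te <- list(x = matrix(v_te, n_te * s, length(sel)),
             label = rep(stack$clip_labels, each = n_te),
             subject = rep(stack$subjects[test_idx], s))
  lev <- sort(stack$clip_labels)
  fit <- e1071::svm(x = tr$x, y = factor(tr$label, levels = lev),
                    kernel = config$kernel, cost = config$cost,
                    scale = config$scale)
  pred <- as.integer(as.character(stats::predict(fit, te$x)))
  data.frame(subject_id = te$subject, clip_label = te$label,
             predicted = pred, stringsAsFactors = FALSE)
}

#' Accuracy, macro-F1 and confusion matrix for clip predictions
#'
#' Macro-F1 is the unweighted mean of per-class F1 scores; a class present
#' in the truth but never predicted scores 0, and a class absent from both
#' truth and predictions is excluded from the mean.
#'
#' @param predicted,truth equal-length integer label vectors.
#' @param labels the full class label set (default 1..15).
#' @return list with `accuracy`, `f1` (macro), `confusion` (truth rows x
#'   predicted columns).
#' @export
classification_scores <- function(predicted, truth, labels = 1:15) {
  if (length(predicted) != length(truth)) stop_invalid("length mismatch")
  if (!all(predicted %in% labels) || !all(truth %in% labels)) {
    stop_invalid("labels outside the class set")
  }
  conf <- table(factor(truth, levels = labels),
                factor(predicted, levels = labels))
  conf <- unclass(conf)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  denom <- 2 * tp + fp + fn
  active <- denom > 0
  f1 <- ifelse(active, 2 * tp / pmax(denom, 1), NA_real_)
  list(accuracy = sum(tp) / sum(conf),
       f1 = mean(f1[active]),
       confusion = conf)
}

cv_result <- function(pred, stack, k, config) {
  lev <- sort(stack$clip_labels)
  sc <- classification_scores(pred$predicted, pred$clip_label, labels = lev)
  structure(
    list(predictions = pred, accuracy = sc$accuracy, f1 = sc$f1,
         confusion = sc$confusion,
         k_used = if (identical(k, "full")) dim(stack$values)[3L] else as.integer(k),
         sparsity_used = stack$sparsity),
    class = "cv_result"
  )
}

#' Leave-one-subject-out cross-validated clip classification
#'
#' For each held-out subject, ACSC scores are computed on the remaining
#' training subjects only, the top-k edges are selected, the classifier is
#' trained on all clips of the training subjects, and all clips of the
#' held-out subject are predicted; predictions are pooled across folds.
#'
#' @param stack a [session_stack()] of FC edge vectors.
#' @param k number of ACSC-selected edges, or `"full"` for all edges.
#' @param config classifier settings from [classifier_config()].
#' @return a `cv_result`: pooled predictions, accuracy, macro-F1, confusion
#'   matrix, `k_used`, `sparsity_used`.
#' @export
loocv_classify <- function(stack, k = "full", config = classifier_config()) {
  stopifnot(inherits(stack, "session_stack"))
  n <- dim(stack$values)[1L]
  if (n < 3L) stop_invalid("need at least 3 subjects for LOOCV")
  preds <- lapply(seq_len(n), function(i) {
    train_predict(stack, setdiff(seq_len(n), i), i, k, config)
  })
  cv_result(do.call(rbind, preds), stack, k, config)
}

#' Subject-grouped k-fold cross-validated clip classification
#'
#' Folds partition subjects (a subject's clips are never split across train
#' and test); assignment is deterministic given the seed. With
#' `n_folds = n_subjects` this reduces exactly to [loocv_classify()].
#'
#' @param stack a [session_stack()].
#' @param k number of ACSC-selected edges, or `"full"`.
#' @param n_folds number of folds (default 10).
#' @param config classifier settings.
#' @param seed seed for the fold assignment.
#' @return a `cv_result`.
#' @export
kfold_classify <- function(stack, k = "full", n_folds = 10,
                           config = classifier_config(), seed = 1) {
  stopifnot(inherits(stack, "session_stack"))
  n <- dim(stack$values)[1L]
  if (n_folds > n) stop_invalid("n_folds cannot exceed the number of subjects")
  if (n_folds < 2L) stop_invalid("need at least 2 folds")
  folds <- with_seed(seed_stream(seed, "folds"),
                     sample(rep(seq_len(n_folds), length.out = n)))
  preds <- lapply(seq_len(n_folds), function(f) {
    test_idx <- which(folds == f)
    train_predict(stack, which(folds != f), test_idx, k, config)
  })
  cv_result(do.call(rbind, preds), stack, k, config)
}

#' Scale the feature-count grid to a smaller connectome
#'
#' The published grid (1,000 to 19,000 in steps of 3,000) is defined for
#' E = 19,900 edges; for smaller region counts each k is rescaled
#' proportionally, `k' = max(1, round(k * E / 19900))`.
#'
#' @param k_grid integer feature counts.
#' @param e_total number of edges of the configured connectome.
#' @return rescaled integer grid.
#' @export
scale_k_grid <- function(k_grid, e_total) {
  if (e_total >= 19900) return(as.integer(k_grid))
  pmax(1L, as.integer(round(k_grid * e_total / 19900)))
}

#' Default published feature-count grid
#' @return c(1000, 4000, ..., 19000).
#' @export
default_k_grid <- function() seq(1000L, 19000L, by = 3000L)

#' Sweep classification performance over feature counts and sparsities
#'
#' One cross-validated classification per (sparsity, k) cell, with the
#' feature grid auto-scaled when the connectome has fewer than 19,900 edges
#' and `"full"` (all edges) appended for comparison — the layout of the
#' published F1 table (rows = sparsity, columns = k).
#'
#' @param dataset a [make_dataset()] bundle.
#' @param k_grid integer feature counts (before scaling).
#' @param sparsity_grid sparsity settings (default 0.2, 0.25, 0.3).
#' @param cv `"loocv"` or `"kfold"`.
#' @param n_folds folds for `cv = "kfold"`.
#' @param config classifier settings.
#' @param seed fold-assignment seed.
#' @param include_full append the all-edges column.
#' @return data.frame with `sparsity`, `k_requested`, `k_used`, `accuracy`,
#'   `f1`.
#' @export
k_sweep <- function(dataset, k_grid = default_k_grid(),
                    sparsity_grid = c(0.2, 0.25, 0.3),
                    cv = c("loocv", "kfold"), n_folds = 10,
                    config = classifier_config(), seed = 1,
                    include_full = TRUE) {
  cv <- match.arg(cv)
  if (length(k_grid) == 0L || length(sparsity_grid) == 0L) {
    stop_invalid("grids must be non-empty")
  }
  out <- list()
  for (sp in sparsity_grid) {
    stack <- fc_stack(dataset, sparsity = sp)
    e_t <- dim(stack$values)[3L]
    ks <- as.list(scale_k_grid(k_grid, e_t))
    labels <- as.character(k_grid)
    if (include_full) {
      ks <- c(ks, list("full"))
      labels <- c(labels, "full")
    }
    for (ki in seq_along(ks)) {
      res <- if (cv == "loocv") {
        loocv_classify(stack, ks[[ki]], config)
      } else {
        kfold_classify(stack, ks[[ki]], n_folds, config, seed)
      }
      out[[length(out) + 1L]] <- data.frame(
        sparsity = sp, k_requested = labels[ki], k_used = res$k_used,
        accuracy = res$accuracy, f1 = res$f1, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
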