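test_that("classification scores match their closed forms and the confusion oracle", {
  perfect <- classification_scores(1:15, 1:15)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)

  truth <- rep(1:15, each = 4)
  allone <- classification_scores(rep(1L, length(truth)), truth)
  expect_equal(allone$accuracy, 1 / 15)
  expect_equal(allone$f1, (2 / 16) / 15)

  for (seed in 1:10) {
    set.seed(seed)
    t_lab <- sample(1:15, 60, replace = TRUE)
    p_lab <- sample(1:15, 60, replace = TRUE)
    mine <- classification_scores(p_lab, t_lab)
    orc <- oracle_scores(p_lab, t_lab, 1:15)
    expect_equal(mine$accuracy, orc$accuracy)
    expect_equal(mine$f1, orc$f1)
    expect_true(all(mine$confusion == orc$confusion))
    # balanced-free identity: micro-F1 (= global TP rate) equals accuracy
    conf <- mine$confusion
    micro <- 2 * sum(diag(conf)) / (2 * sum(diag(conf)) +
                                      (sum(conf) - sum(diag(conf))) * 2)
    expect_equal(micro, mine$accuracy)
  }
  expect_error(classification_scores(c(1, 16), c(1, 2)),
               class = "moviefc_invalid_argument")
})

strong_stack <- strong_signal_stack()  # shared across the blocks below

test_that("strong clip signal is decoded nearly perfectly; label permutation breaks it", {
  res <- loocv_classify(strong_stack, k = 150)
  expect_gte(res$accuracy, 0.9)
  expect_equal(sum(res$confusion), 12 * 15)
  expect_equal(unname(rowSums(res$confusion)), rep(12, 15))
  expect_equal(res$accuracy, sum(diag(res$confusion)) / sum(res$confusion))

  # permute clip labels within each subject -> chance-level accuracy
  perm <- strong_stack
  set.seed(41)
  for (i in seq_len(dim(perm$values)[1])) {
    perm$values[i, , ] <- perm$values[i, sample(15), ]
  }
  res_p <- loocv_classify(perm, k = 150)
  expect_lt(res_p$accuracy, 0.2)
})

test_that("k-fold with one subject per fold reproduces LOOCV and is seed-deterministic", {
  n <- dim(strong_stack$values)[1]
  loo <- loocv_classify(strong_stack, k = 100)
  kf <- kfold_classify(strong_stack, k = 100, n_folds = n, seed = 7)
  ord <- function(p) p[order(p$subject_id, p$clip_label), ]
  expect_equal(ord(loo$predictions), ord(kf$predictions),
               ignore_attr = "row.names")

  k1 <- kfold_classify(strong_stack, k = 100, n_folds = 4, seed = 5)
  k2 <- kfold_classify(strong_stack, k = 100, n_folds = 4, seed = 5)
  expect_identical(k1$predictions, k2$predictions)
  expect_error(kfold_classify(strong_stack, n_folds = n + 1),
               class = "moviefc_invalid_argument")
})

test_that("k = 'full' equals explicit top-k with k = E", {
  e_t <- dim(strong_stack$values)[3]
  res_full <- loocv_classify(strong_stack, k = "full")
  res_e <- loocv_classify(strong_stack, k = e_t)
  expect_identical(res_full$predictions, res_e$predictions)
  expect_equal(res_full$k_used, e_t)
})

test_that("feature selection sees only training subjects (no leakage)", {
  n <- dim(strong_stack$values)[1]
  train_idx <- 2:n
  sc_before <- acsc_score(moviefc:::stack_subset(strong_stack, train_idx))
  corrupted <- strong_stack
  corrupted$values[1, , ] <- 1e6 * matrix(rnorm(15 * dim(corrupted$values)[3]), 15)
  sc_after <- acsc_score(moviefc:::stack_subset(corrupted, train_idx))
  expect_identical(sc_before$score, sc_after$score)
  expect_identical(sc_before$rank, sc_after$rank)
})

test_that("the k-grid rescales proportionally for smaller connectomes", {
  expect_equal(scale_k_grid(default_k_grid(), 19900), default_k_grid())
  expect_equal(scale_k_grid(c(1000, 19000), 1225),
               c(round(1000 * 1225 / 19900), round(19000 * 1225 / 19900)))
  expect_equal(scale_k_grid(1, 50), 1L)
})

test_that("the sweep emits one result cell per sparsity x k", {
  truth <- make_ground_truth(15, seed = 42, clip_edges = 60,
                             clip_strength = 0.4, n_clips = 4)
  cat4 <- data.frame(clip_label = 1:4, name = letters[1:4],
                     duration_tr = rep(60L, 4))
  ds <- make_dataset(make_cohort(6, 0.5, seed = 42), cat4, truth,
                     duration_scale = 1, extra_tr = 0)
  sweep <- k_sweep(ds, k_grid = c(1000, 7000), sparsity_grid = c(0.2, 0.3),
                   include_full = TRUE)
  expect_equal(nrow(sweep), 2 * 3)
  expect_equal(unique(sweep$sparsity), c(0.2, 0.3))
  expect_true(all(sweep$accuracy >= 0 & sweep$accuracy <= 1))
  expect_true(all(sweep$k_used[sweep$k_requested == "full"] == n_edges(15)))
  expect_error(k_sweep(ds, k_grid = integer()),
               class = "moviefc_invalid_argument")
})
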