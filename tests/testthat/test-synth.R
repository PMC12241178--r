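test_that("cohorts respect the sex ratio exactly and are seed-deterministic", {
  co <- make_cohort(4, 0.5, seed = 7)
  expect_equal(nrow(co), 4L)
  expect_equal(as.vector(table(co$sex)), c(2L, 2L))

  study <- make_cohort(169, 68 / 169, seed = 1)
  expect_equal(sum(study$sex == "F"), 68L)
  expect_equal(sum(study$sex == "M"), 101L)
  expect_true(all(study$age_group %in% 1:3))
  expect_true(all(study$mean_motion >= 0))
  expect_false(anyDuplicated(study$subject_id) > 0)

  expect_identical(make_cohort(20, 0.4, seed = 3), make_cohort(20, 0.4, seed = 3))
  expect_error(make_cohort(1), class = "moviefc_invalid_argument")
})

test_that("time-series simulation matches the requested shape and seed streams", {
  truth <- make_ground_truth(50, seed = 5)
  meta <- make_cohort(3, 0.5, seed = 5)[1, ]
  clip <- list(clip_label = 1L, duration_tr = 244L)
  ts <- simulate_timeseries(meta, clip, truth)
  expect_s3_class(ts, "parcellated_ts")
  expect_equal(dim(ts$data), c(244L, 50L))

  ts2 <- simulate_timeseries(meta, clip, truth)
  expect_identical(ts$data, ts2$data)

  other_clip <- list(clip_label = 2L, duration_tr = 244L)
  expect_false(identical(ts$data,
                         simulate_timeseries(meta, other_clip, truth)$data))
})

test_that("a null ground truth produces independent regional signals", {
  truth <- make_ground_truth(10, seed = 2, base_within = 0, base_between = 0,
                             clip_strength = 0, fingerprint_edges = 0,
                             sex_edges = 0, age_edges = 0)
  meta <- make_cohort(2, 0.5, seed = 2)[1, ]
  ts <- simulate_timeseries(meta, list(clip_label = 1L, duration_tr = 5000L), truth)
  z <- compute_fc(ts)$z
  expect_lt(max(abs(vectorize(z))), 0.1)
})

test_that("dataset bundles contain one series per subject x clip", {
  truth <- make_ground_truth(10, seed = 3)
  cohort <- make_cohort(10, 0.5, seed = 3)
  ds <- make_dataset(cohort, clip_catalogue(), truth, duration_scale = 0.05)
  expect_equal(length(ds$timeseries), 150L)
  expect_equal(length(unique(vapply(ds$timeseries, function(t) t$clip_label,
                                    integer(1)))), 15L)
  expect_error(make_dataset(cohort[0, ], clip_catalogue(), truth),
               class = "moviefc_invalid_argument")
})

test_that("planted clip contrasts reappear in the empirical mean FC", {
  # One clip component: +0.4 covariance on a single edge of clip 1 only.
  truth <- make_ground_truth(8, seed = 4, base_within = 0, base_between = 0,
                             clip_strength = 0, fingerprint_edges = 0,
                             sex_edges = 0, age_edges = 0, n_clips = 2)
  target_edge <- 5L  # 0-based
  truth$clip_components[target_edge + 1L, 1] <- 0.4
  meta <- make_cohort(6, 0.5, seed = 4)
  z1 <- z2 <- numeric(nrow(meta))
  for (s in seq_len(nrow(meta))) {
    t1 <- simulate_timeseries(meta[s, ], list(clip_label = 1L, duration_tr = 1500L), truth)
    t2 <- simulate_timeseries(meta[s, ], list(clip_label = 2L, duration_tr = 1500L), truth)
    z1[s] <- vectorize(compute_fc(t1)$z)[target_edge + 1L]
    z2[s] <- vectorize(compute_fc(t2)$z)[target_edge + 1L]
  }
  planted_contrast <- atanh(0.4)
  expect_lt(abs(mean(z1 - z2) - planted_contrast), 3 * sd(z1 - z2) / sqrt(length(z1)) + 0.02)
  expect_gt(mean(z1 - z2), 0.3)
})

test_that("effect injection keeps covariances symmetric and positive definite", {
  truth <- make_ground_truth(20, seed = 6, sex_delta = 0.6, age_slope = 0.3,
                             fingerprint_sd = 0.4, clip_strength = 0.5)
  meta <- make_cohort(4, 0.5, seed = 6)
  for (s in 1:2) {
    sig <- moviefc:::subject_clip_cov(truth, meta[s, ], 3L)
    expect_equal(sig, t(sig))
    expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("fingerprint offsets are subject-stable and land on planted edges", {
  truth <- make_ground_truth(30, seed = 8)
  v1 <- fingerprint_offsets(truth, "sub-001")
  expect_identical(v1, fingerprint_offsets(truth, "sub-001"))
  expect_false(identical(v1, fingerprint_offsets(truth, "sub-002")))
  expect_setequal(which(v1 != 0) - 1L, truth$fingerprint_edges)
})

test_that("edge-level simulation plants effects where it says it does", {
  sim <- simulate_edge_table(n_subjects = 12, n_clips = 4, n_edges_total = 20,
                             sex_edges = 5, sex_delta = 3, seed = 9)
  expect_equal(dim(sim$stack$values), c(12L, 4L, 20L))
  expect_length(sim$planted$sex_edges, 5L)
  # group gap visible on planted edges, absent elsewhere
  f_idx <- sim$meta$sex == "F"
  gaps <- apply(sim$stack$values, 3, function(m) {
    mean(m[f_idx, ]) - mean(m[!f_idx, ])
  })
  planted <- sim$planted$sex_edges + 1L
  expect_true(all(abs(gaps[planted]) > 1.5))
  expect_true(all(abs(gaps[-planted]) < 1.5))
})
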