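test_that("the vectorised split-plot engine agrees with a per-edge lmer fit", {
  skip_if_not_installed("lmerTest")
  skip_if_not_installed("car")
  sim <- simulate_edge_table(n_subjects = 16, n_clips = 5, n_edges_total = 6,
                             sex_edges = 2, sex_delta = 1.5,
                             age_edges = 1, age_slope = 1, seed = 21)
  bw <- fit_edge_models(sim$stack, sim$meta)
  lm_fit <- fit_edge_models(sim$stack, sim$meta, method = "lmer")
  m <- merge(bw, lm_fit, by = c("edge_id", "term"))
  expect_equal(m$df1.x, m$df1.y)
  expect_equal(m$df2.x, m$df2.y, tolerance = 1e-6)
  expect_equal(m$F.x, m$F.y, tolerance = 1e-4)
  both_dir <- !is.na(m$direction.x)
  expect_equal(m$direction.x[both_dir], m$direction.y[both_dir])
})

test_that("a strong planted sex effect is detected with the planted sign", {
  # gap of 1 unit against residual SD 0.1 (and small subject variance)
  sim <- simulate_edge_table(n_subjects = 40, n_clips = 15, n_edges_total = 10,
                             sex_edges = 3, sex_delta = 10,
                             sigma_resid = 0.1, sigma_subject = 0.05,
                             sigma_clip = 0.05, seed = 22)
  eff <- fit_edge_models(sim$stack, sim$meta)
  sx <- eff[eff$term == "sex", ]
  planted <- match(sim$planted$sex_edges, sx$edge_id)
  expect_true(all(sx$p[planted] < 1e-4))
  expect_equal(sx$direction[planted], sim$planted$sex_sign)
})

test_that("partial eta squared follows the F statistic", {
  expect_equal((0 * 2) / (0 * 2 + 30), 0)  # F = 0 -> 0
  f <- seq(0, 20, by = 0.5)
  eta <- (f * 3) / (f * 3 + 42)
  expect_true(all(diff(eta) > 0))
  sim <- simulate_edge_table(n_subjects = 12, n_clips = 4, n_edges_total = 5,
                             sex_edges = 0, seed = 23)
  eff <- fit_edge_models(sim$stack, sim$meta)
  expect_equal(eff$eta_p2, (eff$F * eff$df1) / (eff$F * eff$df1 + eff$df2))
  expect_true(all(eff$eta_p2 >= 0 & eff$eta_p2 <= 1))
  expect_true(all(eff$q >= eff$p - 1e-12))
})

test_that("null edges keep the nominal type-I rate, with and without motion leakage", {
  # 2,000 null edges keep the Monte-Carlo SE of the rate (~0.005) well
  # inside the acceptance band
  sim <- simulate_edge_table(n_subjects = 40, n_clips = 15,
                             n_edges_total = 2000, sex_edges = 0, seed = 1)
  eff <- fit_edge_models(sim$stack, sim$meta)
  rate <- mean(eff$p[eff$term == "sex"] <= 0.05)
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)

  leak <- simulate_edge_table(n_subjects = 40, n_clips = 15,
                              n_edges_total = 2000, sex_edges = 0,
                              motion_leak = 1, motion_sex_gap = 0.1, seed = 2)
  eff_l <- fit_edge_models(leak$stack, leak$meta)
  rate_l <- mean(eff_l$p[eff_l$term == "sex"] <= 0.05)
  expect_gte(rate_l, 0.03); expect_lte(rate_l, 0.07)
})

test_that("Benjamini-Hochberg matches p.adjust and its stated examples", {
  res <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(res$reject))

  expect_false(any(benjamini_hochberg(c(1, 1, 1), alpha = 0.9)$reject))

  single <- benjamini_hochberg(0.04, alpha = 0.05)
  expect_equal(single$q, 0.04)
  expect_true(single$reject)

  for (seed in 1:20) {
    set.seed(seed)
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(benjamini_hochberg(p)$q, p.adjust(p, method = "BH"))
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), class = "moviefc_invalid_argument")
})

test_that("zero-variance edges are flagged and excluded from the FDR family", {
  sim <- simulate_edge_table(n_subjects = 10, n_clips = 4, n_edges_total = 6,
                             sex_edges = 0, seed = 24)
  sim$stack$values[, , 3] <- 1  # constant edge
  eff <- fit_edge_models(sim$stack, sim$meta)
  expect_equal(attr(eff, "flagged_edges"), 2L)
  expect_true(all(is.na(eff$p[eff$edge_id == 2L])))
  expect_true(all(is.na(eff$q[eff$edge_id == 2L])))
  expect_false(anyNA(eff$q[eff$edge_id != 2L]))
})

test_that("network aggregation localises effects and conserves counts", {
  r_n <- 14
  part <- network_partition(r_n, 7)
  idx <- edge_index(r_n)
  # all planted edges inside network 1's block (regions 0-1 -> edge (0,1))
  net1_edges <- idx$k[part$network_id[idx$i + 1] == 1 &
                        part$network_id[idx$j + 1] == 1]
  eff <- data.frame(edge_id = idx$k, term = "sex", F = 1, df1 = 1, df2 = 10,
                    p = 1, q = 1, eta_p2 = 0.1, direction = 1)
  eff$q[eff$edge_id %in% net1_edges] <- 0.01
  eff <- structure(eff, class = c("effects_table", "data.frame"), alpha = 0.05)

  agg <- aggregate_by_network(eff, part, "sex", index = idx)
  expect_equal(agg$total[1, 1], length(net1_edges))
  expect_equal(sum(agg$total), length(net1_edges))
  expect_equal(agg$net[1, 1], length(net1_edges))  # planted sign +
  expect_true(all(agg$total[-1] == 0))

  none <- eff; none$q <- 1
  none <- structure(none, class = class(eff), alpha = 0.05)
  agg0 <- aggregate_by_network(none, part, "sex", index = idx)
  expect_true(all(agg0$total == 0))
})

test_that("single-edge long-format fitting matches the stack engine", {
  sim <- simulate_edge_table(n_subjects = 12, n_clips = 5, n_edges_total = 3,
                             sex_edges = 1, sex_delta = 2, seed = 25)
  eff_all <- fit_edge_models(sim$stack, sim$meta)
  e <- 2L
  obs <- expand.grid(si = seq_len(12), ci = seq_len(5))
  obs <- data.frame(
    subject_id = sim$meta$subject_id[obs$si],
    clip_label = obs$ci,
    fc_value = sim$stack$values[cbind(obs$si, obs$ci, e)],
    sex = sim$meta$sex[obs$si],
    age_group = sim$meta$age_group[obs$si],
    mean_motion = sim$meta$mean_motion[obs$si]
  )
  one <- fit_edge_model(obs)
  for (term in unique(one$term)) {
    expect_equal(one$F[one$term == term],
                 eff_all$F[eff_all$term == term & eff_all$edge_id == e - 1L],
                 tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected up front", {
  sim <- simulate_edge_table(n_subjects = 8, n_clips = 3, n_edges_total = 2,
                             sex_edges = 0, seed = 26)
  meta_onesex <- sim$meta
  meta_onesex$sex <- factor("F", levels = c("F", "M"))
  expect_error(fit_edge_models(sim$stack, meta_onesex),
               class = "moviefc_invalid_argument")
  meta_oneage <- sim$meta
  meta_oneage$age_group <- 2L
  expect_error(fit_edge_models(sim$stack, meta_oneage),
               class = "moviefc_invalid_argument")
})
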