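#' Generate a synthetic subject cohort
#'
#' Sexes follow the requested ratio exactly (rounded female count, order
#' shuffled by seed), age groups are uniform over the three ordinal levels,
#' and mean head motion is log-normal (framewise-displacement-like,
#' arbitrary units).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param sex_ratio female fraction in \[0, 1\]; e.g. 68/169 for the study
#'   cohort.
#' @param seed integer seed; the cohort is deterministic given the seed.
#' @param motion_meanlog,motion_sdlog log-normal parameters for mean motion.
#' @return data.frame with `subject_id`, `sex` (factor F/M), `age_group`
#'   (1..3), `mean_motion`.
#' @export
make_cohort <- function(n_subjects, sex_ratio = 0.5, seed = 1,
                        motion_meanlog = -1.6, motion_sdlog = 0.4) {
  if (!is.numeric(n_subjects) || n_subjects < 2L) {
    stop_invalid("n_subjects must be at least 2")
  }
  if (sex_ratio < 0 || sex_ratio > 1) stop_invalid("sex_ratio must be in [0, 1]")
  n <- as.integer(n_subjects)
  n_f <- as.integer(round(n * sex_ratio))
  with_seed(seed_stream(seed, "cohort"), {
    sex <- sample(rep(c("F", "M"), c(n_f, n - n_f)))
    age <- sample(1:3, n, replace = TRUE)
    motion <- stats::rlnorm(n, meanlog = motion_meanlog, sdlog = motion_sdlog)
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      sex = factor(sex, levels = c("F", "M")),
      age_group = age,
      mean_motion = motion,
      stringsAsFactors = FALSE
    )
  })
}

#' Contiguous-block assignment of regions to canonical networks
#'
#' @param n_regions number of regions R.
#' @param n_networks number of networks (default 7, named after the
#'   canonical cortical systems).
#' @return data.frame with `region_id` (0-based), `network_id` (1-based),
#'   `network_name`.
#' @export
network_partition <- function(n_regions, n_networks = 7) {
  if (n_networks > n_regions) stop_invalid("more networks than regions")
  nm <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")
  if (n_networks > length(nm)) nm <- c(nm, paste0("NET", seq_len(n_networks - length(nm)) + 7L))
  sizes <- rep(n_regions %/% n_networks, n_networks)
  extra <- n_regions %% n_networks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  net <- rep(seq_len(n_networks), sizes)
  data.frame(region_id = 0:(n_regions - 1L), network_id = net,
             network_name = nm[net], stringsAsFactors = FALSE)
}

#' Define the generative ground truth for synthetic FC data
#'
#' Every subject x clip covariance is assembled as
#' `base_cov + clip component + subject fingerprint component + sex/age edge
#' effects`, then repaired to positive definite (eigenvalue floor 1e-6,
#' re-symmetrised). The base covariance is a network-block correlation
#' structure (higher within-network than between-network correlation) scaled
#' by `noise_sd^2`. Clip components are clip-specific uniform offsets on a
#' designated edge set shared across subjects; fingerprint components are
#' subject-specific Gaussian offsets on a designated edge set stable across
#' clips; sex/age effects are signed additive offsets on disjoint designated
#' edge sets, drawn from the within-network edge pool so they survive
#' proportional thresholding.
#'
#' @param n_regions number of regions R (default 50, desk scale; 200 is the
#'   full-scale configuration).
#' @param partition region-to-network table from [network_partition()].
#' @param seed master seed; all per-(subject, clip) streams derive from it.
#' @param base_within,base_between within/between-network baseline
#'   correlations of the base covariance.
#' @param noise_sd marginal SD of the regional signals.
#' @param n_clips number of clips (default 15).
#' @param clip_edges,clip_strength number of clip-informative edges and the
#'   half-width of the uniform clip-specific covariance offsets; 0 strength
#'   gives label-free (null) data.
#' @param fingerprint_edges,fingerprint_sd number of subject-stable
#'   fingerprint edges and the SD of the per-subject offsets.
#' @param sex_edges,sex_delta number of sex-effect edges and the covariance
#'   gap between females and males (random sign per edge; positive sign =
#'   greater in females).
#' @param age_edges,age_slope number of age-effect edges and the per-level
#'   covariance slope (random sign per edge).
#' @return object of class `fc_ground_truth`.
#' @export
make_ground_truth <- function(n_regions = 50, partition = network_partition(n_regions),
                              seed = 1,
                              base_within = 0.3, base_between = 0.1, noise_sd = 1,
                              n_clips = 15,
                              clip_edges = 400, clip_strength = 0.25,
                              fingerprint_edges = 100, fingerprint_sd = 0.15,
                              sex_edges = 50, sex_delta = 0.1,
                              age_edges = 50, age_slope = 0.05) {
  r_n <- as.integer(n_regions)
  e_total <- n_edges(r_n)
  idx <- edge_index(r_n)
  net_i <- partition$network_id[idx$i + 1L]
  net_j <- partition$network_id[idx$j + 1L]
  within <- which(net_i == net_j)
  base <- matrix(base_between, r_n, r_n)
  wmask <- devectorize(as.numeric(seq_len(e_total) %in% within), r_n)
  base <- base + wmask * (base_within - base_between)
  diag(base) <- 1
  base <- base * noise_sd^2

  with_seed(seed_stream(seed, "truth"), {
    n_within_eff <- min(sex_edges + age_edges, length(within))
    eff_pool <- sample(within, n_within_eff)
    sex_set <- if (sex_edges > 0) eff_pool[seq_len(min(sex_edges, length(eff_pool)))] else integer()
    age_set <- setdiff(eff_pool, sex_set)[seq_len(min(age_edges, length(eff_pool) - length(sex_set)))]
    remaining <- setdiff(seq_len(e_total), c(sex_set, age_set))
    fp_set <- if (fingerprint_edges > 0) sample(remaining, min(fingerprint_edges, length(remaining))) else integer()
    remaining <- setdiff(remaining, fp_set)
    clip_set <- if (clip_edges > 0) sample(remaining, min(clip_edges, length(remaining))) else integer()

    clip_comp <- matrix(0, e_total, n_clips)
    if (length(clip_set) > 0 && clip_strength > 0) {
      for (cl in seq_len(n_clips)) {
        clip_comp[clip_set, cl] <- stats::runif(length(clip_set), -clip_strength, clip_strength)
      }
    }
    sex_effect <- numeric(e_total)
    if (length(sex_set) > 0) {
      sex_effect[sex_set] <- sex_delta * sample(c(-1, 1), length(sex_set), replace = TRUE)
    }
    age_effect <- numeric(e_total)
    if (length(age_set) > 0) {
      age_effect[age_set] <- age_slope * sample(c(-1, 1), length(age_set), replace = TRUE)
    }

    structure(
      list(n_regions = r_n, n_edges = e_total, partition = partition,
           base_cov = base, n_clips = as.integer(n_clips),
           clip_components = clip_comp,
           clip_edges = sort(clip_set - 1L),
           fingerprint_edges = sort(fp_set - 1L),
           fingerprint_sd = fingerprint_sd,
           sex_effect = sex_effect, sex_effect_edges = sort(sex_set - 1L),
           age_effect = age_effect, age_effect_edges = sort(age_set - 1L),
           noise_sd = noise_sd, seed = as.integer(seed)),
      class = "fc_ground_truth"
    )
  })
}

#' Per-subject fingerprint covariance offsets
#'
#' Deterministic in (truth seed, subject id): the same subject always gets
#' the same fingerprint component, which is what makes fingerprint edges
#' session-stable and subject-specific.
#'
#' @param truth a [make_ground_truth()] object.
#' @param subject_id subject identifier.
#' @return numeric edge vector (length E) with nonzeros on the fingerprint
#'   edges.
#' @export
fingerprint_offsets <- function(truth, subject_id) {
  v <- numeric(truth$n_edges)
  fp <- truth$fingerprint_edges
  if (length(fp) > 0) {
    v[fp + 1L] <- with_seed(
      seed_stream(truth$seed, "fingerprint", subject_id),
      stats::rnorm(length(fp), 0, truth$fingerprint_sd)
    )
  }
  v
}

# Assemble the (subject, clip) covariance and repair it to positive definite.
subject_clip_cov <- function(truth, meta_row, clip_label) {
  pert <- truth$clip_components[, clip_label] +
    fingerprint_offsets(truth, meta_row$subject_id) +
    truth$sex_effect * (if (meta_row$sex == "F") 0.5 else -0.5) +
    truth$age_effect * (meta_row$age_group - 2)
  sigma <- truth$base_cov + devectorize(pert, truth$n_regions)
  sigma <- (sigma + t(sigma)) / 2
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) {
    es <- eigen(sigma, symmetric = TRUE)
    vals <- pmax(es$values, 1e-6)
    sigma <- es$vectors %*% (vals * t(es$vectors))
    sigma <- (sigma + t(sigma)) / 2
    if (inherits(tryCatch(chol(sigma), error = identity), "error")) {
      stop_data("covariance repair failed for subject ", meta_row$subject_id,
                ", clip ", clip_label)
    }
  }
  sigma
}

#' Simulate one subject x clip parcellated time series
#'
#' Zero-mean multivariate normal draw whose covariance is the ground-truth
#' composition for this subject and clip. The random stream is derived by
#' stable hashing of (master seed, subject id, clip label), so regeneration
#' is order-independent.
#'
#' @param meta one-row subject metadata (from [make_cohort()]).
#' @param clip one clip-catalogue row (needs `clip_label`, `duration_tr`).
#' @param truth ground truth from [make_ground_truth()].
#' @param n_tr number of time points to simulate; defaults to the clip
#'   duration.
#' @return a [parcellated_ts()] object of shape `n_tr x n_regions`.
#' @export
simulate_timeseries <- function(meta, clip, truth, n_tr = clip$duration_tr) {
  sigma <- subject_clip_cov(truth, meta, clip$clip_label)
  ch <- chol(sigma)
  x <- with_seed(
    seed_stream(truth$seed, "ts", meta$subject_id, clip$clip_label),
    matrix(stats::rnorm(n_tr * truth$n_regions), n_tr, truth$n_regions)
  ) %*% ch
  parcellated_ts(x, meta$subject_id, clip$clip_label)
}

#' Simulate a full subject x clip dataset bundle
#'
#' One time series per subject per clip, with the catalogue durations scaled
#' by `duration_scale` and extended by `extra_tr` trailing TRs (emulating
#' the segmentation that keeps 10 TRs after each clip for the hemodynamic
#' peak delay).
#'
#' @param cohort subject table from [make_cohort()].
#' @param catalogue clip catalogue from [clip_catalogue()].
#' @param truth ground truth from [make_ground_truth()].
#' @param duration_scale multiplier on catalogue durations (default 0.5,
#'   desk scale).
#' @param extra_tr trailing TRs appended to each segment (default 10).
#' @return object of class `movie_dataset`: list with `timeseries` (list of
#'   [parcellated_ts()]), `cohort`, `catalogue`, `truth`, and `fingerprints`
#'   (n_subjects x E matrix of planted fingerprint offsets).
#' @export
make_dataset <- function(cohort, catalogue, truth, duration_scale = 0.5,
                         extra_tr = 10) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop_invalid("cohort must be a non-empty data.frame")
  }
  validate_catalogue(catalogue)
  if (nrow(catalogue) != truth$n_clips) {
    stop_invalid("catalogue has ", nrow(catalogue), " clips but truth expects ",
                 truth$n_clips)
  }
  n_tr <- pmax(5L, as.integer(round(catalogue$duration_tr * duration_scale)) + as.integer(extra_tr))
  ts_list <- vector("list", nrow(cohort) * nrow(catalogue))
  nm <- character(length(ts_list))
  pos <- 1L
  for (si in seq_len(nrow(cohort))) {
    for (ci in seq_len(nrow(catalogue))) {
      ts_list[[pos]] <- simulate_timeseries(cohort[si, ], catalogue[ci, ],
                                            truth, n_tr = n_tr[ci])
      nm[pos] <- paste(cohort$subject_id[si], catalogue$clip_label[ci])
      pos <- pos + 1L
    }
  }
  names(ts_list) <- nm
  fp <- t(vapply(cohort$subject_id, function(s) fingerprint_offsets(truth, s),
                 numeric(truth$n_edges)))
  structure(
    list(timeseries = ts_list, cohort = cohort, catalogue = catalogue,
         truth = truth, fingerprints = fp),
    class = "movie_dataset"
  )
}

#' Simulate FC edge observations directly at the edge level
#'
#' Generates the long-format observation structure the per-edge mixed model
#' assumes — subject random intercept + clip effect + planted sex/age fixed
#' effects + residual noise — without passing through time-series
#' simulation, so planted effect sizes are exact in residual-SD units. Used
#' to calibrate sensitivity, FDR and type-I error of the effects stage.
#'
#' @param n_subjects,n_clips cohort and session sizes.
#' @param n_edges_total total number of edges simulated.
#' @param sex_edges,sex_delta number of planted sex edges and the
#'   female-minus-male gap in units of `sigma_resid` (random sign per edge).
#' @param age_edges,age_slope planted age edges and per-level slope in
#'   `sigma_resid` units.
#' @param sigma_subject SD of the subject random intercept.
#' @param sigma_clip SD of the shared per-(clip, edge) effects (makes the
#'   clip term real).
#' @param sigma_resid residual SD (the "1 SD" unit for planted deltas).
#' @param motion_leak coefficient of mean motion on every edge's FC
#'   (0 = null covariate).
#' @param motion_sex_gap additive shift of mean motion in males, creating a
#'   motion-sex confound that the covariate must absorb.
#' @param sex_ratio,seed cohort parameters.
#' @return list with `stack` (a [session_stack()]), `meta` (cohort),
#'   `planted` (edge-id lists and signs, 0-based).
#' @export
simulate_edge_table <- function(n_subjects = 40, n_clips = 15,
                                n_edges_total = 350,
                                sex_edges = 50, sex_delta = 1,
                                age_edges = 0, age_slope = 0,
                                sigma_subject = 0.5, sigma_clip = 0.3,
                                sigma_resid = 1,
                                motion_leak = 0, motion_sex_gap = 0,
                                sex_ratio = 0.5, seed = 1) {
  meta <- make_cohort(n_subjects, sex_ratio, seed = seed_stream(seed, "edgecohort"))
  if (motion_sex_gap != 0) {
    meta$mean_motion <- meta$mean_motion + ifelse(meta$sex == "M", motion_sex_gap, 0)
  }
  n <- nrow(meta)
  e_t <- as.integer(n_edges_total)
  with_seed(seed_stream(seed, "edgetable"), {
    sex_set <- if (sex_edges > 0) sort(sample(e_t, sex_edges)) else integer()
    age_set <- if (age_edges > 0) sort(sample(setdiff(seq_len(e_t), sex_set), age_edges)) else integer()
    sex_sign <- numeric(e_t)
    if (length(sex_set)) sex_sign[sex_set] <- sample(c(-1, 1), length(sex_set), replace = TRUE)
    age_sign <- numeric(e_t)
    if (length(age_set)) age_sign[age_set] <- sample(c(-1, 1), length(age_set), replace = TRUE)

    b <- matrix(stats::rnorm(n * e_t, 0, sigma_subject), n, e_t)
    g <- matrix(stats::rnorm(n_clips * e_t, 0, sigma_clip), n_clips, e_t)
    s_num <- ifelse(meta$sex == "F", 0.5, -0.5)
    a_num <- meta$age_group - 2
    vals <- array(0, dim = c(n, n_clips, e_t))
    for (j in seq_len(n_clips)) {
      eps <- matrix(stats::rnorm(n * e_t, 0, sigma_resid), n, e_t)
      vals[, j, ] <- b +
        matrix(g[j, ], n, e_t, byrow = TRUE) +
        outer(s_num, sex_sign * sex_delta * sigma_resid) +
        outer(a_num, age_sign * age_slope * sigma_resid) +
        motion_leak * matrix(meta$mean_motion, n, e_t) +
        eps
    }
    list(
      stack = session_stack(vals, meta$subject_id, seq_len(n_clips)),
      meta = meta,
      planted = list(sex_edges = sex_set - 1L, sex_sign = sex_sign[sex_set],
                     age_edges = age_set - 1L, age_sign = age_sign[age_set])
    )
  })
}

#' Write a dataset bundle to plain-text files
#'
#' One TSV per subject x clip (rows = time points, columns = region ids),
#' plus metadata, partition and clip-catalogue TSVs and a JSON ground-truth
#' sidecar.
#'
#' @param dataset a [make_dataset()] bundle.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "movie_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(dataset$timeseries)) {
    ts <- dataset$timeseries[[nm]]
    f <- file.path(dir, sprintf("%s_clip-%02d_ts.tsv", ts$subject_id, ts$clip_label))
    df <- as.data.frame(ts$data)
    names(df) <- sprintf("region_%03d", seq_len(ncol(df)) - 1L)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  f_meta <- file.path(dir, "participants.tsv")
  utils::write.table(dataset$cohort, f_meta, sep = "\t", quote = FALSE, row.names = FALSE)
  f_part <- file.path(dir, "networks.tsv")
  utils::write.table(dataset$truth$partition, f_part, sep = "\t", quote = FALSE, row.names = FALSE)
  f_cat <- file.path(dir, "clips.tsv")
  utils::write.table(dataset$catalogue, f_cat, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- dataset$truth
  sidecar <- list(
    n_regions = truth$n_regions, n_clips = truth$n_clips, seed = truth$seed,
    noise_sd = truth$noise_sd, fingerprint_sd = truth$fingerprint_sd,
    clip_edges = truth$clip_edges, fingerprint_edges = truth$fingerprint_edges,
    sex_effect_edges = truth$sex_effect_edges,
    sex_effect = truth$sex_effect[truth$sex_effect_edges + 1L],
    age_effect_edges = truth$age_effect_edges,
    age_effect = truth$age_effect[truth$age_effect_edges + 1L]
  )
  f_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(sidecar, f_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f_meta, f_part, f_cat, f_truth))
}
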