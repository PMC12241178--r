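# Per-edge mixed-effects testing of sex, age and clip effects on FC.

effect_terms <- c("sex", "age", "clip", "sex:age", "sex:clip", "age:clip")

# Residual sums of squares of Y (columns = edges) on design X, via QR.
rss_cols <- function(x, y) {
  q <- qr.Q(qr(x))
  colSums((y - q %*% crossprod(q, y))^2)
}

#' Fit the per-edge mixed model across all edges of a session stack
#'
#' The model for each edge is
#' `fc ~ sex + age + clip + sex:age + sex:clip + age:clip + motion`
#' with a random intercept per subject; movie clip is the within-subject
#' factor, sex and age (ordinal numeric 1..3) are between-subject factors,
#' and mean head motion is a between-subject covariate. For the balanced
#' design produced here (every subject sees every clip once) the model is
#' fitted exactly by the classical between-within (split-plot) decomposition
#' with containment denominator degrees of freedom: subject means carry the
#' between-subject stratum (sex, age, sex:age, motion), within-subject
#' deviations carry the within stratum (clip, sex:clip, age:clip). Type III
#' (drop-term) F-tests with sum-to-zero codings are computed for every term,
#' vectorised across edges. `method = "lmer"` instead fits each edge with
#' `lmerTest` (Satterthwaite df), falling back to OLS with the subject
#' omitted when the random-intercept fit is singular; it is orders of
#' magnitude slower and intended for cross-checking.
#'
#' Partial eta squared is recovered from the F statistic as
#' `F * df1 / (F * df1 + df2)`. Directions are reported for the sex and age
#' main effects only: + = greater FC in females / FC increasing with age.
#'
#' @param stack a [session_stack()] of FC edge values (thresholded adjacency
#'   values by default convention; pass an unthresholded stack for the
#'   continuous-z variant).
#' @param meta subject metadata aligned with `stack$subjects` (columns
#'   `subject_id`, `sex`, `age_group`, `mean_motion`).
#' @param alpha FDR level for the per-term Benjamini-Hochberg correction.
#' @param method `"between_within"` (exact, vectorised; default) or
#'   `"lmer"`.
#' @return object of class `effects_table`: data.frame with one row per
#'   edge x term (`edge_id` 0-based, `term`, `F`, `df1`, `df2`, `p`, `q`,
#'   `eta_p2`, `direction`), plus attribute `flagged_edges` (0-based ids of
#'   zero-variance/degenerate edges excluded from the FDR families).
#' @export
fit_edge_models <- function(stack, meta, alpha = 0.05,
                            method = c("between_within", "lmer")) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "session_stack"))
  meta <- meta[match(stack$subjects, meta$subject_id), , drop = FALSE]
  if (anyNA(meta$subject_id)) stop_data("metadata missing for some stack subjects")
  n <- dim(stack$values)[1L]
  n_c <- dim(stack$values)[2L]
  e_t <- dim(stack$values)[3L]
  if (n_c < 2L) stop_invalid("need at least 2 clips")
  if (min(table(meta$sex)) < 2L) stop_invalid("need at least 2 subjects per sex")
  if (length(unique(meta$age_group)) < 2L) {
    stop_invalid("age_group must vary across subjects")
  }
  if (method == "lmer") {
    return(fit_edge_models_lmer(stack, meta, alpha))
  }

  v <- stack$values
  s_num <- ifelse(meta$sex == "F", 0.5, -0.5)
  a_num <- meta$age_group - mean(meta$age_group)
  mo <- meta$mean_motion - mean(meta$mean_motion)

  # Between stratum: subject means.
  m_mat <- matrix(0, n, e_t)
  for (j in seq_len(n_c)) m_mat <- m_mat + matrix(v[, j, ], n, e_t)
  m_mat <- m_mat / n_c
  xb <- cbind(1, s_num, a_num, s_num * a_num, mo)
  if (qr(xb)$rank < ncol(xb)) stop_data("between-subject design is rank deficient")
  df_den_b <- n - ncol(xb)
  if (df_den_b < 1L) stop_invalid("too few subjects for the between-subject design")
  rss_b <- rss_cols(xb, m_mat)
  coef_b <- solve(crossprod(xb), crossprod(xb, m_mat))
  between <- list(sex = 2L, age = 3L, `sex:age` = 4L)

  # Within stratum: deviations from subject means.
  clipc <- stats::contr.sum(n_c)                       # n_c x (n_c - 1)
  rows_clip <- rep(seq_len(n_c), each = n)
  w_clip <- clipc[rows_clip, , drop = FALSE]
  w_s <- w_clip * rep(s_num, n_c)
  w_a <- w_clip * rep(a_num, n_c)
  w_full <- cbind(w_clip, w_s, w_a)
  d_mat <- matrix(v, n * n_c, e_t) - m_mat[rep(seq_len(n), n_c), , drop = FALSE]
  df_den_w <- n * (n_c - 1L) - ncol(w_full)
  if (df_den_w < 1L) stop_invalid("too few subjects for the within-subject design")
  rss_w <- rss_cols(w_full, d_mat)
  q_w <- n_c - 1L
  within_cols <- list(clip = seq_len(q_w),
                      `sex:clip` = q_w + seq_len(q_w),
                      `age:clip` = 2L * q_w + seq_len(q_w))

  # Degenerate edges: no residual variation in either stratum.
  tol_b <- 1e-12 * max(1, max(abs(m_mat)))^2
  tol_w <- 1e-12 * max(1, max(abs(d_mat)))^2
  flagged <- which(rss_b <= tol_b | rss_w <= tol_w) - 1L

  rows <- vector("list", length(effect_terms))
  names(rows) <- effect_terms
  for (term in effect_terms) {
    if (term %in% names(between)) {
      red <- xb[, -between[[term]], drop = FALSE]
      fstat <- (rss_cols(red, m_mat) - rss_b) / (rss_b / df_den_b)
      df1 <- 1; df2 <- df_den_b
      dir <- if (term == "sex") sign(coef_b[2L, ]) else if (term == "age") sign(coef_b[3L, ]) else NA_real_
    } else {
      red <- w_full[, -within_cols[[term]], drop = FALSE]
      fstat <- ((rss_cols(red, d_mat) - rss_w) / q_w) / (rss_w / df_den_w)
      df1 <- q_w; df2 <- df_den_w
      dir <- NA_real_
    }
    fstat[flagged + 1L] <- NA_real_
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
    rows[[term]] <- data.frame(
      edge_id = 0:(e_t - 1L), term = term, F = fstat, df1 = df1, df2 = df2,
      p = p, q = NA_real_,
      eta_p2 = (fstat * df1) / (fstat * df1 + df2),
      direction = if (term %in% c("sex", "age")) dir else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  finalize_effects(do.call(rbind, rows), alpha, flagged)
}

# Per-term BH families over non-flagged edges.
finalize_effects <- function(tab, alpha, flagged) {
  for (term in unique(tab$term)) {
    sel <- tab$term == term & !is.na(tab$p)
    if (any(sel)) {
      tab$q[sel] <- benjamini_hochberg(tab$p[sel], alpha)$q
    }
  }
  rownames(tab) <- NULL
  structure(tab, class = c("effects_table", "data.frame"),
            flagged_edges = flagged, alpha = alpha)
}

# lmerTest route: one fit per edge, Satterthwaite type-III ANOVA, with an
# OLS fallback (subject omitted) when the random-intercept fit is singular.
fit_edge_models_lmer <- function(stack, meta, alpha) {
  if (!requireNamespace("lmerTest", quietly = TRUE)) {
    stop("method = 'lmer' requires the lmerTest package")
  }
  v <- stack$values
  n <- dim(v)[1L]; n_c <- dim(v)[2L]; e_t <- dim(v)[3L]
  base <- data.frame(
    subject = factor(rep(meta$subject_id, n_c)),
    sex = factor(rep(as.character(meta$sex), n_c), levels = c("F", "M")),
    age = rep(meta$age_group - mean(meta$age_group), n_c),
    clip = factor(rep(seq_len(n_c), each = n)),
    motion = rep(meta$mean_motion - mean(meta$mean_motion), n_c)
  )
  s_num <- ifelse(base$sex == "F", 0.5, -0.5)
  ctr <- list(sex = "contr.sum", clip = "contr.sum")
  rows <- list()
  flagged <- integer()
  for (e in seq_len(e_t)) {
    base$y <- as.numeric(matrix(v[, , e], n, n_c))
    fit <- tryCatch(
      lmerTest::lmer(y ~ sex + age + clip + sex:age + sex:clip + age:clip +
                       motion + (1 | subject),
                     data = base, contrasts = ctr),
      error = function(err) NULL
    )
    singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
    if (singular) {
      flagged <- c(flagged, e - 1L)
      fit <- stats::lm(y ~ sex + age + clip + sex:age + sex:clip + age:clip +
                         motion, data = base, contrasts = ctr)
      an <- car::Anova(fit, type = 3)
      an <- an[!(rownames(an) %in% c("(Intercept)", "Residuals")), , drop = FALSE]
      fvals <- an[, "F value"]; df1 <- an[, "Df"]
      df2 <- rep(stats::df.residual(fit), nrow(an))
      nms <- rownames(an)
    } else {
      an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
      fvals <- an[, "F value"]; df1 <- an[, "NumDF"]; df2 <- an[, "DenDF"]
      nms <- rownames(an)
    }
    nms[nms == "age:sex"] <- "sex:age"
    keep <- nms %in% effect_terms
    p <- stats::pf(fvals[keep], df1[keep], df2[keep], lower.tail = FALSE)
    cf <- if (singular) stats::coef(fit) else lme4::fixef(fit)
    # contr.sum with levels (F, M) codes F = +1, so sign(sex1) = sign(F - M).
    dir_sex <- sign(cf[["sex1"]])
    dir_age <- sign(cf[["age"]])
    rows[[e]] <- data.frame(
      edge_id = e - 1L, term = nms[keep], F = fvals[keep],
      df1 = df1[keep], df2 = df2[keep], p = p, q = NA_real_,
      eta_p2 = (fvals[keep] * df1[keep]) / (fvals[keep] * df1[keep] + df2[keep]),
      direction = ifelse(nms[keep] == "sex", dir_sex,
                         ifelse(nms[keep] == "age", dir_age, NA_real_)),
      stringsAsFactors = FALSE
    )
  }
  finalize_effects(do.call(rbind, rows), alpha, flagged)
}

#' Fit the mixed model for a single edge from long-format observations
#'
#' @param obs data.frame with one row per subject x clip: `subject_id`,
#'   `clip_label`, `fc_value`, `sex`, `age_group`, `mean_motion`.
#' @param ... passed to [fit_edge_models()].
#' @return one-edge `effects_table` (six term rows).
#' @export
fit_edge_model <- function(obs, ...) {
  need <- c("subject_id", "clip_label", "fc_value", "sex", "age_group", "mean_motion")
  if (!all(need %in% names(obs))) {
    stop_invalid("obs must have columns ", paste(need, collapse = ", "))
  }
  subjects <- unique(obs$subject_id)
  clips <- sort(unique(obs$clip_label))
  vals <- array(NA_real_, dim = c(length(subjects), length(clips), 1L))
  vals[cbind(match(obs$subject_id, subjects), match(obs$clip_label, clips), 1L)] <-
    obs$fc_value
  if (anyNA(vals)) stop_data("obs must contain one record per subject x clip")
  meta <- unique(obs[, c("subject_id", "sex", "age_group", "mean_motion")])
  stk <- session_stack(vals, subjects, clips)
  fit_edge_models(stk, meta, ...)
}

#' Benjamini-Hochberg step-up false discovery rate control
#'
#' Standard step-up procedure: with p-values ranked ascending,
#' `q_i = min over k >= rank(i) of m * p_(k) / k`, capped at 1; the null is
#' rejected wherever `q <= alpha`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return list with `q` (adjusted values, same order as input) and `reject`
#'   (logical vector).
#' @export
benjamini_hochberg <- function(p_values, alpha = 0.05) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop_invalid("p-values must be in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  list(q = q, reject = q <= alpha)
}

#' Network-level aggregation of significant edges
#'
#' Counts significant edges (q <= alpha) for a model term within each
#' ordered network pair (a <= b), split by effect direction — the
#' network-level readout of where, e.g., females versus males show greater
#' FC.
#'
#' @param effects an `effects_table` from [fit_edge_models()].
#' @param partition region-to-network table from [network_partition()].
#' @param term one of `sex`, `age`, `clip`, `sex:age`, `sex:clip`,
#'   `age:clip`.
#' @param index edge index from [edge_index()] for the region count of the
#'   partition.
#' @param alpha significance level on q (defaults to the table's FDR level).
#' @return list of K x K matrices (K = number of networks): `positive`,
#'   `negative` (directional counts; zero for terms without direction),
#'   `total`, and `net` (= positive - negative). Only cells with row <= col
#'   are populated.
#' @export
aggregate_by_network <- function(effects, partition, term,
                                 index = edge_index(nrow(partition)),
                                 alpha = attr(effects, "alpha")) {
  stopifnot(term %in% effects$term)
  if (is.null(alpha)) alpha <- 0.05
  k_nets <- max(partition$network_id)
  nm <- partition$network_name[match(seq_len(k_nets), partition$network_id)]
  zero <- matrix(0L, k_nets, k_nets, dimnames = list(nm, nm))
  pos <- neg <- tot <- zero
  sub <- effects[effects$term == term & !is.na(effects$q) & effects$q <= alpha, ]
  if (nrow(sub) > 0L) {
    ii <- index$i[match(sub$edge_id, index$k)]
    jj <- index$j[match(sub$edge_id, index$k)]
    if (anyNA(ii) || anyNA(jj)) stop_data("edge id outside the edge index")
    net_i <- partition$network_id[match(ii, partition$region_id)]
    net_j <- partition$network_id[match(jj, partition$region_id)]
    if (anyNA(net_i) || anyNA(net_j)) stop_data("region not mapped to a network")
    a <- pmin(net_i, net_j)
    b <- pmax(net_i, net_j)
    for (r in seq_len(nrow(sub))) {
      tot[a[r], b[r]] <- tot[a[r], b[r]] + 1L
      if (!is.na(sub$direction[r])) {
        if (sub$direction[r] > 0) pos[a[r], b[r]] <- pos[a[r], b[r]] + 1L
        if (sub$direction[r] < 0) neg[a[r], b[r]] <- neg[a[r], b[r]] + 1L
      }
    }
  }
  list(positive = pos, negative = neg, total = tot, net = pos - neg)
}
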