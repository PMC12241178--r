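# Fingerprint scoring: Average Cross-Session Correlation (ACSC).

# Column-wise sum of |x_p - x_q| over all ordered pairs (p, q), p != q.
# Uses the sorted-weights identity sum_{p,q}|x_p - x_q| = 2 * sum_k
# (2k - m - 1) x_(k), so each column costs one sort instead of m^2 pairs.
pairsum_abs_cols <- function(x) {
  m <- nrow(x)
  if (m < 2L) return(numeric(ncol(x)))
  xs <- matrix(x[order(col(x), x)], m, ncol(x))  # all columns sorted at once
  w <- 2 * (2 * seq_len(m) - m - 1)
  as.numeric(crossprod(xs, w))
}

#' Per-edge ACSC fingerprint scores
#'
#' For each edge independently, consider the subject x subject matrix S of
#' cross-session distances (1-D Euclidean distance = absolute difference;
#' only distinct-session pairs enter, on and off the diagonal). The score is
#' `mean(off-diagonal of S) - mean(diagonal of S)`, so a high score means the
#' edge is stable within a subject across clips while differing between
#' subjects — a good fingerprint feature. `literal_sign = TRUE` flips the
#' sign (diagonal minus off-diagonal).
#'
#' @param stack a [session_stack()] (n_subjects x n_sessions x E).
#' @param literal_sign flip to the diagonal-minus-off-diagonal convention.
#' @return object of class `acsc_scores`: list with `score` (length E),
#'   `rank` (0-based edge ids by descending score, ascending-id tie-break),
#'   `flagged` (0-based ids of zero-variance edges, scored 0).
#' @export
acsc_score <- function(stack, literal_sign = FALSE) {
  stopifnot(inherits(stack, "session_stack"))
  v <- stack$values
  n <- dim(v)[1L]; s <- dim(v)[2L]; e_t <- dim(v)[3L]
  flat <- matrix(v, n * s, e_t)
  t_all <- pairsum_abs_cols(flat)
  t_sess <- numeric(e_t)
  for (a in seq_len(s)) {
    t_sess <- t_sess + pairsum_abs_cols(matrix(v[, a, ], n, e_t))
  }
  t_subj <- numeric(e_t)
  for (i in seq_len(n)) {
    t_subj <- t_subj + pairsum_abs_cols(matrix(v[i, , ], s, e_t))
  }
  diag_mean <- t_subj / (n * s * (s - 1))
  off_mean <- (t_all - t_sess - t_subj) / (n * (n - 1) * s * (s - 1))
  score <- off_mean - diag_mean
  if (literal_sign) score <- -score
  rng <- apply(flat, 2L, function(col) max(col) - min(col))
  flagged <- which(rng == 0) - 1L
  score[flagged + 1L] <- 0
  structure(
    list(score = score, rank = order(-score, seq_along(score)) - 1L,
         flagged = flagged),
    class = "acsc_scores"
  )
}

#' Cross-session distance matrix over subjects
#'
#' `S[i, j]` is the mean, over all ordered session pairs (a, b) with a != b,
#' of the Euclidean distance between subject i's edge-subset vector in
#' session a and subject j's in session b. Diagonal entries therefore
#' average only distinct-session (within-subject) distances.
#'
#' @param stack a [session_stack()].
#' @param edges 0-based edge ids to use, or `"all"`.
#' @return n_subjects x n_subjects symmetric nonnegative matrix.
#' @export
cross_session_matrix <- function(stack, edges = "all") {
  stopifnot(inherits(stack, "session_stack"))
  v <- stack$values
  n <- dim(v)[1L]; s <- dim(v)[2L]
  if (s < 2L) stop_invalid("need at least 2 sessions")
  if (identical(edges, "all")) {
    cols <- seq_len(dim(v)[3L])
  } else {
    if (length(edges) == 0L) stop_invalid("edge subset must be non-empty")
    cols <- as.integer(edges) + 1L
    if (any(cols < 1L) || any(cols > dim(v)[3L])) stop_invalid("edge id out of range")
  }
  acc <- matrix(0, n, n)
  for (a in seq_len(s - 1L)) {
    xa <- matrix(v[, a, cols], n, length(cols))
    ra <- rowSums(xa^2)
    for (b in (a + 1L):s) {
      xb <- matrix(v[, b, cols], n, length(cols))
      sq <- outer(ra, rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
      d <- sqrt(pmax(sq, 0))
      acc <- acc + d + t(d)
    }
  }
  acc / (s * (s - 1))
}

#' Select the top-k edges by ACSC score
#'
#' @param scores an [acsc_score()] object.
#' @param k number of edges, 1 <= k <= E.
#' @return 0-based edge ids, highest score first (ties by ascending id).
#' @export
select_top_k <- function(scores, k) {
  stopifnot(inherits(scores, "acsc_scores"))
  e_t <- length(scores$score)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > e_t) {
    stop_invalid("k must be in [1, ", e_t, "]")
  }
  scores$rank[seq_len(as.integer(k))]
}
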