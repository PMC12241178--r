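#' Canonical edge indexing for an R-region connectome
#'
#' Fixed bijection between the flat edge id `k` and the region pair
#' `(i, j)`, `i < j`, enumerated row-major over the upper triangle and
#' 0-based, so that feature ids and ACSC ranks are stable across the whole
#' pipeline and across file exports.
#'
#' @param n_regions number of regions R (>= 2).
#' @return data.frame with columns `k` (0..E-1), `i`, `j` (0-based region
#'   ids, i < j), where E = R(R-1)/2.
#' @export
edge_index <- function(n_regions) {
  if (n_regions < 2L) stop_invalid("need at least 2 regions")
  n <- as.integer(n_regions)
  i <- rep.int(0:(n - 2L), times = (n - 1L):1L)
  j <- unlist(lapply(1:(n - 1L), function(a) a:(n - 1L)), use.names = FALSE)
  data.frame(k = 0:(length(i) - 1L), i = i, j = j)
}

#' Number of unique edges for R regions
#' @param n_regions number of regions.
#' @return R(R-1)/2.
#' @export
n_edges <- function(n_regions) as.integer(n_regions * (n_regions - 1) / 2)

#' Flatten a symmetric matrix to its canonical edge vector
#'
#' @param m symmetric R x R matrix.
#' @param tol symmetry tolerance (default 1e-10); larger asymmetry is a data
#'   error.
#' @return numeric vector of length R(R-1)/2 in [edge_index()] order.
#' @export
vectorize <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_data("expected a square matrix")
  if (max(abs(m - t(m))) > tol) stop_data("matrix is not symmetric within tolerance")
  idx <- edge_index(nrow(m))
  m[cbind(idx$i + 1L, idx$j + 1L)]
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' Exact inverse of [vectorize()] (up to the diagonal, which carries no edge
#' information).
#'
#' @param v edge vector of length R(R-1)/2.
#' @param n_regions number of regions R.
#' @param diag_value value placed on the diagonal (default 0).
#' @return symmetric R x R matrix.
#' @export
devectorize <- function(v, n_regions, diag_value = 0) {
  if (length(v) != n_edges(n_regions)) {
    stop_invalid("edge vector length ", length(v), " does not match R = ", n_regions)
  }
  idx <- edge_index(n_regions)
  m <- matrix(diag_value, n_regions, n_regions)
  m[cbind(idx$i + 1L, idx$j + 1L)] <- v
  m[cbind(idx$j + 1L, idx$i + 1L)] <- v
  m
}

#' Construct a parcellated time-series object
#'
#' @param data T x R numeric matrix (time points x regions).
#' @param subject_id subject identifier.
#' @param clip_label integer clip label.
#' @param tr_seconds repetition time in seconds (default 1, the 7T movie
#'   protocol).
#' @return object of class `parcellated_ts`.
#' @export
parcellated_ts <- function(data, subject_id = "s", clip_label = 1L,
                           tr_seconds = 1) {
  if (!is.matrix(data) || !is.numeric(data)) stop_data("data must be a numeric matrix")
  if (nrow(data) < 3L) stop_invalid("need at least 3 time points")
  if (ncol(data) < 2L) stop_invalid("need at least 2 regions")
  if (!all(is.finite(data))) stop_data("time series contains non-finite values")
  if (tr_seconds <= 0) stop_invalid("tr_seconds must be positive")
  structure(
    list(subject_id = as.character(subject_id),
         clip_label = as.integer(clip_label),
         data = data, tr_seconds = tr_seconds),
    class = "parcellated_ts"
  )
}

#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlations between region time courses, Fisher
#' z-transformed (`atanh`) after clipping to +/-(1 - 1e-7) so perfect
#' correlations stay finite. Constant region pairs get r := 0 and are
#' recorded as degenerate edges.
#'
#' @param ts a [parcellated_ts()] object or a plain T x R matrix.
#' @return object of class `fc_matrix` with elements `z` (R x R symmetric,
#'   zero diagonal), `degenerate_edges` and `clipped_edges` (0-based edge
#'   ids), `subject_id`, `clip_label`, and placeholders `adjacency`,
#'   `sparsity` filled by [threshold_by_sparsity()].
#' @export
compute_fc <- function(ts) {
  if (is.matrix(ts)) ts <- parcellated_ts(ts)
  if (!inherits(ts, "parcellated_ts")) stop_invalid("ts must be a parcellated_ts or matrix")
  x <- ts$data
  r_n <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  idx <- edge_index(r_n)
  const <- sds == 0
  degenerate <- idx$k[const[idx$i + 1L] | const[idx$j + 1L]]
  r[is.na(r)] <- 0
  bound <- 1 - 1e-7
  v <- r[cbind(idx$i + 1L, idx$j + 1L)]
  clipped <- idx$k[abs(v) >= bound]
  clipped <- setdiff(clipped, degenerate)
  z <- atanh(pmin(pmax(r, -bound), bound))
  diag(z) <- 0
  z <- (z + t(z)) / 2
  structure(
    list(z = z, adjacency = NULL, sparsity = NA_real_,
         degenerate_edges = degenerate, clipped_edges = clipped,
         subject_id = ts$subject_id, clip_label = ts$clip_label),
    class = "fc_matrix"
  )
}

#' Proportional sparsity thresholding of a connectivity matrix
#'
#' Retains the top `floor(sparsity * E)` upper-triangle edges ranked by
#' signed Fisher-z value (largest positive first; ties broken by ascending
#' edge id), zeroes the rest, and mirrors the result, so every subject's
#' network keeps exactly the same number of edges. Retained entries keep
#' their continuous z values.
#'
#' @param fc an `fc_matrix` from [compute_fc()], or a symmetric z matrix.
#' @param sparsity retained edge fraction, in (0, 1); 0.25 is the primary
#'   setting, with 0.2 and 0.3 as robustness settings.
#' @param rank_by `"signed"` (default) ranks by z; `"absolute"` ranks by |z|.
#' @return an `fc_matrix` with `adjacency` and `sparsity` filled in.
#' @export
threshold_by_sparsity <- function(fc, sparsity = 0.25,
                                  rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity >= 1) {
    stop_invalid("sparsity must be a single value in (0, 1)")
  }
  if (is.matrix(fc)) {
    fc <- structure(list(z = fc, adjacency = NULL, sparsity = NA_real_,
                         degenerate_edges = integer(), clipped_edges = integer(),
                         subject_id = NA_character_, clip_label = NA_integer_),
                    class = "fc_matrix")
  }
  v <- vectorize(fc$z)
  e_total <- length(v)
  m_keep <- floor(sparsity * e_total)
  key <- if (rank_by == "signed") v else abs(v)
  ord <- order(-key, seq_along(v))
  keep <- ord[seq_len(m_keep)]
  av <- numeric(e_total)
  av[keep] <- v[keep]
  fc$adjacency <- devectorize(av, nrow(fc$z))
  fc$sparsity <- sparsity
  fc
}

#' Bundle per-(subject, clip) edge vectors into a session stack
#'
#' Computes the FC matrix of every subject x clip time series, thresholds it
#' (unless `thresholded = FALSE`), vectorizes, and stacks the result as an
#' `n_subjects x n_clips x E` array — the container the fingerprinting and
#' classification stages operate on.
#'
#' @param dataset a dataset bundle from [make_dataset()], or a list of
#'   `parcellated_ts` objects.
#' @param sparsity retained edge fraction passed to [threshold_by_sparsity()].
#' @param thresholded if `FALSE`, stack the unthresholded z vectors.
#' @param rank_by ranking rule for thresholding.
#' @return object of class `session_stack`: list with `values`
#'   (n x s x E array), `subjects`, `clip_labels`, `n_regions`, `sparsity`.
#' @export
fc_stack <- function(dataset, sparsity = 0.25, thresholded = TRUE,
                     rank_by = "signed") {
  ts_list <- if (inherits(dataset, "movie_dataset")) dataset$timeseries else dataset
  subjects <- unique(vapply(ts_list, function(t) t$subject_id, character(1)))
  clips <- sort(unique(vapply(ts_list, function(t) t$clip_label, integer(1))))
  r_n <- ncol(ts_list[[1L]]$data)
  e_total <- n_edges(r_n)
  vals <- array(NA_real_, dim = c(length(subjects), length(clips), e_total))
  key <- paste(vapply(ts_list, function(t) t$subject_id, character(1)),
               vapply(ts_list, function(t) t$clip_label, integer(1)))
  names(ts_list) <- key
  for (si in seq_along(subjects)) {
    for (ci in seq_along(clips)) {
      ts <- ts_list[[paste(subjects[si], clips[ci])]]
      if (is.null(ts)) {
        stop_data("subject ", subjects[si], " is missing clip ", clips[ci])
      }
      fc <- compute_fc(ts)
      v <- if (thresholded) {
        vectorize(threshold_by_sparsity(fc, sparsity, rank_by)$adjacency)
      } else {
        vectorize(fc$z)
      }
      vals[si, ci, ] <- v
    }
  }
  session_stack(vals, subjects, clips, n_regions = r_n,
                sparsity = if (thresholded) sparsity else NA_real_)
}

#' Construct a session stack directly from an array of edge values
#'
#' @param values n_subjects x n_sessions x E numeric array.
#' @param subjects subject identifiers (length n_subjects).
#' @param clip_labels session (clip) labels (length n_sessions).
#' @param n_regions region count the edges refer to (optional).
#' @param sparsity sparsity the values were thresholded at (NA if none).
#' @return object of class `session_stack`.
#' @export
session_stack <- function(values, subjects = NULL, clip_labels = NULL,
                          n_regions = NA_integer_, sparsity = NA_real_) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_invalid("values must be a 3-d array (subjects x sessions x edges)")
  }
  d <- dim(values)
  if (d[1L] < 2L) stop_invalid("need at least 2 subjects")
  if (d[2L] < 2L) stop_invalid("need at least 2 sessions")
  if (anyNA(values)) stop_data("session stack contains missing values")
  if (is.null(subjects)) subjects <- paste0("sub-", seq_len(d[1L]))
  if (is.null(clip_labels)) clip_labels <- seq_len(d[2L])
  structure(
    list(values = values, subjects = as.character(subjects),
         clip_labels = as.integer(clip_labels),
         n_regions = n_regions, sparsity = sparsity),
    class = "session_stack"
  )
}

# Subset a stack to a set of subjects (by position), preserving metadata.
stack_subset <- function(stack, subject_idx) {
  session_stack(stack$values[subject_idx, , , drop = FALSE],
                stack$subjects[subject_idx], stack$clip_labels,
                stack$n_regions, stack$sparsity)
}
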