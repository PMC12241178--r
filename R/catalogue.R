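#' Presentation structure of the HCP 7T movie-watching runs
#'
#' The four movie runs (two per scanning day) each present a sequence of
#' short film excerpts followed by a repeated "validation" clip; durations
#' are in TRs (1 TR = 1000 ms). This is the run-level structure: the
#' validation clip appears once per run, i.e. four times in total.
#'
#' @return A data.frame with columns `day`, `run`, `position`, `name`,
#'   `duration_tr` (18 rows: 14 distinct excerpts + 4 validation showings).
#' @seealso [collapse_runs()] for the 15-category clip catalogue.
#' @export
hcp_movie_runs <- function() {
  data.frame(
    day = c(rep(1L, 9L), rep(2L, 9L)),
    run = c(rep(1L, 5L), rep(2L, 4L), rep(3L, 5L), rep(4L, 4L)),
    position = c(1:5, 1:4, 1:5, 1:4),
    name = c(
      "Two Men", "Welcome To Bridgeville", "Pockets",
      "Inside The Human Body", "Validation clip",
      "Inception", "Social Network", "Ocean's Eleven", "Validation clip",
      "Off The Shelf", "Mrs. Meyer's Clean Day", "1212",
      "Northwest Passage", "Validation clip",
      "Home Alone", "Erin Brockovich", "The Empire Strikes Back",
      "Validation clip"
    ),
    duration_tr = c(
      244L, 222L, 188L, 64L, 83L,
      227L, 259L, 249L, 83L,
      181L, 185L, 204L, 142L, 83L,
      233L, 230L, 255L, 83L
    ),
    stringsAsFactors = FALSE
  )
}

#' Collapse the run structure into the 15 clip categories
#'
#' Distinct excerpts keep one entry each; the validation clip, shown once in
#' every run, is collapsed to a single category (its repeated showings are
#' averaged downstream), yielding exactly 15 clip categories per subject.
#' Labels 1..15 are assigned in presentation order with the validation clip
#' last.
#'
#' @param runs run table as returned by [hcp_movie_runs()].
#' @return A clip catalogue: data.frame with `clip_label` (1..15), `name`,
#'   `duration_tr`.
#' @export
collapse_runs <- function(runs = hcp_movie_runs()) {
  stopifnot(is.data.frame(runs), all(c("name", "duration_tr") %in% names(runs)))
  val <- runs$name == "Validation clip"
  distinct <- runs[!val, c("name", "duration_tr")]
  if (anyDuplicated(distinct$name) > 0L) {
    stop_data("duplicate non-validation clip names in run table")
  }
  vdur <- unique(runs$duration_tr[val])
  if (length(vdur) > 1L) {
    stop_data("validation clip durations differ across runs")
  }
  out <- rbind(distinct,
               data.frame(name = "Validation clip", duration_tr = vdur))
  out <- data.frame(clip_label = seq_len(nrow(out)), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' The 15-clip movie catalogue
#'
#' @param duration_scale multiplier applied to the published TR durations
#'   (e.g. 0.5 for desk-scale simulation); durations are rounded and floored
#'   at 5 TRs.
#' @return data.frame with `clip_label`, `name`, `duration_tr`.
#' @export
clip_catalogue <- function(duration_scale = 1) {
  stopifnot(is.numeric(duration_scale), duration_scale > 0)
  cat <- collapse_runs()
  cat$duration_tr <- pmax(5L, as.integer(round(cat$duration_tr * duration_scale)))
  cat
}

validate_catalogue <- function(catalogue) {
  if (!is.data.frame(catalogue) || nrow(catalogue) == 0L) {
    stop_invalid("clip catalogue must be a non-empty data.frame")
  }
  stopifnot(all(c("clip_label", "duration_tr") %in% names(catalogue)))
  if (!identical(sort(catalogue$clip_label), seq_len(nrow(catalogue)))) {
    stop_invalid("clip labels must be contiguous 1..", nrow(catalogue))
  }
  if (any(catalogue$duration_tr <= 0)) stop_invalid("clip durations must be positive")
  invisible(catalogue)
}
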