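# Internal helpers shared across modules.

#' Derive a reproducible integer seed from a list of tokens
#'
#' Stable string hash (polynomial rolling hash mod a prime < 2^31) so that
#' per-(subject, clip) random streams depend only on the master seed and the
#' identifiers, never on generation order or platform.
#'
#' @param ... tokens (coerced to character) identifying the stream.
#' @return a single non-negative integer < 2^31, usable with [set.seed()].
#' @keywords internal
seed_stream <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- 113
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("moviefc_invalid_argument", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("moviefc_data_error", "error")))
}
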