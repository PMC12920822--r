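# Internal helpers shared across modules.

#' Derive a reproducible child seed
#'
#' Maps a parent seed plus a streamname (e.g. a patient id or stage name) to
#' an integer seed below 2^31, so independent random streams can be spawned
#' from one global seed without reshuffling existing streams when a cohort
#' grows.
#'
#' @param seed integer parent seed.
#' @param key character or integer stream identifier.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(paste0(as.character(key), collapse = ""))
  h <- (seed %% 2147483647)
  for (c in chars) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3D array", call. = FALSE)
  as.integer(d)
}

stopifnot_spacing <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)", call. = FALSE)
  as.numeric(spacing)
}

# condition constructor for patient-exclusion errors
exclusion_error <- function(msg, patient_id = NA_character_) {
  stop(structure(
    class = c("radrot_exclusion", "error", "condition"),
    list(message = sprintf("[%s] %s", patient_id, msg), call = NULL,
         patient_id = patient_id)
  ))
}
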