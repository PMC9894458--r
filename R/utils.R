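#' Admissible recording stage labels
#'
#' The nine time points of the occlusion protocol: `"T-1"` is the baseline
#' acquired 10 min before surgery; `"T1"` to `"T8"` follow every 20 min after
#' venous blockade.
#'
#' @format Character vector of length 9.
#' @export
STAGES <- c("T-1", paste0("T", 1:8))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a parent seed and a stream index, staying well
# below .Machine$integer.max (R seeds are 32-bit).
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 10007L + as.integer(stream) %% 10007L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_stage <- function(stage) {
  if (!all(stage %in% STAGES)) {
    stopf("unknown stage label(s): %s (admissible: %s)",
          paste(setdiff(stage, STAGES), collapse = ", "),
          paste(STAGES, collapse = ", "))
  }
  invisible(stage)
}
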