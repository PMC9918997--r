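# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not clobber the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derived from a parent seed and a set of integer
# tags (participant, subtrial, iteration ...). Kept well below 2^31.
child_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.numeric(seed)
  for (t in tags) x <- (x * 7919 + as.numeric(t) * 104729 + 13) %% 2147483647
  as.integer(x)
}

# key string used throughout for one subtrial
subtrial_key <- function(participant_id, activity, subtrial) {
  sprintf("p%02d_%s_%02d", as.integer(participant_id), activity,
          as.integer(subtrial))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("`%s` must be a finite numeric scalar >= %g", name, min),
         call. = FALSE)
  }
  invisible(x)
}
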