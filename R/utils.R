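# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
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

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  low_ok <- if (strict_lower) x > lower else x >= lower
  high_ok <- if (strict_upper) x < upper else x <= upper
  if (!low_ok || !high_ok) {
    stop(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

#' Ground truth attached to synthetic datasets
#'
#' Every generator in the package attaches a `ground_truth` attribute: the
#' modality tag, the true parameter set used to simulate the data, and the
#' seed, so downstream recovery tests can compare estimates against truth.
#'
#' @param x A generated object.
#' @return A list with elements `modality`, `params`, and `seed`, or `NULL`
#'   if `x` carries no ground truth.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

new_ground_truth <- function(modality, params, seed) {
  structure(list(modality = modality, params = params, seed = seed),
            class = "nicocircuit_ground_truth")
}
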