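#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the current `.Random.seed`, runs `code` under `set.seed(seed)`, and
#' restores the previous generator state, so seeded helpers do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Wrap angles into (-pi, pi]
#' @param theta angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is (-pi, pi]
  out[out == -pi] <- pi
  out
}

vec_norm <- function(v) sqrt(sum(v^2))

row_norms <- function(m) sqrt(rowSums(m^2))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
}
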