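#' Arena configuration
#'
#' Describes the square world both agents move in: its side length, the
#' boundary behaviour (solid reflective walls or a periodic torus), the time
#' discretization, and the per-agent speed caps.
#'
#' @param side_length arena side in meters (default 1, a 1 m x 1 m box).
#' @param boundary `"reflective"` (solid walls) or `"periodic"` (torus:
#'   leaving one side re-enters at the opposite side; all distances then use
#'   the minimal image).
#' @param dt time-step duration in seconds.
#' @param n_steps number of time-steps per trial.
#' @param v_max_target,v_max_agent speed caps in m/s for the target and the
#'   pursuing agent.
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(side_length = 1, boundary = c("reflective", "periodic"),
                         dt = 0.05, n_steps = 100,
                         v_max_target = 0.4, v_max_agent = 0.3) {
  boundary <- match.arg(boundary)
  stopifnot(side_length > 0, dt > 0, n_steps >= 2,
            v_max_target > 0, v_max_agent > 0)
  if (v_max_target * dt >= side_length / 2)
    stop("v_max_target * dt must be < side_length/2 (minimal image unambiguous)")
  structure(list(side_length = side_length, boundary = boundary, dt = dt,
                 n_steps = as.integer(n_steps),
                 v_max_target = v_max_target, v_max_agent = v_max_agent),
            class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %.2f m square, %s boundary, dt=%.3g s, T=%d\n",
              x$side_length, x$boundary, x$dt, x$n_steps))
  invisible(x)
}

#' Resolve a position against the arena boundary
#'
#' Periodic arenas wrap coordinate-wise modulo the side length; reflective
#' arenas clip to the box (the trajectory generators steer away from walls,
#' so clipping is a safety net, not a reflection law).
#'
#' @param p numeric position: a length-2 vector or an n x 2 matrix.
#' @param arena an [arena_config()].
#' @return position(s) inside `[0, side_length]^2`, same shape as `p`.
#' @export
resolve_boundary <- function(p, arena) {
  L <- arena$side_length
  if (arena$boundary == "periodic") {
    p %% L
  } else {
    pmin(pmax(p, 0), L)
  }
}

#' Boundary-aware displacement between positions
#'
#' Returns `p - q` for reflective arenas; for periodic arenas each coordinate
#' uses the minimal image, so the norm of the result is the geodesic distance
#' on the torus. All inter-agent distances in the package go through this.
#'
#' @param p,q length-2 vectors or n x 2 matrices inside the arena.
#' @param arena an [arena_config()].
#' @return displacement(s), same shape as the inputs.
#' @export
displacement <- function(p, q, arena) {
  d <- p - q
  if (arena$boundary == "periodic") {
    L <- arena$side_length
    d <- d - L * round(d / L)
  }
  d
}

#' Geodesic distance between positions
#' @inheritParams displacement
#' @return numeric distance(s) in meters.
#' @export
arena_distance <- function(p, q, arena) {
  d <- displacement(p, q, arena)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Largest possible inter-point distance in the arena
#' @param arena an [arena_config()].
#' @return meters: the box diagonal (reflective) or the torus diameter.
#' @export
arena_diameter <- function(arena) {
  L <- arena$side_length
  if (arena$boundary == "periodic") L / sqrt(2) else L * sqrt(2)
}
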