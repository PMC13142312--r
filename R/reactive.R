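#' Non-predictive (reactive) pursuit baseline
#'
#' The reactive control starts where the RNN-agent started and, at every
#' step, moves straight toward the target's *current* position, using the
#' instantaneous speed of the paired RNN rollout rather than the maximum
#' speed -- a realistic reactive pursuer, not an optimal greedy one. In a
#' periodic arena the chase direction is the minimal-image direction, i.e.
#' through a wall when that is shorter. The step length is clamped to the
#' current distance so the control never overshoots the target.
#'
#' @param trial the trial (shared with the RNN rollout).
#' @param speed_series per-step speeds (m/s), length T; typically
#'   `sqrt(rowSums(rollout$out_velocities^2))` of the paired RNN rollout.
#' @param arena an [arena_config()].
#' @return an object of class `control_rollout` with `positions` (T x 2) and
#'   `end_distance` (m).
#' @export
reactive_rollout <- function(trial, speed_series, arena) {
  T_ <- arena$n_steps
  if (length(speed_series) != T_)
    stop("speed_series length must equal the trial length")
  pos <- matrix(NA_real_, T_, 2)
  p <- trial$rnn_start
  pos[1, ] <- p
  for (t in seq_len(T_ - 1)) {
    d <- displacement(trial$target$positions[t, ], p, arena)
    dist <- vec_norm(d)
    step <- min(speed_series[t] * arena$dt, dist)
    if (dist > 1e-12) p <- resolve_boundary(p + d / dist * step, arena)
    pos[t + 1, ] <- p
  }
  structure(list(
    positions = pos,
    end_distance = arena_distance(pos[T_, ], trial$target$positions[T_, ],
                                  arena)),
    class = "control_rollout")
}
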