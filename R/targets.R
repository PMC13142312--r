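#' Random-trajectory (RT) generator parameters
#'
#' The RT target is a smooth random forager: its heading performs a Gaussian
#' random walk, its speed an autoregressive process around `speed_mean`, and
#' near a reflective wall it turns away and slows down, producing smooth
#' wall-avoiding paths. Every RT trial is unique.
#'
#' @param speed_mean,speed_std stationary mean and sd of the speed process
#'   (m/s); sampled speeds are clipped to `[0, v_max_target]`.
#' @param heading_noise_sd heading diffusion in rad/sqrt(s): per-step heading
#'   increments have sd `heading_noise_sd * sqrt(dt)`.
#' @param wall_avoid_dist distance (m) from a wall at which avoidance engages.
#' @param wall_avoid_turn turning rate (rad/s) applied away from a nearby wall.
#' @param speed_smoothing AR(1) coefficient of the speed process, in `[0, 1)`.
#' @return an object of class `rt_params`.
#' @export
rt_params <- function(speed_mean = 0.2, speed_std = 0.05,
                      heading_noise_sd = 1.5, wall_avoid_dist = 0.1,
                      wall_avoid_turn = 6, speed_smoothing = 0.8) {
  stopifnot(speed_mean >= 0, speed_std >= 0, heading_noise_sd >= 0,
            wall_avoid_dist >= 0, wall_avoid_turn >= 0,
            speed_smoothing >= 0, speed_smoothing < 1)
  structure(list(speed_mean = speed_mean, speed_std = speed_std,
                 heading_noise_sd = heading_noise_sd,
                 wall_avoid_dist = wall_avoid_dist,
                 wall_avoid_turn = wall_avoid_turn,
                 speed_smoothing = speed_smoothing),
            class = "rt_params")
}

#' Characteristic-trajectory (CT) generator parameters
#'
#' CT targets repeat one of four stereotyped routes: from a start location on
#' one wall, straight across the arena to the opposite wall, then along that
#' wall toward its midpoint. Speed and heading jitter make each realization
#' slightly different while preserving the route skeleton.
#'
#' @param start_locations optional 4 x 2 matrix of start positions (meters);
#'   `NULL` uses the default geometry for the arena (wall midpoints offset
#'   0.1 m toward the origin corner; see [ct_default_geometry()]).
#' @param route_waypoints optional list of four waypoint matrices (each row a
#'   waypoint, the first row being the start); `NULL` uses the default routes.
#' @param speed_mean mean target speed along the route (m/s).
#' @param speed_jitter_sd per-step speed jitter sd (m/s).
#' @param heading_jitter_sd per-step heading jitter sd (rad).
#' @return an object of class `ct_params`.
#' @export
ct_params <- function(start_locations = NULL, route_waypoints = NULL,
                      speed_mean = 0.3, speed_jitter_sd = 0.03,
                      heading_jitter_sd = 0.05) {
  stopifnot(speed_mean > 0, speed_jitter_sd >= 0, heading_jitter_sd >= 0)
  if (!is.null(route_waypoints)) {
    stopifnot(is.list(route_waypoints), length(route_waypoints) == 4)
  }
  structure(list(start_locations = start_locations,
                 route_waypoints = route_waypoints,
                 speed_mean = speed_mean, speed_jitter_sd = speed_jitter_sd,
                 heading_jitter_sd = heading_jitter_sd),
            class = "ct_params")
}

#' Default characteristic-route geometry
#'
#' Reflective arenas: route i starts at the midpoint of wall i offset 0.1 m
#' toward the origin corner, crosses straight to the opposite wall, then runs
#' along that wall to its midpoint. Periodic arenas: the route instead exits
#' through the near wall (expressed with unwrapped waypoints beyond the box),
#' reappears at the opposite side, crosses most of the arena, and finishes
#' with a short lateral leg -- the torus analogue of "cross, then along the
#' wall".
#'
#' @param arena an [arena_config()].
#' @param offset lateral offset of the start from the wall midpoint (m).
#' @return list of four waypoint matrices (rows: start, crossing point, end).
#' @export
ct_default_geometry <- function(arena, offset = 0.1) {
  L <- arena$side_length
  m <- L / 2
  if (arena$boundary == "reflective") {
    # walls: 1 bottom, 2 right, 3 top, 4 left; start on wall i, cross to the
    # opposite wall, then along it to its midpoint
    list(
      rbind(c(m - offset, 0), c(m - offset, L), c(m, L)),
      rbind(c(L, m - offset), c(0, m - offset), c(0, m)),
      rbind(c(m - offset, L), c(m - offset, 0), c(m, 0)),
      rbind(c(0, m - offset), c(L, m - offset), c(L, m))
    )
  } else {
    # unwrapped waypoints: leave through the near wall, reappear opposite,
    # travel back across, small lateral leg at the end
    s <- 0.2 * L
    e <- 0.3 * L
    list(
      rbind(c(m - offset, s), c(m - offset, s - 0.9 * L), c(m, s - 0.9 * L)),
      rbind(c(L - s, m - offset), c(L - s + 0.9 * L, m - offset),
            c(L - s + 0.9 * L, m)),
      rbind(c(m - offset, L - s), c(m - offset, L - s + 0.9 * L),
            c(m, L - s + 0.9 * L)),
      rbind(c(s, m - offset), c(s - 0.9 * L, m - offset), c(s - 0.9 * L, m))
    )
  }
}

new_target_trajectory <- function(positions, velocities, kind,
                                  ct_start_index = NA_integer_) {
  structure(list(positions = positions, velocities = velocities,
                 kind = kind, ct_start_index = ct_start_index),
            class = "target_trajectory")
}

#' @export
print.target_trajectory <- function(x, ...) {
  cat(sprintf("<target_trajectory> kind=%s, T=%d\n", x$kind,
              nrow(x$positions)))
  invisible(x)
}

# turn `heading` toward `goal` angle by at most `max_turn` (wrap-aware)
turn_toward <- function(heading, goal, max_turn) {
  d <- wrap_angle(goal - heading)
  heading + sign(d) * min(abs(d), max_turn)
}

#' Sample a random target trajectory (RT)
#'
#' Simulates the smooth random forager for `arena$n_steps` steps: Gaussian
#' heading random walk, AR(1) speed around `speed_mean`, and (reflective
#' arenas only) steering away from walls within `wall_avoid_dist` with a
#' halved step. Positions never leave the arena (periodic positions are
#' wrapped); velocities are the realized per-step displacements / `dt`, so the
#' stored trajectory is self-consistent under [resolve_boundary()].
#'
#' @param arena an [arena_config()].
#' @param params an [rt_params()].
#' @param start optional start position; default uniform in the arena.
#' @return a `target_trajectory`.
#' @export
sample_rt <- function(arena, params, start = NULL) {
  L <- arena$side_length
  dt <- arena$dt
  T_ <- arena$n_steps
  vmax <- arena$v_max_target
  lam <- params$speed_smoothing
  sd_innov <- params$speed_std * sqrt(1 - lam^2)

  pos <- matrix(NA_real_, T_, 2)
  vel <- matrix(NA_real_, T_, 2)
  p <- if (is.null(start)) stats::runif(2, 0, L) else as.numeric(start)
  heading <- stats::runif(1, -pi, pi)
  speed <- min(max(params$speed_mean, 0), vmax)
  pos[1, ] <- p

  reflective <- arena$boundary == "reflective"
  for (t in seq_len(T_)) {
    if (t > 1) {
      heading <- heading + stats::rnorm(1, 0, params$heading_noise_sd * sqrt(dt))
      speed <- params$speed_mean + lam * (speed - params$speed_mean) +
        stats::rnorm(1, 0, sd_innov)
      speed <- min(max(speed, 0), vmax)
    }
    slow <- FALSE
    if (reflective && params$wall_avoid_dist > 0) {
      # inward normals of walls the agent is close to and heading into
      u <- c(cos(heading), sin(heading))
      if (p[1] < params$wall_avoid_dist && u[1] < 0) {
        heading <- turn_toward(heading, 0, params$wall_avoid_turn * dt)
        slow <- TRUE
      } else if (p[1] > L - params$wall_avoid_dist && u[1] > 0) {
        heading <- turn_toward(heading, pi, params$wall_avoid_turn * dt)
        slow <- TRUE
      }
      u <- c(cos(heading), sin(heading))
      if (p[2] < params$wall_avoid_dist && u[2] < 0) {
        heading <- turn_toward(heading, pi / 2, params$wall_avoid_turn * dt)
        slow <- TRUE
      } else if (p[2] > L - params$wall_avoid_dist && u[2] > 0) {
        heading <- turn_toward(heading, -pi / 2, params$wall_avoid_turn * dt)
        slow <- TRUE
      }
    }
    s <- if (slow) speed / 2 else speed
    p_next <- resolve_boundary(p + s * c(cos(heading), sin(heading)) * dt, arena)
    vel[t, ] <- displacement(p_next, p, arena) / dt
    if (t < T_) pos[t + 1, ] <- p_next
    p <- p_next
  }
  new_target_trajectory(pos, vel, "RT")
}

#' Sample a characteristic target trajectory (CT)
#'
#' Steers the target through the stereotyped waypoint route of
#' `start_index`, with per-step heading and speed jitter. The realized path
#' keeps the route skeleton; once the final waypoint is reached the target
#' stays there, so endpoints concentrate at the route end.
#'
#' @param arena an [arena_config()].
#' @param params a [ct_params()].
#' @param start_index route index in `0:3`.
#' @return a `target_trajectory` (with `ct_start_index` set).
#' @export
sample_ct <- function(arena, params, start_index) {
  stopifnot(start_index %in% 0:3)
  dt <- arena$dt
  T_ <- arena$n_steps
  vmax <- arena$v_max_target
  routes <- params$route_waypoints
  if (is.null(routes)) routes <- ct_default_geometry(arena)
  if (!is.null(params$start_locations)) {
    for (i in 1:4) routes[[i]][1, ] <- params$start_locations[i, ]
  }
  wp <- routes[[start_index + 1]]
  if (arena$boundary == "reflective" &&
      (any(wp < 0) || any(wp > arena$side_length)))
    stop("CT waypoints must lie inside a reflective arena")
  route_len <- sum(sqrt(rowSums((wp[-1, , drop = FALSE] -
                                 wp[-nrow(wp), , drop = FALSE])^2)))
  if (route_len > params$speed_mean * T_ * dt)
    stop(sprintf(
      "CT route infeasible: length %.3f m needs %.1f steps at %.3f m/s but T = %d",
      route_len, route_len / (params$speed_mean * dt), params$speed_mean, T_))

  # steer in unwrapped coordinates (periodic waypoints may lie outside the
  # box); wrap only for the stored positions
  pos <- matrix(NA_real_, T_, 2)
  p <- wp[1, ]
  k <- 2L
  pos[1, ] <- resolve_boundary(p, arena)
  unwrapped <- matrix(NA_real_, T_, 2)
  unwrapped[1, ] <- p
  for (t in 2:T_) {
    if (k <= nrow(wp)) {
      d <- wp[k, ] - p
      dist_wp <- vec_norm(d)
      goal <- atan2(d[2], d[1])
      heading <- goal + stats::rnorm(1, 0, params$heading_jitter_sd)
      speed <- params$speed_mean + stats::rnorm(1, 0, params$speed_jitter_sd)
      speed <- min(max(speed, 0), vmax)
      step <- speed * dt
      if (step >= dist_wp) {
        p <- wp[k, ]
        k <- k + 1L
      } else {
        p <- p + step * c(cos(heading), sin(heading))
      }
    }
    if (arena$boundary == "reflective") p <- resolve_boundary(p, arena)
    unwrapped[t, ] <- p
    pos[t, ] <- resolve_boundary(p, arena)
  }
  vel <- rbind(diff(unwrapped) / dt, c(0, 0))
  new_target_trajectory(pos, vel, "CT", as.integer(start_index))
}
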