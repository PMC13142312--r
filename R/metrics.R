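#' Shortcut metric of a pursuit trajectory
#'
#' Average distance between the trajectory and the reference "perfect
#' knowledge" path: the straight segment from the pursuer's start to the
#' target's final location. An agent that knows the target's endpoint can
#' head straight there, so 0 is the lower bound and smaller values mean more
#' shortcut-like (more predictive) pursuit. Distances are point-to-segment
#' (the reference is the bounded segment, not the infinite line). In a
#' periodic arena the segment is the minimal-image chord and every
#' trajectory point is unwrapped into the start's frame before projection.
#'
#' @param traj T x 2 trajectory (m).
#' @param ref_start reference start position (usually the pursuer's start).
#' @param target_end target's final position.
#' @param arena an [arena_config()].
#' @return meters; 0 when the trajectory lies on the segment.
#' @export
shortcut_metric <- function(traj, ref_start, target_end, arena) {
  seg <- displacement(target_end, ref_start, arena)
  rel <- displacement(traj, matrix(ref_start, nrow(traj), 2, byrow = TRUE),
                      arena)
  L2 <- sum(seg^2)
  if (L2 < 1e-24) return(mean(sqrt(rowSums(rel^2))))
  tt <- pmin(pmax((rel %*% seg) / L2, 0), 1)
  proj <- tt %*% t(seg)
  mean(sqrt(rowSums((rel - proj)^2)))
}

#' Normalized deviation between two trajectories
#'
#' Mean pointwise distance between time-aligned trajectories, divided by the
#' path length of `traj_a` (the RNN-agent trajectory). Unitless; 0 for
#' identical paths.
#'
#' @param traj_a,traj_b T x 2 trajectories of equal length (same trial).
#' @param arena optional [arena_config()] for boundary-aware pointwise
#'   distances; `NULL` uses plain Euclidean.
#' @return unitless ratio, or `NA` (flagged undefined) when `traj_a` has zero
#'   path length.
#' @export
normalized_deviation <- function(traj_a, traj_b, arena = NULL) {
  stopifnot(nrow(traj_a) == nrow(traj_b))
  dev <- if (is.null(arena)) sqrt(rowSums((traj_a - traj_b)^2))
         else arena_distance(traj_a, traj_b, arena)
  steps <- if (is.null(arena)) diff(traj_a)
           else displacement(traj_a[-1, , drop = FALSE],
                             traj_a[-nrow(traj_a), , drop = FALSE], arena)
  len <- sum(sqrt(rowSums(steps^2)))
  if (len < 1e-12) return(NA_real_)
  mean(dev) / len
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the empirical
#' CDFs; the p-value comes from the asymptotic Kolmogorov distribution.
#'
#' @param x,y numeric samples.
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' First-order Wasserstein distance between 1-D samples
#'
#' The area between the two empirical CDFs. For equal sample sizes this is
#' the mean absolute difference between the sorted samples.
#'
#' @param x,y numeric samples.
#' @return nonnegative scalar in the units of the samples.
#' @export
wasserstein_1d <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  all_v <- sort(c(x, y))
  if (length(all_v) == 1) return(0)
  cdf_x <- stats::ecdf(x)
  cdf_y <- stats::ecdf(y)
  mids <- all_v[-length(all_v)]
  widths <- diff(all_v)
  sum(abs(cdf_x(mids) - cdf_y(mids)) * widths)
}

#' Detect waiting periods in a distance series
#'
#' A waiting period is a maximal run of at least `min_len` steps over which
#' the per-step change of the distance stays below `eps` -- the ambush-like
#' strategy where the pursuer parks at the location where the target will
#' end up (or reappear) and holds still.
#'
#' @param dist_series per-step distances (m), e.g. agent distance to the
#'   target's final location.
#' @param eps maximum absolute per-step change (m) counted as "not moving".
#' @param min_len minimum run length in steps.
#' @return data.frame with columns `start_step`, `end_step` (1-based,
#'   inclusive, indices into `dist_series`), zero rows if none.
#' @export
detect_waiting <- function(dist_series, eps, min_len) {
  flat <- abs(diff(dist_series)) < eps
  out <- data.frame(start_step = integer(), end_step = integer())
  if (!any(flat)) return(out)
  r <- rle(flat)
  pos <- cumsum(c(1, r$lengths))
  for (i in seq_along(r$values)) {
    # a run of k flat diffs spans k + 1 samples
    if (r$values[i] && r$lengths[i] + 1 >= min_len) {
      out <- rbind(out, data.frame(start_step = pos[i],
                                   end_step = pos[i] + r$lengths[i]))
    }
  }
  out
}

#' Mean distance-to-endpoint curves by trial group
#'
#' For each group (typically CT start index), the mean over trials of the
#' per-step geodesic distance between the pursuer and that trial's target
#' end location. The final value of each curve equals the group's mean end
#' distance.
#'
#' @param rollouts list of rollouts (`rollout_result` or `control_rollout`).
#' @param trials matching list of trials.
#' @param arena an [arena_config()].
#' @param group_by vector of group labels, one per trial (default: the CT
#'   start index of each trial).
#' @return named list of mean distance curves (length-T vectors).
#' @export
distance_to_endpoint_curves <- function(rollouts, trials, arena,
                                        group_by = NULL) {
  stopifnot(length(rollouts) == length(trials))
  if (is.null(group_by))
    group_by <- vapply(trials, function(tr) tr$target$ct_start_index,
                       integer(1))
  groups <- split(seq_along(trials), group_by)
  if (any(lengths(groups) == 0)) stop("empty trial group")
  lapply(groups, function(idx) {
    curves <- vapply(idx, function(i) {
      T_ <- nrow(rollouts[[i]]$positions)
      endp <- matrix(trials[[i]]$target$positions[T_, ], T_, 2, byrow = TRUE)
      arena_distance(rollouts[[i]]$positions, endp, arena)
    }, numeric(arena$n_steps))
    rowMeans(curves)
  })
}
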