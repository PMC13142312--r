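#' Egocentric target coordinates along a rollout
#'
#' Expresses the target's position relative to the pursuing agent: `distance`
#' is the boundary-aware inter-agent distance and `bearing` the angle of the
#' target direction relative to the agent's heading, wrapped to `(-pi, pi]`,
#' counterclockwise, 0 = straight ahead (so +pi/2 is to the agent's left).
#' Samples are invalid until the agent has established a heading (moved
#' faster than the heading threshold at least once). With `shift != 0` the
#' agent state at step t is paired with the target position at t + shift
#' (positive = prospective); overhanging steps are invalid.
#'
#' @param rollout a `rollout_result`.
#' @param trial the trial it came from.
#' @param arena an [arena_config()].
#' @param shift integer time shift in steps.
#' @return data.frame with columns `distance` (m), `bearing` (rad), `valid`.
#' @export
egocentric_coords <- function(rollout, trial, arena, shift = 0L) {
  T_ <- nrow(rollout$positions)
  shift <- as.integer(shift)
  distance <- rep(NA_real_, T_)
  bearing <- rep(NA_real_, T_)
  valid <- rep(FALSE, T_)
  ts <- seq_len(T_)
  ok <- ts + shift >= 1L & ts + shift <= T_
  idx <- ts[ok]
  d <- displacement(trial$target$positions[idx + shift, , drop = FALSE],
                    rollout$positions[idx, , drop = FALSE], arena)
  distance[idx] <- sqrt(rowSums(d^2))
  bearing[idx] <- wrap_angle(atan2(d[, 2], d[, 1]) - rollout$headings[idx])
  valid <- ok & !is.na(rollout$headings)
  data.frame(distance = distance, bearing = bearing, valid = valid)
}

bearing_bin_index <- function(bearing, n_bearing) {
  idx <- floor((bearing + pi) / (2 * pi / n_bearing)) + 1L
  pmin(pmax(idx, 1L), n_bearing)
}

bearing_bin_centers <- function(n_bearing) {
  -pi + (seq_len(n_bearing) - 0.5) * 2 * pi / n_bearing
}

#' Egocentric target ratemap of a unit
#'
#' Mean activation per (bearing, distance) bin over the valid samples; bins
#' with occupancy below `min_occ` are masked (NA in the map).
#'
#' @param unit_activations per-sample activation values.
#' @param ego matching [egocentric_coords()] samples.
#' @param n_bearing,n_dist bin counts.
#' @param min_occ minimum samples per bin.
#' @param max_dist distance covered by the bins; defaults to the largest
#'   observed distance.
#' @return list with `map` (n_bearing x n_dist, NA where masked),
#'   `occupancy` (same shape), `bearing_centers`, `dist_breaks`.
#' @export
ego_ratemap <- function(unit_activations, ego, n_bearing = 36, n_dist = 10,
                        min_occ = 20, max_dist = NULL) {
  keep <- ego$valid
  if (!any(keep)) stop("no valid egocentric samples")
  a <- unit_activations[keep]
  br <- ego$bearing[keep]
  ds <- ego$distance[keep]
  if (is.null(max_dist)) max_dist <- max(ds)
  bi <- bearing_bin_index(br, n_bearing)
  di <- pmin(pmax(floor(ds / max_dist * n_dist) + 1L, 1L), n_dist)
  cell <- (di - 1L) * n_bearing + bi
  occ <- matrix(tabulate(cell, n_bearing * n_dist), n_bearing, n_dist)
  sums <- matrix(0, n_bearing, n_dist)
  s <- rowsum(a, cell)
  sums[as.integer(rownames(s))] <- s
  map <- sums / occ
  map[occ < min_occ] <- NA_real_
  list(map = map, occupancy = occ,
       bearing_centers = bearing_bin_centers(n_bearing),
       dist_breaks = seq(0, max_dist, length.out = n_dist + 1))
}

# bearing tuning curves for a matrix of units: n_bearing x N mean activation
# (NA for unoccupied bins), plus occupancy counts
bearing_tuning <- function(activations, bin_idx, n_bearing) {
  counts <- tabulate(bin_idx, n_bearing)
  sums <- matrix(0, n_bearing, ncol(activations))
  s <- rowsum(activations, bin_idx)
  sums[as.integer(rownames(s)), ] <- s
  w <- sums / counts
  w[counts == 0, ] <- NA_real_
  list(w = w, counts = counts)
}

# MRL of each column of a tuning-curve matrix (n_bearing x N):
# min-subtract per unit (activations are signed), then circular resultant
mrl_from_tuning <- function(w, centers) {
  occ <- !is.na(w[, 1])
  if (sum(occ) == 1) {
    out <- rep(1, ncol(w))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  wo <- w[occ, , drop = FALSE]
  wo <- sweep(wo, 2, apply(wo, 2, min), "-")
  den <- colSums(wo)
  num <- sqrt(colSums(wo * cos(centers[occ]))^2 +
              colSums(wo * sin(centers[occ]))^2)
  ifelse(den > 1e-12, num / den, 0)
}

#' Mean resultant length of a unit's egocentric bearing tuning
#'
#' Builds the occupancy-normalized bearing tuning curve (distance
#' marginalized), shifts it by its minimum so the weights are nonnegative
#' (unit activations are signed), and returns the circular concentration
#' `|sum_j w_j exp(i theta_j)| / sum_j w_j` over the occupied bin centers:
#' 0 for flat tuning, 1 for a single-bin delta. Independent of the
#' inter-agent distance by construction.
#'
#' @param unit_activations per-sample activations (vector, or T x N matrix
#'   for many units at once).
#' @param ego matching [egocentric_coords()] samples.
#' @param n_bearing number of bearing bins.
#' @return MRL in `[0, 1]` (vector of length N for matrix input). A single
#'   occupied bin yields 1 with attribute `degenerate = TRUE`.
#' @export
mrl <- function(unit_activations, ego, n_bearing = 36) {
  A <- as.matrix(unit_activations)
  keep <- ego$valid
  if (!any(keep)) stop("no valid egocentric samples")
  bi <- bearing_bin_index(ego$bearing[keep], n_bearing)
  tun <- bearing_tuning(A[keep, , drop = FALSE], bi, n_bearing)
  out <- mrl_from_tuning(tun$w, bearing_bin_centers(n_bearing))
  deg <- attr(out, "degenerate")
  if (is.vector(unit_activations)) out <- out[1]
  if (isTRUE(deg)) attr(out, "degenerate") <- TRUE
  out
}

#' Shuffle null distribution of the MRL
#'
#' Permutes the activation time series against the fixed egocentric
#' coordinates and recomputes the MRL. One permutation per shuffle round is
#' applied to all units jointly (per-unit null percentiles are unaffected).
#'
#' @inheritParams mrl
#' @param n_shuffles number of permutations.
#' @param seed integer seed.
#' @return n_shuffles x N matrix of null MRLs (or a vector for one unit).
#' @export
shuffle_mrl <- function(unit_activations, ego, n_bearing = 36,
                        n_shuffles = 200, seed = 1) {
  A <- as.matrix(unit_activations)
  keep <- ego$valid
  bi <- bearing_bin_index(ego$bearing[keep], n_bearing)
  Ak <- A[keep, , drop = FALSE]
  centers <- bearing_bin_centers(n_bearing)
  with_seed(seed, {
    out <- matrix(NA_real_, n_shuffles, ncol(Ak))
    for (s in seq_len(n_shuffles)) {
      perm <- sample.int(nrow(Ak))
      tun <- bearing_tuning(Ak[perm, , drop = FALSE], bi, n_bearing)
      out[s, ] <- mrl_from_tuning(tun$w, centers)
    }
    if (ncol(out) == 1) out[, 1] else out
  })
}

#' Classify egocentric target units (ETUs)
#'
#' A unit is an ETU when its full-data MRL exceeds the 99th percentile of
#' its own shuffle null *and* its MRL in each of two disjoint halves of the
#' trials exceeds the corresponding split null's 99th percentile (the
#' split-consistency criterion). Returns per-unit statistics and the
#' population ETU fraction.
#'
#' @param activations T_total x N activation matrix, rows stacked over
#'   trials.
#' @param ego stacked [egocentric_coords()] rows matching `activations`.
#' @param trial_ids integer label of the trial of each row; the split is
#'   first half vs second half of the unique ids.
#' @param n_bearing bearing bins.
#' @param n_shuffles permutations per null.
#' @param seed integer seed.
#' @param percentile null percentile for the threshold.
#' @return list with `units` (data.frame: unit, mrl, threshold, mrl_split1,
#'   mrl_split2, is_etu), `fraction`, and `null` (pooled full-data null
#'   matrix, for population histograms).
#' @export
classify_etus <- function(activations, ego, trial_ids, n_bearing = 36,
                          n_shuffles = 200, seed = 1, percentile = 0.99) {
  stopifnot(nrow(activations) == nrow(ego),
            length(trial_ids) == nrow(ego))
  uid <- unique(trial_ids)
  h1 <- trial_ids %in% uid[seq_len(floor(length(uid) / 2))]
  if (!any(h1) || all(h1)) stop("both trial halves must be non-empty")
  eval_half <- function(rows, seed_off) {
    m <- mrl(activations[rows, , drop = FALSE], ego[rows, ], n_bearing)
    null <- shuffle_mrl(activations[rows, , drop = FALSE], ego[rows, ],
                        n_bearing, n_shuffles, seed + seed_off)
    thr <- apply(as.matrix(null), 2, stats::quantile, probs = percentile,
                 names = FALSE)
    list(mrl = as.numeric(m), thr = thr, null = null)
  }
  full <- eval_half(seq_len(nrow(activations)), 0L)
  s1 <- eval_half(which(h1), 1L)
  s2 <- eval_half(which(!h1), 2L)
  is_etu <- full$mrl > full$thr & s1$mrl > s1$thr & s2$mrl > s2$thr
  units <- data.frame(unit = seq_len(ncol(activations)), mrl = full$mrl,
                      threshold = full$thr, mrl_split1 = s1$mrl,
                      mrl_split2 = s2$mrl, is_etu = is_etu)
  list(units = units, fraction = mean(is_etu), null = full$null)
}

#' MRL and ETU fraction across time shifts
#'
#' Re-pairs unit activations at step t with the target's egocentric
#' coordinates at t + shift (positive = prospective, negative =
#' retrospective) and recomputes the population mean MRL and the fraction of
#' units above their shuffle threshold at each shift. Retrospective shifts of
#' a predictive code should degrade tuning more than prospective ones.
#'
#' @param rollouts list of `rollout_result`s (their `activations` are used).
#' @param trials matching trials.
#' @param arena an [arena_config()].
#' @param shifts integer vector of time shifts (steps).
#' @param n_bearing bearing bins.
#' @param n_shuffles permutations for the per-shift threshold (threshold-only
#'   classification; no trial split at the profile level).
#' @param seed integer seed.
#' @return data.frame with columns `shift`, `mean_mrl`, `etu_fraction`.
#' @export
time_shift_profile <- function(rollouts, trials, arena, shifts,
                               n_bearing = 36, n_shuffles = 100, seed = 1) {
  T_ <- arena$n_steps
  stopifnot(all(abs(shifts) < T_ / 2))
  out <- data.frame()
  for (s in shifts) {
    acts <- list()
    egos <- list()
    for (i in seq_along(rollouts)) {
      ego <- egocentric_coords(rollouts[[i]], trials[[i]], arena, shift = s)
      acts[[i]] <- rollouts[[i]]$activations
      egos[[i]] <- ego
    }
    A <- do.call(rbind, acts)
    E <- do.call(rbind, egos)
    m <- mrl(A, E, n_bearing)
    null <- shuffle_mrl(A, E, n_bearing, n_shuffles, seed)
    thr <- apply(as.matrix(null), 2, stats::quantile, probs = 0.99,
                 names = FALSE)
    out <- rbind(out, data.frame(shift = s, mean_mrl = mean(m),
                                 etu_fraction = mean(m > thr)))
  }
  out
}

#' Number of principal components explaining 95% of variance
#'
#' @param X samples x dims matrix (mean-centered internally).
#' @param threshold cumulative variance fraction.
#' @return smallest integer k whose leading eigenvalues reach the threshold;
#'   0 with attribute `zero_variance = TRUE` for constant data.
#' @export
pca95 <- function(X, threshold = 0.95) {
  stopifnot(nrow(X) >= 2)
  Xc <- sweep(X, 2, colMeans(X))
  lam <- svd(Xc, nu = 0, nv = 0)$d^2
  tot <- sum(lam)
  if (tot < 1e-24) {
    out <- 0L
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  as.integer(which(cumsum(lam) / tot >= threshold)[1])
}

#' Participation ratio of the activation covariance
#'
#' `(sum lambda_i)^2 / sum lambda_i^2` over the covariance eigenvalues: a
#' soft count of effective dimensions, d for d equal eigenvalues and 1 for a
#' single nonzero one.
#'
#' @param X samples x dims matrix.
#' @return float in `[1, dims]`; `NA` with attribute `zero_variance` for
#'   constant data.
#' @export
participation_ratio <- function(X) {
  stopifnot(nrow(X) >= 2)
  Xc <- sweep(X, 2, colMeans(X))
  lam <- svd(Xc, nu = 0, nv = 0)$d^2
  if (sum(lam) < 1e-24) {
    out <- NA_real_
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  sum(lam)^2 / sum(lam^2)
}

#' Latent variables of a low-rank rollout
#'
#' The r-dimensional projections `t(Q) %*% tanh(h) / N` that drive the
#' recurrent dynamics of a rank-r network; their dimensionality is what the
#' rank constrains.
#'
#' @param params an `rnn_params`.
#' @param activations T x N activation matrix from a rollout.
#' @return T x rank matrix.
#' @export
rnn_latents <- function(params, activations) {
  activations %*% params$Q / params$N
}

# closed-form ridge via one SVD, reusable across penalties: returns
# function(newX, lambda) -> predictions
ridge_fit <- function(X, Y, lambda = NULL) {
  mx <- colMeans(X)
  my <- colMeans(Y)
  sv <- svd(sweep(X, 2, mx))
  UtY <- t(sv$u) %*% sweep(Y, 2, my)
  pred <- function(newX, lam) {
    W <- sv$v %*% ((sv$d / (sv$d^2 + lam)) * UtY)
    sweep(sweep(newX, 2, mx) %*% W, 2, my, "+")
  }
  if (is.null(lambda)) pred else function(newX) pred(newX, lambda)
}

#' Linearly decode a task feature from population activations
#'
#' Ridge regression from activations at step t to the feature at t + shift,
#' cross-validated by trial (never by time sample, so no within-trial
#' leakage). The ridge penalty is chosen by inner cross-validation on the
#' training trials. Reports the median absolute error on held-out trials
#' (Euclidean per sample for 2-D features), the pooled explained variance,
#' and a shuffle baseline in which whole-trial feature blocks are permuted
#' across trials before running the same pipeline.
#'
#' @param activations T_total x N matrix, rows stacked over trials.
#' @param feature T_total x k matrix (k = 1 or 2) aligned with the rows.
#' @param trial_ids trial label per row; trials must have equal lengths for
#'   the shuffle baseline.
#' @param shift time shift in steps (positive = decode the future).
#' @param lambdas candidate ridge penalties.
#' @param cv_folds number of trial-level folds.
#' @param seed integer seed (fold assignment, shuffle, inner CV).
#' @param shuffle_baseline compute the trial-permuted baseline.
#' @return list with `error` (median absolute error), `r2`, `shuffle_error`
#'   (or NA), `shift`, `n_samples`. `r2` is NA (flagged) for a constant
#'   feature.
#' @export
linear_decode <- function(activations, feature, trial_ids, shift = 0L,
                          lambdas = 10^seq(-4, 2), cv_folds = 5, seed = 1,
                          shuffle_baseline = TRUE) {
  feature <- as.matrix(feature)
  stopifnot(nrow(activations) == nrow(feature),
            length(trial_ids) == nrow(feature))
  uid <- unique(trial_ids)
  if (length(uid) < cv_folds) stop("fewer trials than folds")
  shift <- as.integer(shift)

  # within-trial shift pairing
  rows_x <- integer(0)
  rows_y <- integer(0)
  for (id in uid) {
    rows <- which(trial_ids == id)
    Tl <- length(rows)
    ts <- seq_len(Tl)
    ok <- ts + shift >= 1L & ts + shift <= Tl
    rows_x <- c(rows_x, rows[ts[ok]])
    rows_y <- c(rows_y, rows[ts[ok] + shift])
  }
  X <- activations[rows_x, , drop = FALSE]
  Y <- feature[rows_y, , drop = FALSE]
  ids <- trial_ids[rows_x]

  run_cv <- function(X, Y, ids, fold_of) {
    err <- rep(NA_real_, nrow(X))
    pred <- matrix(NA_real_, nrow(X), ncol(Y))
    for (f in sort(unique(fold_of))) {
      test <- ids %in% uid[fold_of == f]
      train_ids <- uid[fold_of != f]
      train <- ids %in% train_ids
      # inner CV over lambda on the training trials (one SVD per inner split)
      inner_fold <- rep(seq_len(3), length.out = length(train_ids))
      inner_err <- numeric(length(lambdas))
      for (g in 1:3) {
        tr <- ids %in% train_ids[inner_fold != g]
        te <- ids %in% train_ids[inner_fold == g]
        fit <- ridge_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
        for (j in seq_along(lambdas)) {
          inner_err[j] <- inner_err[j] +
            sum((fit(X[te, , drop = FALSE], lambdas[j]) -
                 Y[te, , drop = FALSE])^2)
        }
      }
      lam <- lambdas[which.min(inner_err)]
      fit <- ridge_fit(X[train, , drop = FALSE], Y[train, , drop = FALSE])
      pred[test, ] <- fit(X[test, , drop = FALSE], lam)
    }
    pred
  }

  with_seed(seed, {
    fold_of <- sample(rep(seq_len(cv_folds), length.out = length(uid)))
    pred <- run_cv(X, Y, ids, fold_of)
    resid <- pred - Y
    err <- stats::median(sqrt(rowSums(resid^2)))
    sstot <- sum(sweep(Y, 2, colMeans(Y))^2)
    r2 <- if (sstot < 1e-24) NA_real_ else 1 - sum(resid^2) / sstot
    shuffle_error <- NA_real_
    if (shuffle_baseline) {
      perm <- sample(length(uid))
      Ys <- Y
      for (i in seq_along(uid)) {
        from <- which(ids == uid[perm[i]])
        to <- which(ids == uid[i])
        stopifnot(length(from) == length(to))
        Ys[to, ] <- Y[from, , drop = FALSE]
      }
      pred_s <- run_cv(X, Ys, ids, fold_of)
      shuffle_error <- stats::median(sqrt(rowSums((pred_s - Ys)^2)))
    }
    out <- list(error = err, r2 = r2, shuffle_error = shuffle_error,
                shift = shift, n_samples = nrow(X))
    if (is.na(r2)) attr(out, "constant_feature") <- TRUE
    out
  })
}
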