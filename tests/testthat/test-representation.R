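# helper: build ego samples directly from bearings/distances
ego_df <- function(bearing, distance = NULL, valid = NULL) {
  n <- length(bearing)
  data.frame(distance = if (is.null(distance)) rep(0.3, n) else distance,
             bearing = bearing,
             valid = if (is.null(valid)) rep(TRUE, n) else valid)
}

test_that("egocentric coordinates follow the left-positive convention", {
  arena <- arena_config()
  T_ <- 3
  # agent at center heading east
  agent <- fake_rollout(matrix(rep(c(0.5, 0.5), each = T_), T_, 2),
                        rep(0, T_))
  east <- fixed_trial(matrix(rep(c(0.8, 0.5), each = T_), T_, 2),
                      c(0.5, 0.5), arena)
  ego <- egocentric_coords(agent, east, arena)
  expect_equal(ego$bearing, rep(0, T_))
  expect_equal(ego$distance, rep(0.3, T_))

  north <- fixed_trial(matrix(rep(c(0.5, 0.8), each = T_), T_, 2),
                       c(0.5, 0.5), arena)
  ego_n <- egocentric_coords(agent, north, arena)
  expect_equal(ego_n$bearing, rep(pi / 2, T_))

  # heading north, target east -> bearing -pi/2 (to the right)
  agent_n <- fake_rollout(matrix(rep(c(0.5, 0.5), each = T_), T_, 2),
                          rep(pi / 2, T_))
  ego_r <- egocentric_coords(agent_n, east, arena)
  expect_equal(ego_r$bearing, rep(-pi / 2, T_))

  # undefined heading -> invalid samples
  agent_na <- fake_rollout(matrix(rep(c(0.5, 0.5), each = T_), T_, 2),
                           c(NA, NA, 0))
  expect_equal(egocentric_coords(agent_na, east, arena)$valid,
               c(FALSE, FALSE, TRUE))
})

test_that("periodic egocentric coordinates look through the wall", {
  arena <- arena_config(boundary = "periodic")
  T_ <- 2
  agent <- fake_rollout(matrix(rep(c(0.95, 0.5), each = T_), T_, 2),
                        rep(0, T_))
  tr <- fixed_trial(matrix(rep(c(0.05, 0.5), each = T_), T_, 2),
                    c(0.95, 0.5), arena)
  ego <- egocentric_coords(agent, tr, arena)
  expect_equal(ego$distance, rep(0.1, T_), tolerance = 1e-12)
  expect_equal(ego$bearing, rep(0, T_), tolerance = 1e-12)
})

test_that("ratemaps average activations per egocentric bin", {
  set.seed(1)
  n <- 5000
  ego <- ego_df(runif(n, -pi, pi), runif(n, 0, 0.5))
  rm1 <- ego_ratemap(rep(2.5, n), ego, n_bearing = 8, n_dist = 4,
                     min_occ = 10)
  expect_true(all(rm1$map[!is.na(rm1$map)] == 2.5))
  expect_equal(sum(rm1$occupancy), n)

  # activation 1 only in one bearing column
  bi <- pursuitnet:::bearing_bin_index(ego$bearing, 8)
  act <- as.numeric(bi == 3)
  rm2 <- ego_ratemap(act, ego, n_bearing = 8, n_dist = 4, min_occ = 10)
  expect_true(all(rm2$map[3, ] > 0, na.rm = TRUE))
  expect_true(all(rm2$map[-3, ] == 0, na.rm = TRUE))

  expect_error(ego_ratemap(act, ego_df(rep(0, 3), valid = rep(FALSE, 3)),
                           8, 4, 1), "valid")
})

test_that("MRL hits delta, uniform and cosine closed forms", {
  n_b <- 72
  centers <- pursuitnet:::bearing_bin_centers(n_b)
  # many samples exactly at bin centers
  bearing <- rep(centers, each = 50)

  delta_act <- as.numeric(rep(seq_len(n_b), each = 50) == 10)
  expect_equal(mrl(delta_act, ego_df(bearing), n_b), 1, tolerance = 1e-12)

  expect_equal(mrl(rep(1, length(bearing)), ego_df(bearing), n_b), 0,
               tolerance = 1e-12)

  cos_act <- 1 + cos(rep(centers, each = 50))
  expect_equal(mrl(cos_act, ego_df(bearing), n_b), 0.5, tolerance = 1e-3)

  # invariance: constant shift and positive rescaling
  set.seed(2)
  act <- rnorm(length(bearing))
  base <- mrl(act, ego_df(bearing), n_b)
  expect_equal(mrl(act + 5, ego_df(bearing), n_b), base, tolerance = 1e-10)
  expect_equal(mrl(act * 3.7, ego_df(bearing), n_b), base, tolerance = 1e-10)
  expect_gte(base, 0); expect_lte(base, 1)
})

test_that("MRL with a single occupied bin is flagged degenerate", {
  ego <- ego_df(rep(0.1, 100))
  m <- mrl(rnorm(100), ego, 36)
  expect_equal(as.numeric(m), 1)
  expect_true(isTRUE(attr(m, "degenerate")))
})

test_that("shuffled MRL nulls behave as expected", {
  set.seed(3)
  n <- 10000
  ego <- ego_df(runif(n, -pi, pi))
  # constant unit: flat tuning whatever the permutation
  null_c <- shuffle_mrl(rep(1, n), ego, 36, n_shuffles = 20, seed = 4)
  expect_true(all(null_c == 0))
  # iid gaussian unit: small circular concentration at T = 1e4
  null_g <- shuffle_mrl(rnorm(n), ego, 36, n_shuffles = 100, seed = 5)
  expect_lt(quantile(null_g, 0.99), 0.2)
})

test_that("ETU classification recovers planted tuned units", {
  set.seed(6)
  n <- 10000
  n_tuned <- 30; n_noise <- 70
  bearing <- runif(n, -pi, pi)
  ego <- ego_df(bearing)
  trial_ids <- rep(seq_len(50), each = n / 50)
  prefs <- runif(n_tuned, -pi, pi)
  A <- matrix(NA_real_, n, n_tuned + n_noise)
  for (i in seq_len(n_tuned))
    A[, i] <- exp(2 * cos(bearing - prefs[i])) / exp(2) +
      rnorm(n, sd = 0.3)
  for (i in seq_len(n_noise)) A[, n_tuned + i] <- rnorm(n)
  res <- classify_etus(A, ego, trial_ids, n_bearing = 36, n_shuffles = 100,
                       seed = 7)
  expect_gte(sum(res$units$is_etu[1:n_tuned]), 27)
  expect_lte(sum(res$units$is_etu[n_tuned + seq_len(n_noise)]), 3)
  expect_equal(res$fraction, mean(res$units$is_etu))
})

test_that("false-positive rate on pure noise stays at the nominal level", {
  # 20 seeds x 40 noise units; threshold at the 99th percentile with split
  # consistency should keep FPs rare
  fp <- 0; total <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 2000
    ego <- ego_df(runif(n, -pi, pi))
    ids <- rep(1:20, each = n / 20)
    A <- matrix(rnorm(n * 40), n, 40)
    res <- classify_etus(A, ego, ids, n_bearing = 36, n_shuffles = 100,
                         seed = s)
    fp <- fp + sum(res$units$is_etu); total <- total + 40
  }
  expect_lte(fp / total, 0.02)
})

test_that("nonstationary tuning fails the split-consistency criterion", {
  set.seed(8)
  n <- 8000
  bearing <- runif(n, -pi, pi)
  ego <- ego_df(bearing)
  ids <- rep(1:40, each = n / 40)
  half1 <- ids <= 20
  act <- ifelse(half1, exp(2 * cos(bearing)) / exp(2), rnorm(n) * 0.1)
  res <- classify_etus(matrix(act, ncol = 1), ego, ids, n_bearing = 36,
                       n_shuffles = 100, seed = 9)
  expect_false(res$units$is_etu[1])
})

test_that("time-shift profiles peak at the planted lag", {
  # a teleporting target makes successive bearings independent, so only the
  # planted lag carries tuning; smooth trajectories would smear it
  arena <- arena_config(n_steps = 400)
  set.seed(10)
  lag <- 5L
  T_ <- arena$n_steps
  rollouts <- list(); trials <- list()
  for (k in 1:6) {
    target <- matrix(runif(2 * T_, 0.05, 0.95), T_, 2)
    tr <- fixed_trial(target, c(0.5, 0.5), arena)
    ro <- fake_rollout(matrix(rep(c(0.5, 0.5), each = T_), T_, 2),
                       rep(0, T_))   # parked agent, fixed heading
    ego_fw <- egocentric_coords(ro, tr, arena, shift = lag)
    act <- cos(ego_fw$bearing); act[is.na(act)] <- 0
    ro$activations <- cbind(act + rnorm(T_, sd = 0.1), rnorm(T_))
    rollouts[[k]] <- ro; trials[[k]] <- tr
  }
  prof <- time_shift_profile(rollouts, trials, arena,
                             shifts = c(-5, 0, 5, 10),
                             n_shuffles = 50, seed = 11)
  expect_equal(prof$shift[which.max(prof$mean_mrl)], 5)
  # the planted shift clearly dominates the neighbors
  expect_gt(prof$mean_mrl[prof$shift == 5],
            max(prof$mean_mrl[prof$shift != 5]) + 0.05)

  # a white-noise population has a flat profile
  noise_rolls <- lapply(rollouts, function(r) {
    r$activations <- cbind(rnorm(T_), rnorm(T_)); r })
  prof_n <- time_shift_profile(noise_rolls, trials, arena,
                               shifts = c(-5, 0, 5, 10),
                               n_shuffles = 50, seed = 12)
  expect_lt(diff(range(prof_n$mean_mrl)), 0.15)

  # shift 0 reproduces the unshifted population MRL
  A <- do.call(rbind, lapply(rollouts, function(r) r$activations))
  E <- do.call(rbind, lapply(seq_along(rollouts), function(i)
    egocentric_coords(rollouts[[i]], trials[[i]], arena, shift = 0)))
  expect_equal(prof$mean_mrl[prof$shift == 0], mean(mrl(A, E, 36)),
               tolerance = 1e-12)
})

test_that("dimensionality estimates match eigendecomposition oracles", {
  set.seed(12)
  X <- matrix(rnorm(20 * 8), 20, 8)
  lam <- eigen(stats::cov(X), symmetric = TRUE)$values
  # oracle pca95
  k_oracle <- which(cumsum(lam) / sum(lam) >= 0.95)[1]
  expect_equal(pca95(X), as.integer(k_oracle))
  # oracle participation ratio (scaling of lam cancels)
  expect_equal(participation_ratio(X), sum(lam)^2 / sum(lam^2),
               tolerance = 1e-10)
})

test_that("dimensionality handles exact low-rank and constructed spectra", {
  set.seed(13)
  basis <- qr.Q(qr(matrix(rnorm(50 * 3), 50, 3)))
  X <- matrix(rnorm(200 * 3), 200, 3) %*% t(basis)   # exact 3-dim in 50 dims
  expect_equal(pca95(X), 3L)
  expect_equal(pca95(cbind(X, X[, 1])), 3L)  # duplicate coordinate

  # data with exact covariance spectrum via whiten-then-scale
  spectrum_data <- function(lams) {
    d <- length(lams)
    Z <- matrix(rnorm(300 * d), 300, d)
    Zc <- sweep(Z, 2, colMeans(Z))
    W <- svd(Zc)
    U <- W$u * sqrt(300 - 1)
    U %*% diag(sqrt(lams), d)
  }
  X2 <- spectrum_data(c(0.9, 0.06, 0.04))
  expect_equal(pca95(X2), 2L)
  X3 <- spectrum_data(c(3, 1))
  expect_equal(participation_ratio(X3), 1.6, tolerance = 1e-10)
  X4 <- spectrum_data(rep(2, 5))
  expect_equal(participation_ratio(X4), 5, tolerance = 1e-10)
  X5 <- spectrum_data(c(1, 1e-28))
  expect_equal(participation_ratio(X5), 1, tolerance = 1e-6)

  const <- matrix(1, 10, 4)
  expect_true(isTRUE(attr(pca95(const), "zero_variance")))
  expect_true(is.na(participation_ratio(const)))
})

test_that("the linear decoder recovers linearly embedded features", {
  set.seed(14)
  n_trials <- 20; T_ <- 40; N <- 30
  A <- matrix(rnorm(n_trials * T_ * N), ncol = N)
  ids <- rep(seq_len(n_trials), each = T_)
  W <- matrix(rnorm(N * 2), N, 2)
  Y <- A %*% W + rnorm(nrow(A), sd = 1e-3)
  dec <- linear_decode(A, Y, ids, shift = 0, seed = 15)
  expect_lt(dec$error, 1e-2)
  expect_gt(dec$r2, 0.999)
  expect_gt(dec$shuffle_error, 50 * dec$error)

  # constant feature: zero error, undefined r2
  dec_c <- linear_decode(A, matrix(1, nrow(A), 1), ids, shift = 0, seed = 16,
                         shuffle_baseline = FALSE)
  expect_lt(dec_c$error, 1e-10)
  expect_true(is.na(dec_c$r2))
})

test_that("trial-level cross-validation does not leak across trials", {
  # each trial has its own disjoint feature offset; without leakage the
  # held-out error must be on the order of the offset spread
  set.seed(17)
  n_trials <- 12; T_ <- 30; N <- 20
  A <- matrix(rnorm(n_trials * T_ * N), ncol = N)
  ids <- rep(seq_len(n_trials), each = T_)
  offsets <- seq_len(n_trials) * 10
  Y <- matrix(offsets[ids], ncol = 1)
  dec <- linear_decode(A, Y, ids, shift = 0, seed = 18,
                       shuffle_baseline = FALSE)
  expect_gt(dec$error, 1)  # would be ~0 if time samples leaked across folds

  # decoding a trial-shuffled feature is no better than the shuffle baseline
  set.seed(19)
  Yr <- matrix(rnorm(nrow(A)), ncol = 1)
  dec_r <- linear_decode(A, Yr, ids, shift = 0, seed = 20)
  expect_lt(abs(dec_r$error - dec_r$shuffle_error) / dec_r$shuffle_error, 0.5)
})

test_that("decoder respects within-trial time shifts", {
  set.seed(21)
  n_trials <- 10; T_ <- 30; N <- 15
  ids <- rep(seq_len(n_trials), each = T_)
  A <- matrix(rnorm(n_trials * T_ * N), ncol = N)
  W <- matrix(rnorm(N), N, 1)
  # feature at t equals readout of activations at t - 3 within each trial
  Y <- matrix(0, nrow(A), 1)
  for (id in seq_len(n_trials)) {
    rows <- which(ids == id)
    z <- A[rows, ] %*% W
    Y[rows[4:T_], 1] <- z[1:(T_ - 3)]
  }
  dec <- linear_decode(A, Y, ids, shift = 3, seed = 22,
                       shuffle_baseline = FALSE)
  expect_lt(dec$error, 1e-4)   # exact up to the smallest ridge penalty
})
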