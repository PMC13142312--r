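test_that("boundary resolution wraps periodically and clips reflectively", {
  per <- arena_config(boundary = "periodic")
  ref <- arena_config(boundary = "reflective")
  expect_equal(resolve_boundary(c(1.05, 0.5), per), c(0.05, 0.5))
  expect_equal(resolve_boundary(c(-0.1, 0.5), per), c(0.9, 0.5))
  expect_equal(resolve_boundary(c(0.5, 0.5), ref), c(0.5, 0.5))
  expect_equal(resolve_boundary(c(1.3, -0.2), ref), c(1, 0))
})

test_that("displacement uses the minimal image and behaves like a metric", {
  ref <- arena_config(boundary = "reflective")
  per <- arena_config(boundary = "periodic")
  expect_equal(displacement(c(0.2, 0.2), c(0.1, 0.2), ref), c(0.1, 0))
  expect_equal(displacement(c(0.95, 0.5), c(0.05, 0.5), per), c(-0.1, 0))
  expect_equal(arena_distance(c(0.95, 0.5), c(0.05, 0.5), per), 0.1)

  set.seed(42)
  pts <- matrix(runif(300), ncol = 2)
  for (i in 1:50) {
    idx <- sample(nrow(pts), 3)
    p <- pts[idx[1], ]; q <- pts[idx[2], ]; r <- pts[idx[3], ]
    d <- displacement(p, q, per)
    expect_true(all(abs(d) <= per$side_length / 2 + 1e-12))
    expect_equal(d, -displacement(q, p, per))
    expect_lte(arena_distance(p, r, per),
               arena_distance(p, q, per) + arena_distance(q, r, per) + 1e-12)
  }
})

test_that("zero-noise RT is a straight constant-speed path", {
  arena <- arena_config(n_steps = 20)
  params <- rt_params(speed_mean = 0.2, speed_std = 0, heading_noise_sd = 0,
                      wall_avoid_dist = 0)
  set.seed(1)
  tr <- sample_rt(arena, params, start = c(0.5, 0.5))
  steps <- diff(tr$positions)
  sp <- sqrt(rowSums(steps^2)) / arena$dt
  expect_equal(sp, rep(0.2, nrow(steps)), tolerance = 1e-12)
  dirs <- atan2(steps[, 2], steps[, 1])
  expect_equal(diff(dirs), rep(0, nrow(steps) - 1), tolerance = 1e-12)
})

test_that("RT positions stay inside the arena over long runs", {
  arena <- arena_config(n_steps = 10000)
  set.seed(7)
  tr <- sample_rt(arena, rt_params())
  expect_true(all(tr$positions >= 0 & tr$positions <= 1))
  sp <- sqrt(rowSums(tr$velocities^2))
  expect_true(all(sp <= arena$v_max_target + 1e-12))
})

test_that("open-field heading increments match the stated diffusion", {
  # huge arena so no wall events; speed noise off so movement directions
  # are exactly the heading sequence
  arena <- arena_config(side_length = 1000, n_steps = 1e5, v_max_target = 0.4)
  params <- rt_params(speed_mean = 0.2, speed_std = 0, heading_noise_sd = 1.5)
  set.seed(3)
  tr <- sample_rt(arena, params, start = c(500, 500))
  dirs <- atan2(tr$velocities[, 2], tr$velocities[, 1])
  inc <- wrap_angle(diff(dirs))
  expect_equal(sd(inc), params$heading_noise_sd * sqrt(arena$dt),
               tolerance = 0.05)
})

test_that("zero-jitter CT is piecewise linear through the waypoints", {
  arena <- arena_config()
  params <- ct_params(speed_jitter_sd = 0, heading_jitter_sd = 0)
  set.seed(1)
  tr <- sample_ct(arena, params, 0)
  wp <- ct_default_geometry(arena)[[1]]
  expect_equal(tr$positions[1, ], wp[1, ])
  expect_equal(tr$positions[nrow(tr$positions), ], wp[nrow(wp), ])
  # every point lies on one of the two legs (distance to the polyline ~ 0)
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
    sqrt(sum((p - a - t * ab)^2))
  }
  d <- apply(tr$positions, 1, function(p)
    min(seg_dist(p, wp[1, ], wp[2, ]), seg_dist(p, wp[2, ], wp[3, ])))
  expect_lt(max(d), 1e-10)
})

test_that("CT endpoints concentrate at the final waypoint", {
  arena <- arena_config()
  params <- ct_params()
  set.seed(2)
  for (k in 0:3) {
    wp <- ct_default_geometry(arena)[[k + 1]]
    ends <- t(replicate(25, {
      tr <- sample_ct(arena, params, k)
      tr$positions[nrow(tr$positions), ]
    }))
    d <- sqrt(rowSums(sweep(ends, 2, wp[nrow(wp), ])^2))
    expect_true(all(d < 0.1))
  }
})

test_that("CT realizations differ but share the waypoint skeleton", {
  arena <- arena_config()
  params <- ct_params()
  t1 <- local({ set.seed(10); sample_ct(arena, params, 2) })
  t2 <- local({ set.seed(20); sample_ct(arena, params, 2) })
  expect_false(isTRUE(all.equal(t1$positions, t2$positions)))
  # both end at the same final waypoint and start at the same start
  expect_equal(t1$positions[1, ], t2$positions[1, ])
  expect_equal(t1$positions[nrow(t1$positions), ],
               t2$positions[nrow(t2$positions), ], tolerance = 1e-12)
})

test_that("infeasible CT routes are rejected with an explicit error", {
  arena <- arena_config(n_steps = 10)   # 0.5 s trial, route needs ~3.7 s
  expect_error(sample_ct(arena, ct_params(), 0), "infeasible")
})

test_that("CT paths are far more stereotyped than RT paths", {
  arena <- arena_config()
  set.seed(5)
  cts <- replicate(6, sample_ct(arena, ct_params(), 1)$positions,
                   simplify = FALSE)
  rts <- replicate(6, sample_rt(arena, rt_params())$positions,
                   simplify = FALSE)
  pair_mean <- function(paths) {
    tot <- c()
    for (i in seq_along(paths)) for (j in seq_len(i - 1)) {
      tot <- c(tot, mean(sqrt(rowSums((paths[[i]] - paths[[j]])^2))))
    }
    mean(tot)
  }
  expect_lt(pair_mean(cts), 0.2 * pair_mean(rts))
})

test_that("datasets honor the trial mixture and mask pattern", {
  arena <- arena_config()
  ts <- make_dataset(20, 0, 0, arena, rt_params(), ct_params(), seed = 1)
  expect_true(all(trial_kinds(ts) == "RT"))

  ts2 <- make_dataset(5, 0.5, 0.5, arena, rt_params(), ct_params(), seed = 2)
  for (tr in ts2$trials) {
    expect_equal(sum(tr$mask), 50)
    expect_true(tr$mask[1])
  }

  # start separation
  for (tr in ts2$trials)
    expect_gte(arena_distance(tr$rnn_start, tr$target$positions[1, ], arena),
               0.1)

  expect_error(make_dataset(2, 0.5, 1, arena, rt_params(), ct_params()))
})

test_that("CT counts fall in the binomial 3-sigma band", {
  params <- ct_params(speed_mean = 3)  # fast so the route fits in 0.5 s
  arena2 <- arena_config(n_steps = 10, v_max_target = 4)  # kind counting only
  ts <- make_dataset(4000, 0.25, 0, arena2, rt_params(), params, seed = 9)
  n_ct <- sum(trial_kinds(ts) == "CT")
  expect_gte(n_ct, 900)
  expect_lte(n_ct, 1100)
})

test_that("datasets are reproducible from their seed", {
  arena <- arena_config()
  a <- make_dataset(6, 0.5, 0.3, arena, rt_params(), ct_params(), seed = 77)
  b <- make_dataset(6, 0.5, 0.3, arena, rt_params(), ct_params(), seed = 77)
  expect_identical(a$trials, b$trials)
})

test_that("trial sets round-trip through the on-disk format", {
  arena <- arena_config(n_steps = 30, dt = 0.15)
  ts <- make_dataset(4, 0.5, 0.4, arena, rt_params(), ct_params(), seed = 5)
  dir <- tempfile("tset")
  write_trialset(ts, dir)
  back <- read_trialset(dir)
  expect_equal(length(back$trials), 4)
  for (i in 1:4) {
    expect_equal(back$trials[[i]]$target$positions,
                 ts$trials[[i]]$target$positions, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(back$trials[[i]]$mask, ts$trials[[i]]$mask)
    expect_equal(back$trials[[i]]$rnn_start, ts$trials[[i]]$rnn_start,
                 tolerance = 1e-12)
  }
  expect_identical(trial_kinds(back), trial_kinds(ts))
  unlink(dir, recursive = TRUE)
})
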