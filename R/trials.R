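#' Build a mask over time-steps for the velocity input
#'
#' Masking withholds the target-velocity input on a fraction of steps. The
#' default pattern is regular temporal subsampling: keep every k-th step with
#' k chosen so the kept fraction is approximately `1 - mask_fraction`, which
#' realizes masking as an increase in temporal spacing between inputs. A
#' Bernoulli pattern is available as an option. The first step is always kept.
#'
#' @param n_steps trial length.
#' @param mask_fraction fraction of steps to mask, in `[0, 1)`.
#' @param kind `"regular"` or `"bernoulli"`.
#' @return logical vector of length `n_steps`; `TRUE` = input delivered.
#' @export
make_mask <- function(n_steps, mask_fraction, kind = c("regular", "bernoulli")) {
  kind <- match.arg(kind)
  stopifnot(mask_fraction >= 0, mask_fraction < 1)
  if (mask_fraction == 0) return(rep(TRUE, n_steps))
  mask <- rep(FALSE, n_steps)
  if (kind == "regular") {
    k <- max(2L, as.integer(round(1 / (1 - mask_fraction))))
    mask[seq(1L, n_steps, by = k)] <- TRUE
  } else {
    mask <- stats::runif(n_steps) >= mask_fraction
    mask[1] <- TRUE
  }
  mask
}

new_trial <- function(rnn_start, target, mask) {
  structure(list(rnn_start = rnn_start, target = target, mask = mask),
            class = "trial")
}

#' Generate a set of pursuit trials
#'
#' Draws trial kinds (RT vs CT) by `ct_fraction`, CT start indices uniformly
#' over the four routes, and for each trial a pursuer start position uniform
#' in the arena but at least `min_start_sep` from the target's start (so no
#' trial begins already captured). Each trial carries an input mask from
#' [make_mask()].
#'
#' @param n_trials number of trials.
#' @param ct_fraction probability that a trial is a CT.
#' @param mask_fraction fraction of masked velocity-input steps, in `[0, 1)`.
#' @param arena an [arena_config()].
#' @param rt_params an [rt_params()].
#' @param ct_params a [ct_params()].
#' @param seed optional integer; when given the set is reproducible.
#' @param mask_kind passed to [make_mask()].
#' @param min_start_sep minimum pursuer-target start separation (m).
#' @return an object of class `trial_set` (list of trials plus the configs).
#' @export
make_dataset <- function(n_trials, ct_fraction, mask_fraction, arena,
                         rt_params, ct_params, seed = NULL,
                         mask_kind = "regular", min_start_sep = 0.1) {
  stopifnot(n_trials >= 1, ct_fraction >= 0, ct_fraction <= 1)
  gen <- function() {
    trials <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      is_ct <- stats::runif(1) < ct_fraction
      target <- if (is_ct) {
        sample_ct(arena, ct_params, sample.int(4, 1) - 1L)
      } else {
        sample_rt(arena, rt_params)
      }
      repeat {
        start <- stats::runif(2, 0, arena$side_length)
        if (arena_distance(start, target$positions[1, ], arena) >= min_start_sep)
          break
      }
      mask <- make_mask(arena$n_steps, mask_fraction, mask_kind)
      trials[[i]] <- new_trial(start, target, mask)
    }
    trials
  }
  trials <- if (is.null(seed)) gen() else with_seed(seed, gen())
  structure(list(trials = trials, ct_fraction = ct_fraction,
                 mask_fraction = mask_fraction, seed = seed, arena = arena,
                 rt_params = rt_params, ct_params = ct_params),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  kinds <- vapply(x$trials, function(tr) tr$target$kind, character(1))
  cat(sprintf("<trial_set> %d trials (%d CT / %d RT), mask_fraction=%.2f\n",
              length(x$trials), sum(kinds == "CT"), sum(kinds == "RT"),
              x$mask_fraction))
  invisible(x)
}

#' Kinds of the trials in a set
#' @param ts a `trial_set`.
#' @return character vector (`"RT"`/`"CT"`).
#' @export
trial_kinds <- function(ts) {
  vapply(ts$trials, function(tr) tr$target$kind, character(1))
}

#' Write a trial set to a directory
#'
#' Layout: `manifest.json` (arena/generator configs and seed), `trials.csv`
#' (trial_id, kind, ct_start_index, rnn_start_x, rnn_start_y) and one
#' `trial_<id>.csv` per trial with columns t (0-based), target_x, target_y,
#' target_vx, target_vy, mask. Coordinates in meters, origin at the arena's
#' lower-left corner.
#'
#' @param ts a `trial_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trialset <- function(ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    n_trials = length(ts$trials), ct_fraction = ts$ct_fraction,
    mask_fraction = ts$mask_fraction, seed = ts$seed,
    arena = unclass(ts$arena), rt_params = unclass(ts$rt_params),
    ct_params = list(speed_mean = ts$ct_params$speed_mean,
                     speed_jitter_sd = ts$ct_params$speed_jitter_sd,
                     heading_jitter_sd = ts$ct_params$heading_jitter_sd))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  idx <- data.frame(
    trial_id = seq_along(ts$trials),
    kind = trial_kinds(ts),
    ct_start_index = vapply(ts$trials, function(tr) tr$target$ct_start_index,
                            integer(1)),
    rnn_start_x = vapply(ts$trials, function(tr) tr$rnn_start[1], numeric(1)),
    rnn_start_y = vapply(ts$trials, function(tr) tr$rnn_start[2], numeric(1)))
  utils::write.csv(format(idx, digits = 17, trim = TRUE),
                   file.path(dir, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  for (i in seq_along(ts$trials)) {
    tr <- ts$trials[[i]]
    df <- data.frame(t = seq_len(nrow(tr$target$positions)) - 1L,
                     target_x = tr$target$positions[, 1],
                     target_y = tr$target$positions[, 2],
                     target_vx = tr$target$velocities[, 1],
                     target_vy = tr$target$velocities[, 2],
                     mask = as.integer(tr$mask))
    utils::write.csv(format(df, digits = 17, trim = TRUE),
                     file.path(dir, sprintf("trial_%04d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a trial set written by [write_trialset()]
#' @param dir dataset directory.
#' @return a `trial_set`.
#' @export
read_trialset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  arena <- arena_config(man$arena$side_length, man$arena$boundary,
                        man$arena$dt, man$arena$n_steps,
                        man$arena$v_max_target, man$arena$v_max_agent)
  rt <- do.call(rt_params, man$rt_params)
  ct <- do.call(ct_params, man$ct_params)
  idx <- utils::read.csv(file.path(dir, "trials.csv"))
  trials <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    df <- utils::read.csv(file.path(dir, sprintf("trial_%04d.csv", i)))
    target <- new_target_trajectory(
      cbind(df$target_x, df$target_y), cbind(df$target_vx, df$target_vy),
      idx$kind[i],
      if (is.na(idx$ct_start_index[i])) NA_integer_
      else as.integer(idx$ct_start_index[i]))
    trials[[i]] <- new_trial(c(idx$rnn_start_x[i], idx$rnn_start_y[i]),
                             target, df$mask == 1)
  }
  structure(list(trials = trials, ct_fraction = man$ct_fraction,
                 mask_fraction = man$mask_fraction, seed = man$seed,
                 arena = arena, rt_params = rt, ct_params = ct),
            class = "trial_set")
}
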