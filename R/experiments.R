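#' Scale presets for experiments
#'
#' `smoke` is a seconds-scale contract check, `desk` a single-workstation
#' replication scale (small networks, hundreds of evaluation trials), and
#' `full` the study scale (N = 1000 units, ranks up to 1000, many seeds),
#' which is compute-heavy and intended for cluster use.
#'
#' @param scale `"smoke"`, `"desk"` or `"full"`.
#' @return named list of sizes: `N`, `n_steps`, `dt`, `ranks`, `epochs`,
#'   `trials_per_epoch`, `batch_size`, `n_eval`, `n_shuffles`, `n_seeds`.
#' @export
scale_preset <- function(scale = c("desk", "smoke", "full")) {
  scale <- match.arg(scale)
  switch(scale,
    smoke = list(N = 32L, n_steps = 30L, dt = 0.15, ranks = c(2L, 8L),
                 epochs = 2L, trials_per_epoch = 32L, batch_size = 16L,
                 learning_rate = 3e-3, n_eval = 8L, n_shuffles = 20L,
                 n_seeds = 1L),
    desk = list(N = 64L, n_steps = 100L, dt = 0.05, ranks = c(2L, 8L, 32L, 64L),
                epochs = 150L, trials_per_epoch = 128L, batch_size = 32L,
                learning_rate = 3e-3, n_eval = 500L, n_shuffles = 200L,
                n_seeds = 3L),
    full = list(N = 1000L, n_steps = 100L, dt = 0.05,
                ranks = c(10L, 20L, 50L, 100L, 200L, 500L, 900L, 1000L),
                epochs = 500L, trials_per_epoch = 1024L, batch_size = 64L,
                learning_rate = 1e-3, n_eval = 1000L, n_shuffles = 500L,
                n_seeds = 30L))
}

#' Experiment configuration
#'
#' @param name one of `"pursuit_basic"`, `"etu_analysis"`, `"predictivity"`,
#'   `"masking_sweep"`, `"ct_fraction_sweep"`, `"rank_sweep"`,
#'   `"periodic_ct"`, `"decoding_sweep"`, `"unit_count_sweep"`.
#' @param scale preset name passed to [scale_preset()].
#' @param seed integer master seed.
#' @param ... overrides of individual preset fields (e.g. `epochs = 10`) or
#'   experiment-specific grids (`mask_fractions`, `ct_fractions`,
#'   `unit_counts`, `shifts`, `loss_kind`).
#' @return an `experiment_config`.
#' @export
experiment_config <- function(name, scale = "desk", seed = 1, ...) {
  name <- match.arg(name, c("pursuit_basic", "etu_analysis", "predictivity",
                            "masking_sweep", "ct_fraction_sweep", "rank_sweep",
                            "periodic_ct", "decoding_sweep",
                            "unit_count_sweep"))
  preset <- scale_preset(scale)
  dots <- list(...)
  for (nm in names(dots)) preset[[nm]] <- dots[[nm]]
  structure(list(name = name, scale = scale, seed = as.integer(seed),
                 preset = preset),
            class = "experiment_config")
}

exp_arena <- function(preset, boundary = "reflective") {
  arena_config(1, boundary, dt = preset$dt, n_steps = preset$n_steps)
}

exp_train <- function(rank, preset, arena, rt, ct, seed,
                      loss_kind = "final_distance", ct_fraction = 0.25,
                      mask_fraction = 0, N = preset$N) {
  params <- init_rnn(N, rank, seed = seed)
  cfg <- train_config(loss_kind = loss_kind, epochs = preset$epochs,
                      trials_per_epoch = preset$trials_per_epoch,
                      batch_size = preset$batch_size,
                      learning_rate = preset$learning_rate,
                      ct_fraction = ct_fraction,
                      mask_fraction = mask_fraction, seed = seed)
  train_rnn(params, arena, rt, ct, cfg)
}

#' Paired evaluation of an RNN and its reactive control
#'
#' For each trial, rolls out the RNN, feeds the reactive control the RNN's
#' instantaneous speed series on the same trial, and computes the behavioral
#' metrics of both: end distance, shortcut metric, and the normalized
#' deviation between the two trajectories.
#'
#' @param params trained `rnn_params`.
#' @param trials list of trials.
#' @param arena an [arena_config()].
#' @return list with `rollouts`, `controls`, and `metrics` -- a tidy
#'   data.frame with one row per trial per model
#'   (`model %in% c("rnn", "control")`).
#' @export
paired_evaluation <- function(params, trials, arena) {
  ro <- rollout_batch(params, trials, arena)
  controls <- vector("list", length(trials))
  rows <- vector("list", 2 * length(trials))
  T_ <- arena$n_steps
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    speeds <- sqrt(rowSums(ro$out_velocities[[i]]^2))
    ctl <- reactive_rollout(tr, speeds, arena)
    controls[[i]] <- ctl
    end_t <- tr$target$positions[T_, ]
    nd <- normalized_deviation(ro$positions[[i]], ctl$positions, arena)
    rows[[2 * i - 1]] <- data.frame(
      trial_id = i, kind = tr$target$kind, model = "rnn",
      end_distance = ro$end_distance[i],
      shortcut = shortcut_metric(ro$positions[[i]], tr$rnn_start, end_t, arena),
      normalized_deviation = nd)
    rows[[2 * i]] <- data.frame(
      trial_id = i, kind = tr$target$kind, model = "control",
      end_distance = ctl$end_distance,
      shortcut = shortcut_metric(ctl$positions, tr$rnn_start, end_t, arena),
      normalized_deviation = nd)
  }
  list(rollouts = ro, controls = controls, metrics = do.call(rbind, rows))
}

#' Condition-level predictivity summary
#'
#' Per trial kind: median end distances of RNN and control, mean normalized
#' deviation, and the KS test and Wasserstein distance between the RNN and
#' control shortcut-metric distributions.
#'
#' @param metrics the tidy metrics table from [paired_evaluation()].
#' @return data.frame with one row per kind present.
#' @export
summarize_predictivity <- function(metrics) {
  out <- data.frame()
  for (k in unique(metrics$kind)) {
    m <- metrics[metrics$kind == k, ]
    rnn <- m[m$model == "rnn", ]
    ctl <- m[m$model == "control", ]
    ks <- ks_two_sample(rnn$shortcut, ctl$shortcut)
    out <- rbind(out, data.frame(
      kind = k, n_trials = nrow(rnn),
      rnn_median_end = stats::median(rnn$end_distance),
      control_median_end = stats::median(ctl$end_distance),
      mean_normalized_deviation = mean(rnn$normalized_deviation, na.rm = TRUE),
      rnn_mean_shortcut = mean(rnn$shortcut),
      control_mean_shortcut = mean(ctl$shortcut),
      ks_D = ks$D, ks_p = ks$p,
      wasserstein = wasserstein_1d(rnn$shortcut, ctl$shortcut)))
  }
  out
}

#' Stack rollouts into decoding-ready matrices
#'
#' @param rollouts list of `rollout_result`s.
#' @param trials matching trials.
#' @param arena an [arena_config()].
#' @return list: `activations` (stacked T x N blocks), `trial_ids`,
#'   `ego_distance` (1 col), `target_position`, `self_position` (2 cols).
#' @export
build_decode_data <- function(rollouts, trials, arena) {
  acts <- list()
  ids <- list()
  egod <- list()
  tpos <- list()
  spos <- list()
  for (i in seq_along(rollouts)) {
    ro <- rollouts[[i]]
    acts[[i]] <- ro$activations
    ids[[i]] <- rep(i, nrow(ro$activations))
    egod[[i]] <- arena_distance(trials[[i]]$target$positions, ro$positions,
                                arena)
    tpos[[i]] <- trials[[i]]$target$positions
    spos[[i]] <- ro$positions
  }
  list(activations = do.call(rbind, acts), trial_ids = unlist(ids),
       ego_distance = matrix(unlist(egod), ncol = 1),
       target_position = do.call(rbind, tpos),
       self_position = do.call(rbind, spos))
}

write_manifest <- function(out_dir, cfg, extra = list()) {
  man <- c(list(name = cfg$name, scale = cfg$scale, seed = cfg$seed,
                preset = cfg$preset,
                package_version = as.character(utils::packageVersion("pursuitnet"))),
           extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

write_tidy_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run a named experiment
#'
#' Config-driven orchestration of the package's analyses at a chosen scale:
#' trains the required networks, evaluates them against the reactive
#' control, and writes tidy CSVs plus a JSON summary and a manifest
#' sufficient to reproduce the run. See [experiment_config()] for the
#' experiment names.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly; side effect: files under `out_dir`.
#' @export
run_experiment <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- cfg$preset
  rt <- rt_params()
  ct <- ct_params()
  seed <- cfg$seed
  eval_set <- function(arena, n, ctf = 0.5, maskf = 0)
    make_dataset(n, ctf, maskf, arena, rt, ct, seed = seed + 7777L)

  res <- switch(cfg$name,
    pursuit_basic = {
      arena <- exp_arena(p)
      fit <- exp_train(max(p$ranks), p, arena, rt, ct, seed)
      write_tidy_csv(fit$history, file.path(out_dir, "history.csv"))
      save_rnn(fit$params, file.path(out_dir, "checkpoint.rds"))
      ev <- eval_set(arena, p$n_eval)
      pe <- paired_evaluation(fit$params, ev$trials, arena)
      write_tidy_csv(pe$metrics, file.path(out_dir, "metrics.csv"))
      summarize_predictivity(pe$metrics)
    },
    predictivity = {
      arena <- exp_arena(p)
      fit <- exp_train(max(p$ranks), p, arena, rt, ct, seed)
      ev <- eval_set(arena, p$n_eval)
      pe <- paired_evaluation(fit$params, ev$trials, arena)
      write_tidy_csv(pe$metrics, file.path(out_dir, "metrics.csv"))
      summarize_predictivity(pe$metrics)
    },
    etu_analysis = {
      arena <- exp_arena(p)
      fit <- exp_train(max(p$ranks), p, arena, rt, ct, seed)
      ev <- eval_set(arena, p$n_eval, ctf = 0)
      ro <- rollout_batch(fit$params, ev$trials, arena)
      egos <- lapply(seq_along(ev$trials), function(i)
        egocentric_coords(structure(list(
          positions = ro$positions[[i]], headings = ro$headings[[i]]),
          class = "rollout_result"), ev$trials[[i]], arena))
      A <- do.call(rbind, ro$activations)
      E <- do.call(rbind, egos)
      ids <- rep(seq_along(ev$trials), each = arena$n_steps)
      etu <- classify_etus(A, E, ids, n_shuffles = p$n_shuffles, seed = seed)
      write_tidy_csv(etu$units, file.path(out_dir, "etu_units.csv"))
      abl <- ablation_curve(fit$params, etu$units$mrl,
                            c(0, 0.1, 0.25, 0.5), ev$trials, arena,
                            ordering = "highest_mrl", seed = seed)
      write_tidy_csv(abl$summary, file.path(out_dir, "ablation_highest.csv"))
      data.frame(etu_fraction = etu$fraction)
    },
    masking_sweep = {
      arena <- exp_arena(p)
      grid <- p$mask_fractions %||% c(0, 0.3, 0.5, 0.7)
      out <- data.frame()
      for (mf in grid) {
        fit <- exp_train(max(p$ranks), p, arena, rt, ct, seed,
                         mask_fraction = mf)
        ev <- eval_set(arena, p$n_eval, maskf = mf)
        pe <- paired_evaluation(fit$params, ev$trials, arena)
        s <- summarize_predictivity(pe$metrics)
        s$mask_fraction <- mf
        out <- rbind(out, s)
      }
      out
    },
    ct_fraction_sweep = {
      arena <- exp_arena(p)
      grid <- p$ct_fractions %||% c(0, 0.1, 0.25, 0.5)
      out <- data.frame()
      for (cf in grid) {
        fit <- exp_train(max(p$ranks), p, arena, rt, ct, seed,
                         ct_fraction = cf)
        ev <- eval_set(arena, p$n_eval)
        pe <- paired_evaluation(fit$params, ev$trials, arena)
        s <- summarize_predictivity(pe$metrics)
        s$ct_fraction <- cf
        out <- rbind(out, s)
      }
      out
    },
    rank_sweep = {
      arena <- exp_arena(p)
      loss_kind <- p$loss_kind %||% "final_distance"
      out <- data.frame()
      for (r in p$ranks) for (s_i in seq_len(p$n_seeds)) {
        fit <- exp_train(r, p, arena, rt, ct, seed + s_i - 1L,
                         loss_kind = loss_kind)
        ev <- eval_set(arena, p$n_eval)
        pe <- paired_evaluation(fit$params, ev$trials, arena)
        sm <- summarize_predictivity(pe$metrics)
        A <- do.call(rbind, pe$rollouts$activations)
        sm$rank <- r
        sm$seed <- seed + s_i - 1L
        sm$pca95_activations <- pca95(A)
        sm$pca95_latents <- pca95(rnn_latents(fit$params, A))
        sm$participation_ratio <- participation_ratio(A)
        out <- rbind(out, sm)
      }
      out
    },
    periodic_ct = {
      arena <- exp_arena(p, boundary = "periodic")
      fit <- exp_train(max(p$ranks), p, arena, rt, ct, seed)
      ev <- make_dataset(p$n_eval, 1, 0, arena, rt, ct, seed = seed + 7777L)
      ro <- rollout_batch(fit$params, ev$trials, arena)
      rolls <- lapply(seq_along(ev$trials), function(i)
        structure(list(positions = ro$positions[[i]]), class = "rollout_result"))
      curves <- distance_to_endpoint_curves(rolls, ev$trials, arena)
      cdf <- do.call(rbind, lapply(names(curves), function(g)
        data.frame(group = g, t = seq_along(curves[[g]]) - 1L,
                   mean_distance = curves[[g]])))
      write_tidy_csv(cdf, file.path(out_dir, "endpoint_curves.csv"))
      waits <- lapply(seq_along(ev$trials), function(i) {
        T_ <- arena$n_steps
        endp <- matrix(ev$trials[[i]]$target$positions[T_, ], T_, 2,
                       byrow = TRUE)
        d <- arena_distance(ro$positions[[i]], endp, arena)
        w <- detect_waiting(d, eps = 0.005, min_len = 10)
        if (nrow(w)) cbind(trial_id = i, w) else NULL
      })
      waits <- do.call(rbind, waits)
      if (!is.null(waits))
        write_tidy_csv(waits, file.path(out_dir, "waiting.csv"))
      data.frame(median_end = stats::median(ro$end_distance),
                 n_waiting_trials = if (is.null(waits)) 0L
                                    else length(unique(waits$trial_id)))
    },
    decoding_sweep = {
      arena <- exp_arena(p)
      shifts <- p$shifts %||% c(-10L, -5L, 0L, 5L, 10L)
      out <- data.frame()
      for (r in p$ranks) {
        fit <- exp_train(r, p, arena, rt, ct, seed)
        ev <- eval_set(arena, p$n_eval)
        ro <- rollout_batch(fit$params, ev$trials, arena)
        rolls <- lapply(seq_along(ev$trials), function(i)
          structure(list(positions = ro$positions[[i]],
                         activations = ro$activations[[i]]),
                    class = "rollout_result"))
        dd <- build_decode_data(rolls, ev$trials, arena)
        for (feat in c("ego_distance", "target_position", "self_position"))
          for (s in shifts) {
            dec <- linear_decode(dd$activations, dd[[feat]], dd$trial_ids,
                                 shift = s, seed = seed)
            out <- rbind(out, data.frame(
              feature = feat, shift = s, rank = r, seed = seed,
              error = dec$error, r2 = dec$r2,
              shuffle_error = dec$shuffle_error))
          }
      }
      out
    },
    unit_count_sweep = {
      arena <- exp_arena(p)
      counts <- p$unit_counts %||% c(32L, 64L, 128L)
      r <- min(p$ranks)
      out <- data.frame()
      for (N in counts) {
        fit <- exp_train(min(r, N), p, arena, rt, ct, seed, N = N)
        ev <- eval_set(arena, p$n_eval)
        pe <- paired_evaluation(fit$params, ev$trials, arena)
        s <- summarize_predictivity(pe$metrics)
        s$N <- N
        out <- rbind(out, s)
      }
      out
    })

  write_tidy_csv(res, file.path(out_dir, "summary.csv"))
  jsonlite::write_json(res, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(out_dir, cfg)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
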