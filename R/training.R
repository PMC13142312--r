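#' Training configuration
#'
#' @param loss_kind `"final_distance"` (distance between the agents on the
#'   last step -- the capture-like objective) or `"mean_distance"` (average
#'   distance over all steps -- incentivizes reactive pursuit).
#' @param epochs number of training epochs; fresh trials are sampled each
#'   epoch.
#' @param trials_per_epoch,batch_size dataset and minibatch sizes.
#' @param learning_rate Adam step size.
#' @param lr_decay factor applied to the learning rate late in training
#'   (1 disables); stabilizes the endpoint after the loss has plateaued.
#' @param lr_decay_at fraction of epochs after which the decay applies.
#' @param grad_clip global gradient-norm clip (`Inf` disables).
#' @param ct_fraction,mask_fraction trial mixture and input masking used for
#'   the training data.
#' @param seed integer; the whole run (data and updates) is reproducible.
#' @param squared use squared distance in the loss instead of plain distance.
#' @param eval_trials number of held-out trials (half RT, half CT) used for
#'   the per-epoch RT/CT median end-distance snapshots; 0 disables.
#' @return an object of class `train_config`.
#' @export
train_config <- function(loss_kind = c("final_distance", "mean_distance"),
                         epochs = 150, trials_per_epoch = 128, batch_size = 32,
                         learning_rate = 3e-3, lr_decay = 0.2,
                         lr_decay_at = 0.7, grad_clip = 1,
                         ct_fraction = 0.25, mask_fraction = 0, seed = 1,
                         squared = FALSE, eval_trials = 0) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(epochs >= 1, trials_per_epoch >= 1, batch_size >= 1,
            learning_rate > 0, lr_decay > 0, lr_decay <= 1,
            lr_decay_at >= 0, lr_decay_at <= 1,
            ct_fraction >= 0, ct_fraction < 1 + 1e-12,
            mask_fraction >= 0, mask_fraction < 1)
  structure(list(loss_kind = loss_kind, epochs = as.integer(epochs),
                 trials_per_epoch = as.integer(trials_per_epoch),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 lr_decay_at = lr_decay_at, grad_clip = grad_clip,
                 ct_fraction = ct_fraction, mask_fraction = mask_fraction,
                 seed = as.integer(seed), squared = squared,
                 eval_trials = as.integer(eval_trials)),
            class = "train_config")
}

#' Final-distance loss of a rollout
#'
#' Geodesic (boundary-aware) distance between pursuer and target on the last
#' time-step; identical to the rollout's `end_distance`.
#'
#' @param rollout a `rollout_result` produced from `trial`.
#' @param trial the trial.
#' @param arena an [arena_config()].
#' @return meters.
#' @export
loss_final <- function(rollout, trial, arena) {
  T_ <- nrow(rollout$positions)
  arena_distance(rollout$positions[T_, ], trial$target$positions[T_, ], arena)
}

#' Mean-distance loss of a rollout
#'
#' Mean over time-steps of the geodesic inter-agent distance.
#'
#' @inheritParams loss_final
#' @return meters.
#' @export
loss_mean <- function(rollout, trial, arena) {
  mean(arena_distance(rollout$positions, trial$target$positions, arena))
}

# gradient of the squashed velocity v = c z/(1+||z||) w.r.t. z, applied to
# upstream gradient gv (2 x B matrices)
squash_backward <- function(z, gv, v_max) {
  n <- sqrt(colSums(z^2))
  inv1 <- 1 / (1 + n)
  dots <- colSums(z * gv)
  coef <- ifelse(n > 1e-12, dots / (n * (1 + n)^2), 0)
  v_max * (sweep(gv, 2, inv1, "*") - sweep(z, 2, coef, "*"))
}

#' Loss and parameter gradients on a batch of trials
#'
#' Runs the batched forward pass and backpropagation through time, returning
#' the mean per-trial loss and its exact gradients with respect to all
#' parameters (`M`, `Q`, `B`, `b`, `W_out`). Boundary resolution is treated
#' as the identity in the backward pass (straight-through), which is exact
#' whenever no clipping/wrapping occurs on the rollout.
#'
#' @param params an `rnn_params`.
#' @param trials list of trials (equal length).
#' @param arena an [arena_config()].
#' @param loss_kind `"final_distance"` or `"mean_distance"`.
#' @param squared use squared distances.
#' @return list with `loss` (scalar), `grads` (named list of arrays), and
#'   `end_distance` (per-trial vector).
#' @export
rnn_loss_grads <- function(params, trials, arena,
                           loss_kind = "final_distance", squared = FALSE) {
  ba <- batch_arrays(params, trials, arena)
  res <- .bptt_core(params$M, params$Q, params$B, params$b, params$W_out,
                    ba$U, ba$P0, ba$TG, params$alpha, arena$dt,
                    arena$v_max_agent, arena$side_length,
                    arena$boundary == "periodic",
                    if (loss_kind == "final_distance") 0L else 1L,
                    squared, TRUE, FALSE)
  grads <- res$grads
  grads$b <- as.numeric(grads$b)
  list(loss = res$loss, grads = grads,
       end_distance = as.numeric(res$end_distance))
}

#' Mean training loss of parameters on fixed trials
#'
#' Convenience wrapper (used e.g. for finite-difference checks): forward pass
#' only, no gradients.
#' @inheritParams rnn_loss_grads
#' @return scalar loss.
#' @export
rnn_training_loss <- function(params, trials, arena,
                              loss_kind = "final_distance", squared = FALSE) {
  ba <- batch_arrays(params, trials, arena)
  res <- .bptt_core(params$M, params$Q, params$B, params$b, params$W_out,
                    ba$U, ba$P0, ba$TG, params$alpha, arena$dt,
                    arena$v_max_agent, arena$side_length,
                    arena$boundary == "periodic",
                    if (loss_kind == "final_distance") 0L else 1L,
                    squared, FALSE, FALSE)
  res$loss
}

adam_init <- function(params) {
  lapply(params[c("M", "Q", "B", "b", "W_out")],
         function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(params, grads, state, step, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(state)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^step)
    vhat <- state[[nm]]$v / (1 - beta2^step)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the pursuit RNN
#'
#' Gradient-based minimization of the chosen distance loss with Adam and
#' backpropagation through time. Fresh trials are sampled every epoch from
#' the given generators; the run is fully reproducible from `cfg$seed`.
#' Only the factors `M`, `Q` (never the dense recurrent matrix) are updated,
#' so the rank constraint is preserved exactly throughout training.
#'
#' @param params initial `rnn_params` from [init_rnn()].
#' @param arena an [arena_config()].
#' @param rt_params,ct_params target-trajectory generator parameters.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `params` (trained) and `history` (data.frame: epoch,
#'   loss, end_distance, and if `cfg$eval_trials > 0` rt_median, ct_median).
#' @export
train_rnn <- function(params, arena, rt_params, ct_params, cfg,
                      verbose = FALSE) {
  with_seed(cfg$seed, {
    eval_set <- NULL
    if (cfg$eval_trials > 0) {
      half <- max(1L, cfg$eval_trials %/% 2L)
      ev_rt <- make_dataset(half, 0, cfg$mask_fraction, arena, rt_params,
                            ct_params)$trials
      ev_ct <- make_dataset(half, 1, cfg$mask_fraction, arena, rt_params,
                            ct_params)$trials
      eval_set <- list(rt = ev_rt, ct = ev_ct)
    }
    state <- adam_init(params)
    step <- 0L
    history <- data.frame(epoch = integer(), loss = numeric(),
                          end_distance = numeric(),
                          rt_median = numeric(), ct_median = numeric())
    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate *
        if (epoch > cfg$lr_decay_at * cfg$epochs) cfg$lr_decay else 1
      ts <- make_dataset(cfg$trials_per_epoch, cfg$ct_fraction,
                         cfg$mask_fraction, arena, rt_params, ct_params)
      ord <- sample.int(length(ts$trials))
      losses <- c()
      ends <- c()
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        lg <- rnn_loss_grads(params, ts$trials[idx], arena, cfg$loss_kind,
                             cfg$squared)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
        gn <- sqrt(sum(vapply(lg$grads, function(g) sum(g^2), numeric(1))))
        if (is.finite(cfg$grad_clip) && gn > cfg$grad_clip)
          lg$grads <- lapply(lg$grads, function(g) g * cfg$grad_clip / gn)
        step <- step + 1L
        upd <- adam_update(params, lg$grads, state, step, lr)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, lg$loss)
        ends <- c(ends, mean(lg$end_distance))
      }
      rt_med <- ct_med <- NA_real_
      if (!is.null(eval_set)) {
        rt_med <- stats::median(rollout_batch(params, eval_set$rt,
                                              arena)$end_distance)
        ct_med <- stats::median(rollout_batch(params, eval_set$ct,
                                              arena)$end_distance)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = mean(losses), end_distance = mean(ends),
        rt_median = rt_med, ct_median = ct_med))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  end %.4f  rt %.3f  ct %.3f",
                        epoch, mean(losses), mean(ends), rt_med, ct_med))
    }
    list(params = params, history = history)
  })
}

#' Silence a set of recurrent units
#'
#' Structural ablation: zeroes the units' rows of `M`, `B` and bias entries
#' (so their state stays at 0) and their rows of `Q` and columns of `W_out`
#' (so nothing downstream sees them). The rank bound of the recurrent matrix
#' is preserved. Duplicate ids are deduplicated.
#'
#' @param params an `rnn_params`.
#' @param unit_ids integer unit indices (1-based) in `1:N`.
#' @return ablated `rnn_params` (self-contained; rollouts of the result have
#'   exactly zero activation on the ablated units).
#' @export
ablate_units <- function(params, unit_ids) {
  unit_ids <- unique(as.integer(unit_ids))
  if (length(unit_ids) == 0) return(params)
  stopifnot(all(unit_ids >= 1), all(unit_ids <= params$N))
  params$M[unit_ids, ] <- 0
  params$Q[unit_ids, ] <- 0
  params$B[unit_ids, ] <- 0
  params$b[unit_ids] <- 0
  params$W_out[, unit_ids] <- 0
  params
}

#' Performance under progressive unit ablation
#'
#' Evaluates end distances on a fixed trial set while ablating growing
#' fractions of units, ordered by tuning strength (highest or lowest MRL
#' first) or at random. Random ablation is repeated with distinct unit
#' draws and pooled; targeted curves are compared to the pooled random
#' distribution with a two-sample Kolmogorov-Smirnov test at each fraction.
#'
#' @param params trained `rnn_params`.
#' @param mrl_values per-unit MRL vector (length N) used for the ordering.
#' @param fractions ablation fractions in `[0, 1)`.
#' @param eval_trials list of trials for evaluation.
#' @param arena an [arena_config()].
#' @param ordering `"highest_mrl"`, `"lowest_mrl"` or `"random"`.
#' @param n_random_repeats number of random-ablation repeats.
#' @param seed seed for the random unit draws.
#' @return list with `summary` (data.frame: fraction, n_ablated,
#'   mean_end_distance, random_mean_end_distance, ks_D, ks_p) and
#'   `end_distances` (per fraction: targeted and pooled random vectors).
#' @export
ablation_curve <- function(params, mrl_values, fractions, eval_trials, arena,
                           ordering = c("highest_mrl", "lowest_mrl", "random"),
                           n_random_repeats = 5, seed = 1) {
  ordering <- match.arg(ordering)
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1)")
  N <- params$N
  ord_ids <- switch(ordering,
    highest_mrl = order(mrl_values, decreasing = TRUE),
    lowest_mrl = order(mrl_values, decreasing = FALSE),
    random = NULL)
  res <- data.frame()
  dists <- list()
  with_seed(seed, {
    for (f in fractions) {
      k <- as.integer(round(f * N))
      targ <- if (is.null(ord_ids)) {
        rollout_batch(ablate_units(params, sample.int(N, k)), eval_trials,
                      arena)$end_distance
      } else {
        rollout_batch(ablate_units(params, ord_ids[seq_len(k)]), eval_trials,
                      arena)$end_distance
      }
      rand <- unlist(lapply(seq_len(n_random_repeats), function(r) {
        rollout_batch(ablate_units(params, sample.int(N, k)), eval_trials,
                      arena)$end_distance
      }))
      ks <- if (k > 0) ks_two_sample(targ, rand) else list(D = NA_real_,
                                                           p = NA_real_)
      res <- rbind(res, data.frame(
        fraction = f, n_ablated = k, mean_end_distance = mean(targ),
        random_mean_end_distance = mean(rand), ks_D = ks$D, ks_p = ks$p))
      dists[[as.character(f)]] <- list(targeted = targ, random = rand)
    }
  })
  list(summary = res, end_distances = dists, ordering = ordering)
}
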