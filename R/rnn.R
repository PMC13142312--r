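#' Number of input channels of the pursuit RNN
#'
#' Channels 1-4: the initial positions of pursuer and target, delivered as a
#' single pulse on the first step. Channels 5-6: the target's allocentric
#' velocity at steps where the input mask is on, zero otherwise.
#' @export
RNN_N_IN <- 6L

#' Initialize pursuit RNN parameters with rank-constrained recurrence
#'
#' The recurrent matrix is the factor product `W = M %*% t(Q) / N` with
#' `M, Q` of size N x rank, so `rank(W) <= rank` holds exactly, before and
#' after gradient training (training updates the factors, never W itself).
#' Factor entries are i.i.d. Gaussian with a variance chosen so the largest
#' singular value of W is approximately `gain` at every rank (exactly `gain`
#' in expectation at full rank).
#'
#' @param N number of recurrent units.
#' @param rank recurrent rank, `1 <= rank <= N`.
#' @param n_in number of input channels (default [RNN_N_IN]).
#' @param seed integer seed; identical arguments give identical parameters.
#' @param gain target spectral scale of W.
#' @param alpha leak rate in `(0, 1]` of the discrete-time dynamics.
#' @param input_gain scale of the input and readout weights.
#' @return an object of class `rnn_params` with fields `M`, `Q` (N x rank),
#'   `B` (N x n_in), `b` (N), `W_out` (2 x N), `alpha`, `N`, `rank`, `seed`.
#' @export
init_rnn <- function(N, rank, n_in = RNN_N_IN, seed = 1, gain = 1,
                     alpha = 0.5, input_gain = 1) {
  stopifnot(rank >= 1, N >= 1)
  if (rank > N) stop("rank must be <= N")
  stopifnot(alpha > 0, alpha <= 1)
  with_seed(seed, {
    # For factor sd s: t(Q) %*% Q ~ N s^2 I, so sigma_max(W) ~
    # s^2 (1 + sqrt(rank/N)); s^2 = gain / (1 + sqrt(rank/N)) keeps the
    # spectral scale ~ gain at every rank (~ gain at full rank)
    s <- sqrt(gain / (1 + sqrt(rank / N)))
    M <- matrix(stats::rnorm(N * rank, 0, s), N, rank)
    Q <- matrix(stats::rnorm(N * rank, 0, s), N, rank)
    B <- matrix(stats::rnorm(N * n_in, 0, input_gain / sqrt(n_in)), N, n_in)
    b <- rep(0, N)
    W_out <- matrix(stats::rnorm(2 * N, 0, input_gain / sqrt(N)), 2, N)
    structure(list(M = M, Q = Q, B = B, b = b, W_out = W_out,
                   N = as.integer(N), rank = as.integer(rank),
                   n_in = as.integer(n_in), alpha = alpha,
                   seed = as.integer(seed)),
              class = "rnn_params")
  })
}

#' @export
print.rnn_params <- function(x, ...) {
  cat(sprintf("<rnn_params> N=%d, rank=%d, n_in=%d, alpha=%.2f\n",
              x$N, x$rank, x$n_in, x$alpha))
  invisible(x)
}

#' Effective recurrent weight matrix
#' @param params an [init_rnn()] object.
#' @return the N x N matrix `M %*% t(Q) / N`, of rank at most `params$rank`.
#' @export
effective_weight <- function(params) {
  (params$M %*% t(params$Q)) / params$N
}

#' Build the input sequence of a trial
#'
#' @param trial a trial from [make_dataset()].
#' @return a T x 6 matrix: columns 1-4 hold
#'   (pursuer x0, pursuer y0, target x0, target y0) on the first row only;
#'   columns 5-6 hold the target velocity where the mask is on, 0 elsewhere.
#' @export
build_inputs <- function(trial) {
  T_ <- nrow(trial$target$positions)
  u <- matrix(0, T_, RNN_N_IN)
  u[1, 1:4] <- c(trial$rnn_start, trial$target$positions[1, ])
  on <- which(trial$mask)
  u[on, 5:6] <- trial$target$velocities[on, , drop = FALSE]
  u
}

#' One step of the leaky RNN dynamics
#'
#' `h' = (1 - alpha) * h + alpha * (W tanh(h) + B u + b)` with
#' `W = M t(Q)/N` applied in factored form. The nonlinearity sits inside the
#' recurrent product, so with `h(0) = 0` the state stays in
#' `span{columns of M, columns of B, b}` at every step -- the property that
#' bounds the latent dimensionality of a rank-r network by r + n_in (+1).
#'
#' @param params an `rnn_params`.
#' @param h state vector (length N) or N x batch matrix.
#' @param u_t input vector (length n_in) or n_in x batch matrix.
#' @return updated state, same shape as `h`.
#' @export
rnn_step <- function(params, h, u_t) {
  if (!all(is.finite(h)) || !all(is.finite(u_t)))
    stop("non-finite state or input in rnn_step")
  vec_in <- is.null(dim(h))
  a <- tanh(h)
  rec <- params$M %*% (crossprod(params$Q, a) / params$N)
  out <- (1 - params$alpha) * h +
    params$alpha * (rec + params$B %*% u_t + params$b)
  if (vec_in) as.numeric(out) else out
}

# squash a 2 x B readout matrix into velocities bounded by v_max:
# v = v_max * z / (1 + ||z||)
squash_velocity <- function(z, v_max) {
  n <- sqrt(colSums(z^2))
  sweep(z, 2, v_max / (1 + n), "*")
}

#' Roll out the RNN agent on a trial
#'
#' Starting from `h = 0` at the pursuer's start position, iterates
#' [rnn_step()] over the trial inputs; the readout `z_t = W_out tanh(h_t)`
#' is interpreted as movement direction (its angle) and speed
#' `v_max_agent * ||z|| / (1 + ||z||)` (smoothly bounded), and positions are
#' integrated with [resolve_boundary()]. The heading is the direction of the
#' last movement faster than `eps_speed` (NA before any such movement).
#'
#' @param params an `rnn_params`.
#' @param trial a trial.
#' @param arena an [arena_config()].
#' @param eps_speed speed threshold (m/s) below which the heading is frozen.
#' @return an object of class `rollout_result` with fields `activations`
#'   (T x N, `tanh(h_t)`), `out_velocities` (T x 2, m/s), `positions`
#'   (T x 2, m), `headings` (T, rad), `end_distance` (m).
#' @export
rollout <- function(params, trial, arena, eps_speed = 1e-3) {
  res <- rollout_batch(params, list(trial), arena, eps_speed)
  structure(list(activations = res$activations[[1]],
                 out_velocities = res$out_velocities[[1]],
                 positions = res$positions[[1]],
                 headings = res$headings[[1]],
                 end_distance = res$end_distance[1]),
            class = "rollout_result")
}

#' Roll out the RNN on many trials at once
#'
#' Batched version of [rollout()]; all trials must share the same length.
#'
#' @inheritParams rollout
#' @param trials list of trials.
#' @return list with per-trial lists `activations`, `out_velocities`,
#'   `positions`, `headings`, and the numeric vector `end_distance`.
#' @export
rollout_batch <- function(params, trials, arena, eps_speed = 1e-3) {
  fw <- rnn_forward(params, trials, arena)
  B <- length(trials)
  T_ <- arena$n_steps
  end_d <- numeric(B)
  acts <- vector("list", B)
  vels <- vector("list", B)
  poss <- vector("list", B)
  heads <- vector("list", B)
  for (i in seq_len(B)) {
    acts[[i]] <- t(fw$A[, i, , drop = FALSE][, 1, ])
    vels[[i]] <- t(fw$V[, i, , drop = FALSE][, 1, ])
    poss[[i]] <- t(fw$P[, i, , drop = FALSE][, 1, ])
    sp <- sqrt(rowSums(vels[[i]]^2))
    h <- rep(NA_real_, T_)
    cur <- NA_real_
    for (t in seq_len(T_)) {
      if (sp[t] > eps_speed) cur <- atan2(vels[[i]][t, 2], vels[[i]][t, 1])
      h[t] <- cur
    }
    heads[[i]] <- h
    end_d[i] <- arena_distance(poss[[i]][T_, ],
                               trials[[i]]$target$positions[T_, ], arena)
  }
  list(activations = acts, out_velocities = vels, positions = poss,
       headings = heads, end_distance = end_d)
}

# assemble the batched input/target arrays of a trial list
batch_arrays <- function(params, trials, arena) {
  B <- length(trials)
  T_ <- arena$n_steps
  U <- array(0, c(params$n_in, B, T_))
  P0 <- matrix(0, 2, B)
  TG <- array(0, c(2, B, T_))
  for (i in seq_len(B)) {
    U[, i, ] <- t(build_inputs(trials[[i]]))
    P0[, i] <- trials[[i]]$rnn_start
    TG[, i, ] <- t(trials[[i]]$target$positions)
  }
  list(U = U, P0 = P0, TG = TG)
}

# Core batched forward pass (compiled). Returns arrays:
#   A: N x B x T activations tanh(h_t); S: N x B x T pre-activation states;
#   Z: 2 x B x T readouts; V: 2 x B x T velocities; P: 2 x B x T positions;
#   U: n_in x B x T inputs.
# Kept internal; rollout()/training wrap it.
rnn_forward <- function(params, trials, arena) {
  ba <- batch_arrays(params, trials, arena)
  res <- .bptt_core(params$M, params$Q, params$B, params$b, params$W_out,
                    ba$U, ba$P0, ba$TG, params$alpha, arena$dt,
                    arena$v_max_agent, arena$side_length,
                    arena$boundary == "periodic", 0L, FALSE, FALSE, TRUE)
  list(A = res$A, S = res$S, Z = res$Z, V = res$V, P = res$P,
       U = ba$U, targets = ba$TG, P0 = ba$P0,
       end_distance = as.numeric(res$end_distance))
}

#' Save RNN parameters to a checkpoint
#'
#' Writes the parameter arrays as an RDS file (bit-exact round trip) and a
#' sidecar JSON manifest with the scalar attributes.
#'
#' @param params an `rnn_params`.
#' @param path checkpoint path (an `.rds` file).
#' @return `path`, invisibly.
#' @export
save_rnn <- function(params, path) {
  saveRDS(params, path)
  jsonlite::write_json(
    list(N = params$N, rank = params$rank, n_in = params$n_in,
         alpha = params$alpha, seed = params$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load RNN parameters from a checkpoint
#' @param path path written by [save_rnn()].
#' @return an `rnn_params`.
#' @export
load_rnn <- function(path) {
  params <- readRDS(path)
  stopifnot(inherits(params, "rnn_params"))
  params
}
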