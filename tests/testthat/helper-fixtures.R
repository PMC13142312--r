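# Shared fixtures. Trained networks are expensive, so they are built lazily
# and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

default_arena <- function(...) arena_config(...)

# desk-scale training recipe used across behavioral tests
trained_net <- function(rank, N = 64, seed = 11, train_seed = 21,
                        epochs = 150) {
  key <- sprintf("net_%d_%d_%d_%d_%d", N, rank, seed, train_seed, epochs)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  arena <- arena_config()
  fit <- train_rnn(init_rnn(N, rank, seed = seed), arena, rt_params(),
                   ct_params(),
                   train_config(epochs = epochs, seed = train_seed))
  .fixture_cache[[key]] <- fit
  fit
}

eval_trials <- function(n = 400, ct_fraction = 0.5, seed = 99,
                        arena = arena_config()) {
  key <- sprintf("ev_%d_%s_%d_%s_%d", n, format(ct_fraction), seed,
                 arena$boundary, arena$n_steps)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  ts <- make_dataset(n, ct_fraction, 0, arena, rt_params(), ct_params(),
                     seed = seed)
  .fixture_cache[[key]] <- ts
  ts
}

# a hand-made trial with a fully specified target path
fixed_trial <- function(positions, rnn_start, arena,
                        velocities = NULL, mask = NULL) {
  T_ <- nrow(positions)
  if (is.null(velocities))
    velocities <- rbind(displacement(positions[-1, , drop = FALSE],
                                     positions[-T_, , drop = FALSE],
                                     arena) / arena$dt,
                        c(0, 0))
  if (is.null(mask)) mask <- rep(TRUE, T_)
  structure(list(
    rnn_start = rnn_start,
    target = structure(list(positions = positions, velocities = velocities,
                            kind = "RT", ct_start_index = NA_integer_),
                       class = "target_trajectory"),
    mask = mask), class = "trial")
}

# a hand-made rollout carrying just what the representation analyses read
fake_rollout <- function(positions, headings, activations = NULL) {
  structure(list(positions = positions, headings = headings,
                 activations = activations),
            class = "rollout_result")
}
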