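#' Training configuration
#'
#' Collects every knob of the latency-targeted training scheme. The defaults
#' are the tuned short-latency operating point (target latency l = 1):
#' batch size 3, derivative clip 247.36, no-spike penalty 33.83, weight
#' learning rate 1.676e-3, pulse learning rate 1.441e-3, and Glorot mean
#' multipliers -9.53 (regular) / -8.08 (pulse). See [train_config_l16] for
#' the long-latency point.
#'
#' @param latency target latency l: every output neuron is trained to spike
#'   l after its corresponding input pixel (same units as the spike times).
#' @param learning_rate Adam learning rate for the weights.
#' @param learning_rate_pulses Adam learning rate for the pulse spike times.
#' @param batch_size examples per gradient step (gradients are averaged).
#' @param clip_derivative clamp for each exact partial (they diverge near
#'   threshold tangency).
#' @param penalty_no_spike positive penalty added (with negative sign) to the
#'   incoming weight gradients of silent neurons, to encourage spiking.
#' @param epochs passes over the training set.
#' @param nonpulse_init_multiplier,pulse_init_multiplier Glorot mean shifts
#'   used by [init_network].
#' @param seed RNG seed for initialisation and epoch shuffling.
#' @param surrogate spike time substituted for silent output neurons in the
#'   loss; defaults to `latency + 2` (twice the encoding interval past the
#'   latest target).
#' @return an object of class `train_config`.
#' @export
train_config <- function(latency = 1,
                         learning_rate = 0.0016762843980764315,
                         learning_rate_pulses = 0.0014413603337483233,
                         batch_size = 3,
                         clip_derivative = 247.36488789120077,
                         penalty_no_spike = 33.83286251355259,
                         epochs = 100,
                         nonpulse_init_multiplier = -9.533865719823941,
                         pulse_init_multiplier = -8.08055538136939,
                         seed = 0,
                         surrogate = NULL) {
  stopifnot(latency >= 0, learning_rate > 0, learning_rate_pulses > 0,
            batch_size >= 1, clip_derivative > 0, penalty_no_spike >= 0,
            epochs >= 1)
  if (is.null(surrogate)) surrogate <- latency + 2
  structure(list(latency = latency,
                 learning_rate = learning_rate,
                 learning_rate_pulses = learning_rate_pulses,
                 batch_size = as.integer(batch_size),
                 clip_derivative = clip_derivative,
                 penalty_no_spike = penalty_no_spike,
                 epochs = as.integer(epochs),
                 nonpulse_init_multiplier = nonpulse_init_multiplier,
                 pulse_init_multiplier = pulse_init_multiplier,
                 seed = as.integer(seed),
                 surrogate = surrogate),
            class = "train_config")
}

#' Tuned long-latency (l = 16) training configuration
#'
#' The operating point for large target latencies, where regular connections
#' initialise inhibitory and pulses strongly excitatory: batch 27, clip
#' 373.38, penalty 39.56, weight learning rate 3.852e-4, pulse learning rate
#' 0.133, multipliers -6.97 / +9.98. Pair it with
#' `model_params(tau = 0.28781361955998486, theta = 0.9063259346518524)` and
#' 8 pulses per layer.
#'
#' @param latency target latency (default 16).
#' @param ... overrides passed to [train_config].
#' @return a [train_config].
#' @export
train_config_l16 <- function(latency = 16, ...) {
  defaults <- list(latency = latency,
                   learning_rate = 0.00038521130189147893,
                   learning_rate_pulses = 0.13300674961971326,
                   batch_size = 27,
                   clip_derivative = 373.3754658744521,
                   penalty_no_spike = 39.560790380375444,
                   nonpulse_init_multiplier = -6.971635832107275,
                   pulse_init_multiplier = 9.978394158917038)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(train_config, defaults)
}

#' Latency-targeted squared-error loss
#'
#' The reconstruction target for an input pixel spiking at t is an output
#' spike at t + l, so the loss is \eqn{\sum_i (\tilde t_i - t_i - l)^2} over
#' informative pixels. Input pixels with [NO_SPIKE] (white, carrying no
#' information) are excluded from the sum; silent output neurons enter with
#' the surrogate spike time.
#'
#' @param input clean target spike vector (the encoded clean image).
#' @param output network output spike vector (may contain [NO_SPIKE]).
#' @param l target latency.
#' @param surrogate value substituted for silent outputs.
#' @return the summed squared latency error (a single non-negative number).
#' @examples
#' latency_loss(input = 0.3, output = 1.5, l = 1, surrogate = 3)  # 0.04
#' @export
latency_loss <- function(input, output, l, surrogate = l + 2) {
  if (length(input) != length(output)) {
    stop("input and output spike vectors must have the same length")
  }
  keep <- is.finite(input)
  if (!any(keep)) return(0)
  t_eff <- ifelse(is.finite(output), output, surrogate)
  sum((t_eff[keep] - input[keep] - l)^2)
}

#' Initialise Adam optimiser state for a network
#'
#' @param network a [spike_network].
#' @return an `adam_state`: zeroed first/second moments mirroring every
#'   weight matrix and pulse-time vector, and a step counter.
#' @export
adam_init <- function(network) {
  stopifnot(inherits(network, "spike_network"))
  layers <- lapply(network$layers, function(l) {
    list(m_w = array(0, dim(l$weights)), v_w = array(0, dim(l$weights)),
         m_p = numeric(length(l$pulse_times)),
         v_p = numeric(length(l$pulse_times)))
  })
  structure(list(layers = layers, step = 0L), class = "adam_state")
}

#' One Adam update step
#'
#' Standard Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) with separate
#' learning rates for weights and pulse times. Pulse times are clamped to
#' be non-negative after the update (spike times are non-negative by
#' definition).
#'
#' @param network a [spike_network].
#' @param grads a `gradient_bundle` (from [backprop], or a batch average).
#' @param state an `adam_state` from [adam_init].
#' @param config a [train_config].
#' @return list with the updated `network` and `state`.
#' @export
adam_step <- function(network, grads, state, config,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(inherits(network, "spike_network"),
            inherits(grads, "gradient_bundle"),
            inherits(state, "adam_state"),
            inherits(config, "train_config"))
  t <- state$step + 1L
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in seq_along(network$layers)) {
    g <- grads$layers[[l]]
    s <- state$layers[[l]]
    s$m_w <- beta1 * s$m_w + (1 - beta1) * g$d_weights
    s$v_w <- beta2 * s$v_w + (1 - beta2) * g$d_weights^2
    network$layers[[l]]$weights <- network$layers[[l]]$weights -
      config$learning_rate * (s$m_w / bc1) / (sqrt(s$v_w / bc2) + eps)
    if (length(g$d_pulse_times) > 0) {
      s$m_p <- beta1 * s$m_p + (1 - beta1) * g$d_pulse_times
      s$v_p <- beta2 * s$v_p + (1 - beta2) * g$d_pulse_times^2
      pt <- network$layers[[l]]$pulse_times -
        config$learning_rate_pulses * (s$m_p / bc1) / (sqrt(s$v_p / bc2) + eps)
      network$layers[[l]]$pulse_times <- pmax(pt, 0)
    }
    state$layers[[l]] <- s
  }
  state$step <- t
  list(network = network, state = state)
}

# zero-shaped gradient bundle for accumulation
.zero_grads <- function(network) {
  layers <- lapply(network$layers, function(l) {
    list(d_weights = array(0, dim(l$weights)),
         d_pulse_times = numeric(length(l$pulse_times)))
  })
  structure(list(layers = layers), class = "gradient_bundle")
}

.add_grads <- function(a, b, scale = 1) {
  for (l in seq_along(a$layers)) {
    a$layers[[l]]$d_weights <- a$layers[[l]]$d_weights +
      scale * b$layers[[l]]$d_weights
    a$layers[[l]]$d_pulse_times <- a$layers[[l]]$d_pulse_times +
      scale * b$layers[[l]]$d_pulse_times
  }
  a
}

#' Train a latency-coded spiking autoencoder
#'
#' Mini-batch gradient descent on the latency loss with Adam. Each epoch the
#' training pairs are reshuffled (deterministically under the config seed),
#' per-example gradients from [backprop] are averaged over each batch, and
#' one [adam_step] is applied per batch. For denoising, feed noisy spike
#' vectors as `inputs` and the clean encodings as `targets`; for plain
#' reconstruction pass the same matrix twice.
#'
#' @param spec a [network_spec] (a fresh network is initialised from it with
#'   the config's multipliers and seed), or an existing [spike_network] to
#'   continue training.
#' @param inputs numeric matrix, one row per example, one column per input
#'   neuron (entries are spike times; [NO_SPIKE] allowed).
#' @param targets matrix of clean target spike vectors, same shape.
#' @param config a [train_config].
#' @return list with `network` (trained), `history` (data.frame of
#'   epoch and mean per-example train loss), and `config`.
#' @export
train_autoencoder <- function(spec, inputs, targets, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  if (nrow(inputs) == 0) stop("empty dataset")
  if (!all(dim(inputs) == dim(targets))) {
    stop("inputs and targets must have identical dimensions")
  }
  if (inherits(spec, "network_spec")) {
    network <- init_network(spec,
                            nonpulse_multiplier = config$nonpulse_init_multiplier,
                            pulse_multiplier = config$pulse_init_multiplier,
                            seed = config$seed)
  } else if (inherits(spec, "spike_network")) {
    network <- spec
  } else {
    stop("`spec` must be a network_spec or spike_network")
  }
  n <- nrow(inputs)
  state <- adam_init(network)
  set.seed(config$seed + 1L)   # epoch shuffling stream
  history <- data.frame(epoch = integer(0), mean_train_loss = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    b0 <- 1L
    while (b0 <= n) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      acc <- .zero_grads(network)
      for (i in idx) {
        tr <- forward_pass(network, inputs[i, ])
        bp <- backprop(network, tr, targets[i, ], config)
        epoch_loss <- epoch_loss + bp$loss
        acc <- .add_grads(acc, bp$grads, scale = 1 / length(idx))
      }
      st <- adam_step(network, acc, state, config)
      network <- st$network
      state <- st$state
      b0 <- b0 + config$batch_size
    }
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                mean_train_loss = epoch_loss / n))
  }
  list(network = network, history = history, config = config)
}
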