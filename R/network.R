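#' Network architecture specification
#'
#' Describes a feedforward latency-coded network: layer sizes, the number of
#' learnable synchronisation pulses feeding each non-input layer, and the
#' shared neuron model parameters. The autoencoder convention is an
#' input-hidden-output stack where the output size equals the input size and
#' the hidden (embedding) layer is smaller, but any depth is accepted.
#'
#' @param layer_sizes integer vector of layer sizes (input, hidden..., output),
#'   at least two layers.
#' @param n_pulses number of synchronisation pulses per non-input layer;
#'   a scalar (recycled) or one value per non-input layer.
#' @param params a [model_params] object shared by all neurons.
#' @return an object of class `network_spec`.
#' @examples
#' network_spec(c(64, 4, 64), n_pulses = 10, params = model_params(0.3, 0.8))
#' @export
network_spec <- function(layer_sizes, n_pulses, params) {
  stopifnot(inherits(params, "model_params"))
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    stop("`layer_sizes` must contain at least two positive sizes")
  }
  n_layers <- length(layer_sizes) - 1L
  n_pulses <- as.integer(n_pulses)
  if (any(n_pulses < 0)) stop("`n_pulses` must be non-negative")
  if (length(n_pulses) == 1L) n_pulses <- rep(n_pulses, n_layers)
  if (length(n_pulses) != n_layers) {
    stop("`n_pulses` must be a scalar or one value per non-input layer")
  }
  structure(list(layer_sizes = layer_sizes, n_pulses = n_pulses,
                 params = params),
            class = "network_spec")
}

#' Autoencoder specification with the reference hyperparameters
#'
#' Convenience constructor for the three-layer autoencoder
#' (pixels - hidden - pixels). Defaults for the neuron model and pulse count
#' are the tuned short-latency (l = 1) operating point: tau = 0.3139,
#' theta = 0.8012, 10 pulses per layer.
#'
#' @param n_pixels input (and output) layer size.
#' @param hidden embedding layer size.
#' @param n_pulses pulses per non-input layer.
#' @param params a [model_params] object.
#' @return a [network_spec].
#' @export
autoencoder_spec <- function(n_pixels, hidden, n_pulses = 10,
                             params = model_params(tau = 0.3138976904122206,
                                                   theta = 0.8011900124783229)) {
  network_spec(c(n_pixels, hidden, n_pixels), n_pulses = n_pulses,
               params = params)
}

#' Evenly spaced initial pulse times
#'
#' Pulses are initialised evenly over the input interval: inclusive of both
#' endpoints for two or more pulses, at the midpoint for a single pulse.
#'
#' @param n_pulses number of pulses (non-negative).
#' @param interval length-2 numeric, the encoding interval (default `[0, 1]`).
#' @return numeric vector of `n_pulses` initial spike times.
#' @examples
#' init_pulses(3)  # 0, 0.5, 1
#' init_pulses(1)  # 0.5
#' @export
init_pulses <- function(n_pulses, interval = c(0, 1)) {
  if (length(n_pulses) != 1 || is.na(n_pulses) || n_pulses < 0) {
    stop("`n_pulses` must be a non-negative integer")
  }
  n_pulses <- as.integer(n_pulses)
  if (n_pulses == 0L) return(numeric(0))
  if (n_pulses == 1L) return(mean(interval))
  seq(interval[1], interval[2], length.out = n_pulses)
}

#' Initialise a network with shifted Glorot weights
#'
#' Weights are drawn from Normal(mu, sigma) with
#' sigma = sqrt(2 / (fan_in + fan_out)) and mu = multiplier * sigma — Glorot
#' scaling with a tunable mean shift. Connections from regular inputs and
#' from pulses use separate multipliers (a strongly negative regular
#' multiplier seeds inhibition; a positive pulse multiplier seeds excitatory
#' triggers). fan_in counts pulse connections, since pulses enter the same
#' weighted sum.
#'
#' @param spec a [network_spec].
#' @param nonpulse_multiplier mean shift (in units of sigma) for regular
#'   connections.
#' @param pulse_multiplier mean shift for pulse connections.
#' @param seed integer RNG seed; the same seed reproduces the network exactly.
#' @param pulse_interval interval over which initial pulse times are spread.
#' @return an object of class `spike_network`: the spec plus per-layer
#'   weight matrices of shape (n_inputs + n_pulses) x n_outputs and pulse
#'   time vectors.
#' @export
init_network <- function(spec, nonpulse_multiplier = 0, pulse_multiplier = 0,
                         seed = 0, pulse_interval = c(0, 1)) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(as.integer(seed))
  sizes <- spec$layer_sizes
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    n_in <- sizes[l]
    n_out <- sizes[l + 1L]
    p <- spec$n_pulses[l]
    fan_in <- n_in + p
    sigma <- sqrt(2 / (fan_in + n_out))
    w_reg <- matrix(rnorm(n_in * n_out, mean = nonpulse_multiplier * sigma,
                          sd = sigma), n_in, n_out)
    w_pul <- if (p > 0) {
      matrix(rnorm(p * n_out, mean = pulse_multiplier * sigma, sd = sigma),
             p, n_out)
    } else {
      matrix(numeric(0), 0, n_out)
    }
    layers[[l]] <- list(weights = rbind(w_reg, w_pul),
                        pulse_times = init_pulses(p, pulse_interval))
  }
  structure(list(spec = spec, layers = layers), class = "spike_network")
}

#' @export
print.spike_network <- function(x, ...) {
  cat("Latency-coded spiking network:",
      paste(x$spec$layer_sizes, collapse = " - "),
      "(", paste(x$spec$n_pulses, collapse = "/"), "pulses per layer )\n")
  cat("  tau =", x$spec$params$tau, ", theta =", x$spec$params$theta,
      ",", param_count(x$spec), "learnable parameters\n")
  invisible(x)
}

#' Number of learnable parameters
#'
#' Counts every learnable scalar: all weights (regular and pulse
#' connections) plus the pulse spike times. For a three-layer i-h-o network
#' with p pulses per non-input layer this is (i+p)h + (h+p)o + 2p.
#'
#' @param spec a [network_spec].
#' @return integer parameter count.
#' @examples
#' sp <- autoencoder_spec(784, 32, n_pulses = 10)
#' param_count(sp)  # 58356
#' @export
param_count <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- spec$layer_sizes
  n <- length(sizes) - 1L
  total <- 0L
  for (l in seq_len(n)) {
    total <- total + (sizes[l] + spec$n_pulses[l]) * sizes[l + 1L] +
      spec$n_pulses[l]
  }
  as.integer(total)
}

#' Forward pass through a latency-coded network
#'
#' Each non-input layer receives the previous layer's spike times
#' concatenated with its own pulse times, and every neuron's spike is the
#' event-based closed-form solution over that input train with the neuron's
#' weight column. [NO_SPIKE] outputs propagate downstream as absent inputs.
#'
#' @param network a [spike_network] (from [init_network] or training).
#' @param input numeric spike vector of length equal to the input layer.
#' @return an object of class `forward_trace`: `spikes` (list of per-layer
#'   spike-time vectors, input first) and `layers` (per non-input layer, the
#'   cached solver state reused by [backprop]: input times, output times,
#'   Lambert W values, causal sums and the shifted-frame reference).
#' @export
forward_pass <- function(network, input) {
  stopifnot(inherits(network, "spike_network"))
  sizes <- network$spec$layer_sizes
  if (length(input) != sizes[1]) {
    stop("input length ", length(input), " does not match input layer size ",
         sizes[1])
  }
  params <- network$spec$params
  spikes <- vector("list", length(sizes))
  spikes[[1]] <- as.numeric(input)
  layer_state <- vector("list", length(sizes) - 1L)
  for (l in seq_along(network$layers)) {
    lay <- network$layers[[l]]
    in_times <- c(spikes[[l]], lay$pulse_times)
    if (nrow(lay$weights) != length(in_times)) {
      stop("layer ", l, " weight matrix does not match its inputs")
    }
    sol <- .layer_forward(in_times, lay$weights, params)
    spikes[[l + 1L]] <- sol$time
    layer_state[[l]] <- list(in_times = in_times, out_times = sol$time,
                             lambert_w = sol$lambert_w, A = sol$A, B = sol$B,
                             t_ref = sol$t_ref)
  }
  structure(list(spikes = spikes, layers = layer_state),
            class = "forward_trace")
}

#' Save a trained network to a self-describing JSON file
#'
#' Stores the architecture, neuron model, all weights, pulse times and
#' (optionally) the training configuration at full double precision
#' (17 significant digits), so that [load_network] is bit-exact.
#'
#' @param network a [spike_network].
#' @param path output file path.
#' @param config optional [train_config] to embed.
#' @return `path`, invisibly.
#' @export
save_network <- function(network, path, config = NULL) {
  stopifnot(inherits(network, "spike_network"))
  spec <- network$spec
  obj <- list(
    format = "spikelat-network",
    version = 1L,
    layer_sizes = spec$layer_sizes,
    n_pulses = spec$n_pulses,
    tau = spec$params$tau,
    theta = spec$params$theta,
    layers = lapply(network$layers, function(l) {
      list(weights = as.numeric(l$weights), dim = dim(l$weights),
           pulse_times = as.numeric(l$pulse_times))
    }),
    train_config = if (!is.null(config)) unclass(config) else NULL
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a network saved by [save_network]
#'
#' @param path file written by [save_network].
#' @return a [spike_network]; if a training configuration was embedded it is
#'   attached as attribute `"train_config"`.
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "spikelat-network")) {
    stop("not a spikelat network file: ", path)
  }
  spec <- network_spec(obj$layer_sizes, obj$n_pulses,
                       model_params(obj$tau, obj$theta))
  layers <- lapply(seq_along(obj$layers$dim), function(i) NULL)
  # jsonlite simplifies the list of layers into parallel lists
  n_layers <- length(spec$layer_sizes) - 1L
  raw_layers <- if (is.data.frame(obj$layers)) {
    lapply(seq_len(nrow(obj$layers)), function(i) as.list(obj$layers[i, ]))
  } else {
    obj$layers
  }
  layers <- lapply(seq_len(n_layers), function(i) {
    l <- raw_layers[[i]]
    w <- matrix(unlist(l$weights), unlist(l$dim)[1], unlist(l$dim)[2])
    list(weights = w, pulse_times = as.numeric(unlist(l$pulse_times)))
  })
  net <- structure(list(spec = spec, layers = layers),
                   class = "spike_network")
  if (!is.null(obj$train_config)) {
    attr(net, "train_config") <- obj$train_config
  }
  net
}
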