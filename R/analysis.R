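#' Mean reconstruction error over a dataset
#'
#' Runs the network on every input, evaluates the latency loss against the
#' clean target, and normalises per informative (spiking) target pixel, so
#' the value is comparable across images with different stroke sizes.
#'
#' @param network a trained [spike_network].
#' @param inputs matrix of (possibly noisy) input spike vectors, one row per
#'   example.
#' @param targets matrix of clean target spike vectors.
#' @param config the [train_config] used in training (provides latency and
#'   surrogate).
#' @return mean per-spiking-pixel squared latency error (a single number).
#' @export
reconstruction_error <- function(network, inputs, targets, config) {
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  if (nrow(inputs) == 0) stop("empty dataset")
  stopifnot(all(dim(inputs) == dim(targets)))
  per <- vapply(seq_len(nrow(inputs)), function(i) {
    tr <- forward_pass(network, inputs[i, ])
    out <- tr$spikes[[length(tr$spikes)]]
    n_inf <- sum(is.finite(targets[i, ]))
    if (n_inf == 0) return(0)
    latency_loss(targets[i, ], out, l = config$latency,
                 surrogate = config$surrogate) / n_inf
  }, numeric(1))
  mean(per)
}

#' Spike-time distributions per layer
#'
#' Collects every spike emitted by each non-input layer over a dataset into
#' a common set of histogram bins, alongside each layer's current pulse
#' times. Silent neurons contribute no counts, so the histogram total equals
#' the number of spikes emitted.
#'
#' @param network a [spike_network].
#' @param inputs matrix of input spike vectors, one row per example.
#' @param breaks number of histogram bins (spread over the observed range).
#' @return list with one element per non-input layer: `counts`, `breaks`
#'   (bin edges), `n_spikes`, `n_silent`, and `pulse_times`; plus an
#'   `input` element summarising the input layer the same way.
#' @export
spike_distribution <- function(network, inputs, breaks = 20) {
  inputs <- as.matrix(inputs)
  n_layers <- length(network$layers)
  times <- vector("list", n_layers + 1L)
  times[[1]] <- as.numeric(inputs)
  for (i in seq_len(nrow(inputs))) {
    tr <- forward_pass(network, inputs[i, ])
    for (l in seq_len(n_layers)) {
      times[[l + 1L]] <- c(times[[l + 1L]], tr$spikes[[l + 1L]])
    }
  }
  all_fin <- unlist(lapply(times, function(t) t[is.finite(t)]))
  rng <- if (length(all_fin)) range(all_fin) else c(0, 1)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  edges <- seq(rng[1], rng[2], length.out = breaks + 1)
  summarise <- function(t, pulses) {
    fin <- t[is.finite(t)]
    counts <- if (length(fin)) {
      hist(fin, breaks = edges, plot = FALSE)$counts
    } else {
      integer(breaks)
    }
    list(counts = counts, breaks = edges, n_spikes = length(fin),
         n_silent = sum(!is.finite(t)), pulse_times = pulses)
  }
  out <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    out[[l]] <- summarise(times[[l + 1L]], network$layers[[l]]$pulse_times)
  }
  names(out) <- paste0("layer", seq_len(n_layers))
  c(list(input = summarise(times[[1]], numeric(0))), out)
}

#' Weight summaries split by connection class
#'
#' Per layer, summarises regular-input connections and pulse connections
#' separately: mean, standard deviation and the 10/50/90 percent quantiles.
#' This is the summary behind the inhibition analysis — trained
#' long-latency autoencoders show negative mean regular weights and positive
#' mean pulse weights.
#'
#' @param network a [spike_network].
#' @return data.frame with columns layer, class ("regular"/"pulse"), n,
#'   mean, sd, q10, q50, q90.
#' @export
weight_distribution <- function(network) {
  stopifnot(inherits(network, "spike_network"))
  sizes <- network$spec$layer_sizes
  rows <- list()
  for (l in seq_along(network$layers)) {
    W <- network$layers[[l]]$weights
    n_reg <- sizes[l]
    p <- network$spec$n_pulses[l]
    groups <- list(regular = W[seq_len(n_reg), , drop = FALSE])
    if (p > 0) groups$pulse <- W[n_reg + seq_len(p), , drop = FALSE]
    for (cls in names(groups)) {
      w <- as.numeric(groups[[cls]])
      q <- quantile(w, c(0.1, 0.5, 0.9), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = l, class = cls, n = length(w), mean = mean(w),
        sd = stats::sd(w), q10 = q[1], q50 = q[2], q90 = q[3])
    }
  }
  do.call(rbind, rows)
}

#' Hidden-layer embeddings of a dataset
#'
#' One row per example, one column per hidden (embedding) neuron, entries
#' are the hidden spike times. Silent hidden neurons are exported as `Inf`
#' (the [NO_SPIKE] sentinel); CSV written by the CLI carries the same
#' convention, documented in its header comment.
#'
#' @param network a [spike_network].
#' @param inputs matrix of input spike vectors.
#' @param layer which non-input layer to read out (default 1, the encoder).
#' @return numeric matrix of spike times, `nrow(inputs)` x layer size.
#' @export
embed_dataset <- function(network, inputs, layer = 1) {
  inputs <- as.matrix(inputs)
  t(vapply(seq_len(nrow(inputs)), function(i) {
    tr <- forward_pass(network, inputs[i, ])
    tr$spikes[[layer + 1L]]
  }, numeric(network$spec$layer_sizes[layer + 1L])))
}

#' Decode an embedding through the remaining layers
#'
#' Feeds a vector of hidden spike times through the layers after the
#' embedding layer and decodes the output spikes to pixel values. Used e.g.
#' to decode convex combinations of two embeddings (latent interpolation).
#'
#' @param network a [spike_network].
#' @param hidden numeric vector of hidden spike times (length of layer
#'   `layer`'s output; may contain [NO_SPIKE]).
#' @param l target latency used for decoding.
#' @param invert undo brightness inversion for display.
#' @param layer the embedding layer index (default 1).
#' @return pixel values in `[0, 1]`.
#' @export
decode_embedding <- function(network, hidden, l, invert = TRUE, layer = 1) {
  stopifnot(inherits(network, "spike_network"))
  sizes <- network$spec$layer_sizes
  if (length(hidden) != sizes[layer + 1L]) {
    stop("embedding length does not match layer ", layer + 1L)
  }
  spikes <- as.numeric(hidden)
  params <- network$spec$params
  for (lix in (layer + 1L):length(network$layers)) {
    lay <- network$layers[[lix]]
    in_times <- c(spikes, lay$pulse_times)
    spikes <- .layer_forward(in_times, lay$weights, params)$time
  }
  decode_spikes(spikes, l = l, invert = invert)
}
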