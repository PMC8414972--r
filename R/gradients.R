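# Exact spike-time derivatives and backpropagation.
#
# For a spiking neuron with causal sums A, B and cached Lambert value
# W = W0(-tau*theta/A * exp(tau*B/A)), the spike time differentiates in
# closed form with respect to each causal input time and weight. Both
# partials share the denominator A(1+W), which vanishes when the membrane
# potential is tangent to the threshold — hence the clipping.

# shared guard: partial values near tangency are replaced by their
# clipped sign value
.tangency_guard <- function(num, denom_small, clip) {
  sign(num) * clip
}

#' Exact derivative of a spike time with respect to a causal input time
#'
#' \deqn{\partial t_{out} / \partial t_j =
#'   w_j e^{\tau t_j} (\tau (t_j - B/A) + W + 1) / (A (1 + W))}
#' with W the cached principal-branch Lambert value of the solution. Defined
#' only for causal inputs (those spiking strictly before the output); the
#' caller must mask non-causal inputs to zero.
#'
#' @param solution a `spike_solution` from [simulate_neuron] with a finite
#'   spike time.
#' @param input_time spike time of the causal input (absolute frame).
#' @param input_weight weight of that input connection.
#' @param params a [model_params].
#' @param clip clipping bound applied near threshold tangency
#'   (`|1 + W| < 1e-6`), where the exact partial diverges.
#' @return the partial derivative (a single number).
#' @export
d_spike_d_input <- function(solution, input_time, input_weight, params,
                            clip = Inf) {
  stopifnot(inherits(solution, "spike_solution"),
            inherits(params, "model_params"))
  if (!is.finite(solution$time)) stop("solution has no spike")
  if (!(input_time < solution$time)) {
    stop("input at t = ", input_time, " is not causal for a spike at t = ",
         solution$time, "; the caller must mask non-causal inputs")
  }
  tau <- params$tau
  ts <- input_time - solution$t_ref  # same frame as the stored A, B
  W <- solution$lambert_w
  A <- solution$A; B <- solution$B
  num <- input_weight * exp(tau * ts) * (tau * (ts - B / A) + W + 1)
  if (abs(1 + W) < 1e-6) return(.tangency_guard(num, TRUE, clip))
  val <- num / (A * (1 + W))
  max(-clip, min(clip, val))
}

#' Exact derivative of a spike time with respect to an input weight
#'
#' \deqn{\partial t_{out} / \partial w_j =
#'   e^{\tau t_j} (t_j - B/A + W/\tau) / (A (1 + W))}
#' Same causality and tangency rules as [d_spike_d_input].
#'
#' @inheritParams d_spike_d_input
#' @return the partial derivative (a single number).
#' @export
d_spike_d_weight <- function(solution, input_time, params, clip = Inf) {
  stopifnot(inherits(solution, "spike_solution"),
            inherits(params, "model_params"))
  if (!is.finite(solution$time)) stop("solution has no spike")
  if (!(input_time < solution$time)) {
    stop("input at t = ", input_time, " is not causal for a spike at t = ",
         solution$time, "; the caller must mask non-causal inputs")
  }
  tau <- params$tau
  ts <- input_time - solution$t_ref
  W <- solution$lambert_w
  A <- solution$A; B <- solution$B
  num <- exp(tau * ts) * (ts - B / A + W / tau)
  if (abs(1 + W) < 1e-6) return(.tangency_guard(num, TRUE, clip))
  val <- num / (A * (1 + W))
  max(-clip, min(clip, val))
}

# Vectorised per-layer partials. st: shifted input times (length n, Inf for
# absent), state: one layer's forward cache, W_mat: n x m weights.
# Returns list(d_in = n x m matrix of dt_out/dt_in, d_w = n x m matrix of
# dt_out/dw), already causality-masked and clipped.
.layer_partials <- function(state, W_mat, params, clip) {
  tau <- params$tau
  n <- length(state$in_times)
  m <- length(state$out_times)
  d_in <- matrix(0, n, m)
  d_w <- matrix(0, n, m)
  spiking <- which(is.finite(state$out_times))
  if (length(spiking) == 0) return(list(d_in = d_in, d_w = d_w))
  ts <- state$in_times - state$t_ref           # shifted frame of A, B
  fin <- is.finite(state$in_times)
  E <- ifelse(fin, exp(tau * ts), 0)
  for (j in spiking) {
    causal <- fin & (state$in_times < state$out_times[j])  # strict mask
    if (!any(causal)) next
    A <- state$A[j]; B <- state$B[j]; W <- state$lambert_w[j]
    i <- which(causal)
    num_in <- W_mat[i, j] * E[i] * (tau * (ts[i] - B / A) + W + 1)
    num_w <- E[i] * (ts[i] - B / A + W / tau)
    if (abs(1 + W) < 1e-6) {
      d_in[i, j] <- sign(num_in) * clip
      d_w[i, j] <- sign(num_w) * clip
    } else {
      denom <- A * (1 + W)
      d_in[i, j] <- pmax(-clip, pmin(clip, num_in / denom))
      d_w[i, j] <- pmax(-clip, pmin(clip, num_w / denom))
    }
  }
  list(d_in = d_in, d_w = d_w)
}

#' Backpropagation with exact spike-time derivatives
#'
#' Seeds the output layer with the latency-loss adjoints
#' \eqn{2 (\tilde t_i - t_i - l)} and chains them backwards through the
#' network using the exact partials of each spike time with respect to its
#' causal input times and weights. Inputs spiking at or after a neuron's
#' spike get exactly zero contribution. Every partial is clamped to
#' `[-clip, +clip]` at evaluation. A neuron that does not spike receives
#' `-penalty_no_spike` on each of its incoming weight gradients (pushing the
#' weights up so it starts spiking) and passes nothing upstream; non-spiking
#' output neurons enter the loss through the surrogate spike time. Pulse-time
#' gradients accumulate the input-time partials over every neuron the pulse
#' feeds.
#'
#' @param network the [spike_network] that produced `trace`.
#' @param trace a [forward_pass] trace of one example.
#' @param target clean target spike vector (one entry per output neuron);
#'   pixels whose target is [NO_SPIKE] carry no information and are excluded
#'   from the loss.
#' @param config a [train_config] (provides the target latency, surrogate
#'   spike time, clip bound and no-spike penalty).
#' @return list with `loss` (the summed squared latency error of this
#'   example) and `grads`, a `gradient_bundle`: per layer, `d_weights`
#'   (same shape as the weight matrix) and `d_pulse_times`.
#' @export
backprop <- function(network, trace, target, config) {
  stopifnot(inherits(network, "spike_network"),
            inherits(trace, "forward_trace"),
            inherits(config, "train_config"))
  sizes <- network$spec$layer_sizes
  n_out <- sizes[length(sizes)]
  if (length(target) != n_out) {
    stop("target length ", length(target), " does not match output layer (",
         n_out, ")")
  }
  params <- network$spec$params
  clip <- config$clip_derivative
  penalty <- config$penalty_no_spike
  l <- config$latency
  surrogate <- config$surrogate

  out_times <- trace$spikes[[length(trace$spikes)]]
  loss <- latency_loss(target, out_times, l = l, surrogate = surrogate)

  included <- is.finite(target)
  t_eff <- ifelse(is.finite(out_times), out_times, surrogate)
  adj_out <- ifelse(included, 2 * (t_eff - target - l), 0)
  # no-spike outputs reach the loss only through the constant surrogate:
  # their adjoint cannot flow through a spike-time derivative
  adj_out[!is.finite(out_times)] <- 0

  n_layers <- length(network$layers)
  grads <- vector("list", n_layers)
  adj <- adj_out
  for (lix in rev(seq_len(n_layers))) {
    state <- trace$layers[[lix]]
    W_mat <- network$layers[[lix]]$weights
    p <- network$spec$n_pulses[lix]
    n_reg <- sizes[lix]
    parts <- .layer_partials(state, W_mat, params, clip)
    dW <- sweep(parts$d_w, 2, adj, `*`)
    # no-spike penalty on every incoming weight of a silent neuron
    silent <- !is.finite(state$out_times)
    if (any(silent) && penalty > 0) {
      dW[, silent] <- dW[, silent] - min(penalty, clip)
    }
    d_in_adj <- parts$d_in %*% adj     # adjoints for this layer's inputs
    d_pulse <- if (p > 0) {
      as.numeric(d_in_adj[n_reg + seq_len(p)])
    } else {
      numeric(0)
    }
    grads[[lix]] <- list(d_weights = dW, d_pulse_times = d_pulse)
    adj <- as.numeric(d_in_adj[seq_len(n_reg)])
  }
  list(loss = loss,
       grads = structure(list(layers = grads), class = "gradient_bundle"))
}
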