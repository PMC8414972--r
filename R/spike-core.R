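#' @importFrom stats rnorm runif quantile
#' @importFrom graphics hist
#' @importFrom utils write.csv head
NULL

#' The "no spike" sentinel
#'
#' Neurons that never reach threshold are represented by a spike time of
#' `Inf`: it compares later than any finite time, so ordering, causal-set
#' masks, and "earliest spike" logic all work with ordinary comparisons.
#' @export
NO_SPIKE <- Inf

#' Test which entries of a spike vector are actual spikes
#' @param times numeric vector of spike times (may contain [NO_SPIKE]).
#' @return logical vector, `TRUE` where a finite spike time is present.
#' @export
is_spiking <- function(times) is.finite(times)

#' Global neuron model parameters
#'
#' The decay rate \eqn{\tau} and firing threshold \eqn{\theta} are shared by
#' every neuron in a network.
#'
#' @param tau positive decay rate constant of the alpha synaptic kernel
#'   (1/time units); scales the kernel in intensity and time.
#' @param theta positive firing threshold on the membrane potential.
#' @return an object of class `model_params`.
#' @examples
#' model_params(tau = 1, theta = 0.5)
#' @export
model_params <- function(tau, theta) {
  stopifnot(is.numeric(tau), length(tau) == 1, is.finite(tau),
            is.numeric(theta), length(theta) == 1, is.finite(theta))
  if (tau <= 0) stop("`tau` must be positive")
  if (theta <= 0) stop("`theta` must be positive")
  structure(list(tau = tau, theta = theta), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Spiking neuron model: tau =", x$tau, ", theta =", x$theta, "\n")
  invisible(x)
}

#' Membrane potential of an alpha-synapse neuron
#'
#' Each input spike at time \eqn{t_i} with weight \eqn{w_i} contributes an
#' alpha-function kernel \eqn{w_i (t - t_i) e^{\tau (t_i - t)}} for
#' \eqn{t \ge t_i}; inputs that have not yet arrived (and [NO_SPIKE] inputs)
#' contribute zero. The potential is the sum of kernels, valid up to the
#' neuron's own (first) spike.
#'
#' @param t evaluation time(s); must be finite.
#' @param times input spike times (may contain [NO_SPIKE]).
#' @param weights synaptic weights, aligned 1:1 with `times`.
#' @param params a [model_params] object.
#' @return numeric vector of potentials, one per entry of `t`.
#' @examples
#' p <- model_params(tau = 1, theta = 0.5)
#' membrane_potential(2, times = 1, weights = 0.5, params = p)  # 0.5 * exp(-1)
#' @export
membrane_potential <- function(t, times, weights, params) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric")
  }
  if (length(times) != length(weights)) {
    stop("`times` and `weights` must have the same length")
  }
  fin <- is.finite(times)
  ti <- times[fin]; wi <- weights[fin]
  vapply(t, function(tt) {
    act <- ti <= tt
    sum(wi[act] * (tt - ti[act]) * exp(params$tau * (ti[act] - tt)))
  }, numeric(1))
}

#' Closed-form threshold-crossing time from causal sums
#'
#' Given the causal sums \eqn{A = \sum_i w_i e^{\tau t_i}} and
#' \eqn{B = \sum_i w_i e^{\tau t_i} t_i} over a candidate causal input set,
#' the earliest time at which the membrane potential reaches the threshold is
#' \deqn{t_{out} = B/A - \frac{1}{\tau} W_0\!\left(-\frac{\tau\theta}{A}
#'   e^{\tau B / A}\right)}
#' on the principal branch of the Lambert W function (the ascending crossing;
#' the other branch is the descending one).
#'
#' @param A,B causal sums (same time frame as the desired output).
#' @param params a [model_params] object.
#' @param branch_tol Lambert arguments within this distance below \eqn{-1/e}
#'   are treated as an exact tangency.
#' @return `NULL` when the threshold is unreachable for this causal set
#'   (`A <= 0`, or Lambert argument below \eqn{-1/e}); otherwise a list with
#'   `time` (the crossing) and `lambert_w` (the cached \eqn{W_0} value, reused
#'   by the exact derivatives).
#' @examples
#' p <- model_params(tau = 1, theta = exp(-1))
#' # single input at t=0, w=1: threshold equals the kernel peak, hit at t=1
#' spike_time_closed_form(A = 1, B = 0, params = p)$time
#' @export
spike_time_closed_form <- function(A, B, params, branch_tol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  if (!is.finite(A) || !is.finite(B)) stop("causal sums must be finite")
  if (A <= 0) return(NULL)   # no positive drive: no ascending crossing
  tau <- params$tau
  arg <- -tau * params$theta / A * exp(tau * B / A)
  if (!is.finite(arg) || arg < -exp(-1) - branch_tol) return(NULL)
  W <- lambert_w0(arg, branch_tol = branch_tol)
  list(time = B / A - W / tau, lambert_w = W)
}

# Vectorised forward solver for one layer: every output neuron shares the
# same input spike train, so the chronological sweep is shared and the
# candidate crossings for all (event, neuron) pairs are solved in one
# Lambert W call. Times are shifted to the latest finite input so that all
# exponents tau*(t_i - t_ref) are <= 0 (no overflow at any latency).
#
# in_times: length-n input spike times (may contain NO_SPIKE)
# W: n x m weight matrix (rows = inputs, cols = output neurons)
# Returns list(time, lambert_w, A, B  (per neuron, shifted frame),
#              t_ref, shifted_times (length n, NO_SPIKE kept as Inf))
.layer_forward <- function(in_times, W, params) {
  n <- length(in_times)
  m <- ncol(W)
  if (nrow(W) != n) stop("weight matrix rows must match number of inputs")
  out <- list(time = rep(NO_SPIKE, m), lambert_w = rep(NA_real_, m),
              A = rep(NA_real_, m), B = rep(NA_real_, m),
              t_ref = 0, shifted_times = rep(Inf, n))
  fin <- which(is.finite(in_times))
  if (length(fin) == 0) return(out)
  tau <- params$tau; theta <- params$theta

  o <- fin[order(in_times[fin])]
  ts <- in_times[o]
  t_ref <- ts[length(ts)]
  tt <- ts - t_ref
  E <- exp(tau * tt)
  Wf <- W[o, , drop = FALSE]
  nf <- length(o)

  # cumulative causal sums per neuron; column-wise cumsum
  WE <- Wf * E
  Acum <- apply(WE, 2, cumsum)
  Bcum <- apply(WE * tt, 2, cumsum)
  if (nf == 1) { Acum <- matrix(Acum, 1); Bcum <- matrix(Bcum, 1) }

  # simultaneous inputs are processed together: only solve at the last
  # member of each tie group
  last_of_tie <- c(tt[-1] != tt[-nf], TRUE)
  tnext <- c(tt[-1], Inf)
  tnext[!last_of_tie] <- NA  # unused rows

  cand_ok <- Acum > 0 & rep(last_of_tie, times = m)
  arg <- matrix(NA_real_, nf, m)
  arg[cand_ok] <- -tau * theta / Acum[cand_ok] *
    exp(tau * Bcum[cand_ok] / Acum[cand_ok])
  dom <- cand_ok & is.finite(arg) & arg >= -exp(-1) - 1e-12
  Wv <- matrix(NA_real_, nf, m)
  Wv[dom] <- lambert_w0(arg[dom])
  cand <- matrix(NA_real_, nf, m)
  cand[dom] <- Bcum[dom] / Acum[dom] - Wv[dom] / tau

  # validity window: t_k <= cand <= t_{k+1}; ties at the upper end accept
  lower_ok <- sweep(cand, 1, tt, `>=`) | abs(sweep(cand, 1, tt, `-`)) < 1e-9
  upper_ok <- sweep(cand, 1, tnext, `<=`)
  valid <- dom & lower_ok & upper_ok
  valid[is.na(valid)] <- FALSE

  for (j in seq_len(m)) {
    k <- which(valid[, j])
    if (length(k) == 0) next
    k <- k[1]
    out$time[j] <- cand[k, j] + t_ref
    out$lambert_w[j] <- Wv[k, j]
    out$A[j] <- Acum[k, j]
    out$B[j] <- Bcum[k, j]
  }
  out$t_ref <- t_ref
  st <- rep(Inf, n)
  st[o] <- tt
  out$shifted_times <- st
  out
}

#' Event-based simulation of a single spiking neuron
#'
#' Processes the input spikes in chronological order (simultaneous inputs
#' together). After each input, the closed-form crossing time for the inputs
#' seen so far is computed; the predicted spike is valid only if it falls
#' between the current input and the next one — a later input arriving before
#' the predicted crossing can delay or abolish it. The first valid crossing
#' is the neuron's (single) spike.
#'
#' @param times input spike times (unsorted allowed; [NO_SPIKE] inputs are
#'   ignored).
#' @param weights synaptic weights, aligned 1:1 with `times`.
#' @param params a [model_params] object.
#' @return an object of class `spike_solution`: a list with `time` (the spike
#'   time, or [NO_SPIKE]), `causal_set` (indices into `times` of inputs
#'   arriving strictly before the spike), `lambert_w`, and the causal sums
#'   `A`, `B` together with the reference time `t_ref` of the internal
#'   shifted frame in which they were computed.
#' @examples
#' p <- model_params(tau = 1, theta = 0.5)
#' sol <- simulate_neuron(times = c(1, 4, 5, 8, 12, 17, 19),
#'                        weights = c(0.5, 0.3, 0.4, -0.2, -0.3, 1.2, 0.9),
#'                        params = p)
#' round(sol$time, 2)  # 19.39
#' @export
simulate_neuron <- function(times, weights, params) {
  stopifnot(inherits(params, "model_params"))
  if (length(times) != length(weights)) {
    stop("`times` and `weights` must have the same length")
  }
  res <- .layer_forward(times, matrix(weights, ncol = 1), params)
  causal <- if (is.finite(res$time[1])) which(times < res$time[1]) else integer(0)
  structure(list(time = res$time[1],
                 causal_set = causal,
                 lambert_w = res$lambert_w[1],
                 A = res$A[1], B = res$B[1],
                 t_ref = res$t_ref),
            class = "spike_solution")
}

#' @export
print.spike_solution <- function(x, ...) {
  if (is.finite(x$time)) {
    cat("Spike at t =", format(x$time), "(", length(x$causal_set),
        "causal inputs )\n")
  } else {
    cat("No spike (threshold not reached)\n")
  }
  invisible(x)
}
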