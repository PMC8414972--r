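# finite-difference reference for a single neuron's spike time
fd_spike <- function(times, weights, params, j, wrt = c("time", "weight"),
                     h = 1e-6) {
  wrt <- match.arg(wrt)
  bump <- function(s) {
    if (wrt == "time") {
      tp <- times; tp[j] <- tp[j] + s
      simulate_neuron(tp, weights, params)$time
    } else {
      wp <- weights; wp[j] <- wp[j] + s
      simulate_neuron(times, wp, params)$time
    }
  }
  (bump(h) - bump(-h)) / (2 * h)
}

test_that("exact partials match central finite differences on random instances", {
  set.seed(404)
  checked <- 0
  while (checked < 200) {
    inst <- random_instance(3:8)
    sol <- simulate_neuron(inst$times, inst$weights, inst$params)
    if (!is.finite(sol$time)) next
    if (abs(1 + sol$lambert_w) < 1e-3) next   # near-tangency excluded
    # keep clear of candidate-window boundaries where FD steps cross events
    if (any(abs(inst$times - sol$time) < 1e-5)) next
    checked <- checked + 1
    for (j in sol$causal_set) {
      an_t <- d_spike_d_input(sol, inst$times[j], inst$weights[j],
                              inst$params)
      fd_t <- fd_spike(inst$times, inst$weights, inst$params, j, "time")
      expect_lt(abs(an_t - fd_t) / max(abs(fd_t), 1e-8), 1e-4)
      an_w <- d_spike_d_weight(sol, inst$times[j], inst$params)
      fd_w <- fd_spike(inst$times, inst$weights, inst$params, j, "weight")
      expect_lt(abs(an_w - fd_w) / max(abs(fd_w), 1e-8), 1e-4)
    }
  }
})

test_that("causal input-time partials sum to one (time-translation invariance)", {
  set.seed(505)
  checked <- 0
  while (checked < 60) {
    inst <- random_instance(3:8)
    sol <- simulate_neuron(inst$times, inst$weights, inst$params)
    if (!is.finite(sol$time) || length(sol$causal_set) < 2) next
    if (abs(1 + sol$lambert_w) < 1e-3) next
    checked <- checked + 1
    s <- sum(vapply(sol$causal_set, function(j) {
      d_spike_d_input(sol, inst$times[j], inst$weights[j], inst$params)
    }, numeric(1)))
    expect_lt(abs(s - 1), 1e-8)
  }
  # a single causal input shifts the spike one-for-one
  p <- model_params(0.7, 0.3)
  sol <- simulate_neuron(0.2, 3, p)
  expect_equal(d_spike_d_input(sol, 0.2, 3, p), 1, tolerance = 1e-12)
})

test_that("more weight on a rising-edge excitatory input means an earlier spike", {
  p <- model_params(0.7, 0.3)
  sol <- simulate_neuron(0, 2, p)
  expect_lt(d_spike_d_weight(sol, 0, p), 0)
})

test_that("partials refuse non-causal inputs and respect the clip bound", {
  p <- model_params(1, 0.3)
  sol <- simulate_neuron(c(0, 5), c(2, 1), p)
  expect_lt(sol$time, 5)
  expect_error(d_spike_d_input(sol, 5, 1, p), "not causal")
  expect_error(d_spike_d_weight(sol, 5, p), "not causal")

  # near the peak-tangency threshold the partial diverges; the clip bounds it
  pt <- model_params(1, exp(-1) * (1 - 1e-10))
  solt <- simulate_neuron(0, 1, pt)
  expect_true(is.finite(solt$time))
  raw <- abs(d_spike_d_weight(solt, 0, pt))
  expect_gt(raw, 1e4)
  expect_equal(abs(d_spike_d_weight(solt, 0, pt, clip = 100)), 100)

  # the layer-level partial matrices obey the bound entry-wise
  net <- tiny_net(mult = 2.5, theta = 0.25)
  tr <- forward_pass(net, c(0.1, 0.4, 0.7, 0.2))
  for (l in 1:2) {
    parts <- spikelat:::.layer_partials(tr$layers[[l]],
                                        net$layers[[l]]$weights,
                                        net$spec$params, clip = 0.05)
    expect_true(all(abs(parts$d_in) <= 0.05))
    expect_true(all(abs(parts$d_w) <= 0.05))
  }
})

test_that("non-causal inputs get exactly zero gradient and no influence", {
  p <- model_params(1, 0.3)
  times <- c(0, 5); weights <- c(2, 1.5)
  base <- simulate_neuron(times, weights, p)$time
  for (eps in c(-1e-7, 1e-7)) {
    expect_equal(simulate_neuron(c(0, 5 + eps), weights, p)$time, base,
                 tolerance = 1e-12)
  }
  # through the layer machinery: the late input's partial rows are zero
  state <- list(in_times = times, out_times = base,
                lambert_w = simulate_neuron(times, weights, p)$lambert_w,
                A = simulate_neuron(times, weights, p)$A,
                B = simulate_neuron(times, weights, p)$B,
                t_ref = simulate_neuron(times, weights, p)$t_ref)
  parts <- spikelat:::.layer_partials(state, matrix(weights, ncol = 1), p,
                                      clip = 1e6)
  expect_identical(parts$d_in[2, 1], 0)
  expect_identical(parts$d_w[2, 1], 0)
})

test_that("whole-network gradients match finite differences of forward+loss", {
  net <- tiny_net(sizes = c(4, 2, 4), pulses = 2, tau = 0.9, theta = 0.3,
                  mult = 2, seed = 7)
  cfg <- train_config(latency = 1, clip_derivative = 1e6,
                      penalty_no_spike = 0)
  x <- c(0.1, 0.4, 0.7, 0.2)
  tr <- forward_pass(net, x)
  expect_true(all(is.finite(unlist(tr$spikes))))
  bp <- backprop(net, tr, x, cfg)
  lossfun <- function(n2) {
    out <- forward_pass(n2, x)$spikes[[3]]
    latency_loss(x, out, l = cfg$latency, surrogate = cfg$surrogate)
  }
  h <- 1e-6
  for (l in 1:2) {
    W <- net$layers[[l]]$weights
    for (i in seq_len(nrow(W))) {
      for (j in seq_len(ncol(W))) {
        np <- net; np$layers[[l]]$weights[i, j] <- W[i, j] + h
        nm <- net; nm$layers[[l]]$weights[i, j] <- W[i, j] - h
        fd <- (lossfun(np) - lossfun(nm)) / (2 * h)
        an <- bp$grads$layers[[l]]$d_weights[i, j]
        expect_lt(abs(an - fd) / max(abs(fd), 1e-4), 1e-3)
      }
    }
    for (k in seq_along(net$layers[[l]]$pulse_times)) {
      np <- net
      np$layers[[l]]$pulse_times[k] <- np$layers[[l]]$pulse_times[k] + h
      nm <- net
      nm$layers[[l]]$pulse_times[k] <- nm$layers[[l]]$pulse_times[k] - h
      fd <- (lossfun(np) - lossfun(nm)) / (2 * h)
      an <- bp$grads$layers[[l]]$d_pulse_times[k]
      expect_lt(abs(an - fd) / max(abs(fd), 1e-4), 1e-3)
    }
  }
})

test_that("silent neurons receive the weight-amplifying penalty and nothing else", {
  # output neuron 2 silenced by strongly negative incoming weights
  net <- tiny_net(sizes = c(3, 2, 3), pulses = 1, tau = 1, theta = 0.3,
                  mult = 2, seed = 13)
  net$layers[[2]]$weights[, 2] <- -5
  cfg <- train_config(latency = 1, penalty_no_spike = 7,
                      clip_derivative = 1e6)
  x <- c(0.1, 0.3, 0.5)
  tr <- forward_pass(net, x)
  expect_false(is.finite(tr$spikes[[3]][2]))
  bp <- backprop(net, tr, x, cfg)
  expect_true(all(bp$grads$layers[[2]]$d_weights[, 2] == -7))
  # the loss still charges that pixel through the surrogate spike time
  expect_equal(bp$loss,
               latency_loss(x, tr$spikes[[3]], 1, surrogate = cfg$surrogate))

  # hidden neuron silenced: only the penalty reaches its incoming weights,
  # and it passes nothing upstream
  net2 <- tiny_net(sizes = c(3, 2, 3), pulses = 1, tau = 1, theta = 0.3,
                   mult = 2, seed = 13)
  net2$layers[[1]]$weights[, 2] <- -5
  tr2 <- forward_pass(net2, x)
  expect_false(is.finite(tr2$spikes[[2]][2]))
  bp2 <- backprop(net2, tr2, x, cfg)
  expect_true(all(bp2$grads$layers[[1]]$d_weights[, 2] == -7))
  # weights out of a silent neuron get no gradient (no event, no adjoint)
  expect_true(all(bp2$grads$layers[[2]]$d_weights[2, ] == 0))
})

test_that("zero adjoint in gives zero gradient out", {
  net <- tiny_net(mult = 2)
  x <- c(0.1, 0.4, 0.7, 0.2)
  tr <- forward_pass(net, x)
  # target exactly at latency: loss 0, adjoints 0
  target <- tr$spikes[[3]] - 1
  cfg <- train_config(latency = 1, penalty_no_spike = 0)
  bp <- backprop(net, tr, target, cfg)
  expect_equal(bp$loss, 0)
  for (l in 1:2) {
    expect_true(all(bp$grads$layers[[l]]$d_weights == 0))
    expect_true(all(bp$grads$layers[[l]]$d_pulse_times == 0))
  }
  expect_error(backprop(net, tr, c(0.1, 0.2), cfg), "target length")
})
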