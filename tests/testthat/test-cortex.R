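params <- cortical_params()

test_that("transfer function matches its closed-form values", {
  # singular point: phi -> 1/d (6.25 Hz for the excitatory parameters)
  I_sing <- params$b_e / params$a_e
  expect_equal(transfer(I_sing, "exc", params), 1 / params$d_e,
               tolerance = 1e-9)
  expect_equal(transfer(I_sing + 1e-9 / params$a_e, "exc", params),
               1 / params$d_e, tolerance = 1e-4)
  expect_equal(transfer(I_sing - 1e-9 / params$a_e, "exc", params),
               1 / params$d_e, tolerance = 1e-4)

  # I = 0: essentially silent (~2.6e-7 Hz)
  expect_lt(transfer(0, "exc", params), 1e-6)
  expect_equal(transfer(0, "exc", params),
               -125 / (1 - exp(0.16 * 125)), tolerance = 1e-12)

  # I = 1 nA: the exponential term is negligible, phi ~ aI - b = 185 Hz
  expect_equal(transfer(1, "exc", params), 185, tolerance = 1e-6)
})

test_that("analytic transfer derivative agrees with finite differences", {
  h <- 1e-7
  for (which in c("exc", "inh")) {
    I <- seq(0, 2, by = 0.01)
    fd <- (transfer(I + h, which, params) - transfer(I - h, which, params)) /
      (2 * h)
    an <- transfer_derivative(I, which, params)
    expect_lt(max(abs(an - fd) / pmax(abs(fd), 1e-12)), 1e-6)
  }
  # large current: derivative approaches a
  expect_equal(transfer_derivative(2, "exc", params), params$a_e,
               tolerance = 1e-3)
  # singular point: a/2
  expect_equal(transfer_derivative(params$b_e / params$a_e, "exc", params),
               params$a_e / 2, tolerance = 1e-6)
  # strictly positive everywhere
  expect_true(all(transfer_derivative(seq(-0.5, 3, by = 0.01), "inh",
                                      params) > 0))
})

test_that("effective time constant scales and clamps correctly", {
  I <- 0.5
  H <- transfer(I, "exc", params)
  tau <- effective_tau(H, I, "exc", params)
  expect_equal(tau, min(max(params$tau_pop0 * params$delta_T *
                              transfer_derivative(I, "exc", params) / H,
                            params$tau_clamp[1]), params$tau_clamp[2]))
  # doubling the rate halves tau (before clamping)
  tau2 <- effective_tau(2 * H, I, "exc", params)
  if (tau < params$tau_clamp[2] && tau2 > params$tau_clamp[1]) {
    expect_equal(tau2, tau / 2, tolerance = 1e-9)
  }
  # vanishing rate returns the clamp maximum, not an error
  expect_equal(effective_tau(0, I, "exc", params), params$tau_clamp[2])
})

test_that("synaptic gating reaches its analytic fixed points", {
  p <- cortical_params(sigma = 0)
  dt <- 1e-4
  H <- 40
  S <- 0
  for (i in 1:30000) S <- synaptic_step(S, H, "ampa", p, dt)
  expect_equal(S, p$tau_ampa * H, tolerance = 1e-3)
  S <- 0
  for (i in 1:30000) S <- synaptic_step(S, H, "nmda", p, dt)
  g <- p$gamma * p$tau_nmda * H
  expect_equal(S, g / (1 + g), tolerance = 1e-3)
  expect_lt(S, 1)
  # exponential decay from S0 with H = 0: halves every tau ln 2
  S <- 0.8
  n_half <- round(p$tau_gaba * log(2) / dt)
  for (i in seq_len(n_half)) S <- synaptic_step(S, 0, "gaba", p, dt)
  expect_equal(S, 0.4, tolerance = 0.02)   # first-order Euler decay bias
})

test_that("connectivity matrices implement the harmonic architecture", {
  conn <- build_connectivity(default_grid, params)
  expect_equal(conn$C_ee, diag(250))
  expect_equal(diag(conn$C_ii), rep(1, 250))
  expect_equal(conn$C_ii[1, 2], 0.1)
  expect_true(all(conn$C_ei >= 0) && all(conn$C_ie >= 0))

  # inhibitory column at T = 5 ms listens to excitatory columns at 5, 10
  # and 15 ms (and nowhere else beyond the Gaussian smearing)
  k5 <- nearest_column(default_grid, 5e-3)
  w <- conn$C_ei[k5, ]
  strong <- which(w > 0.5)
  targets <- nearest_column(default_grid, c(5e-3, 10e-3, 15e-3))
  expect_true(all(vapply(strong, function(i) min(abs(i - targets)) <= 2,
                         logical(1))))
  expect_true(all(w[targets] > 0.9))

  # the inhibitory column at T projects to lower harmonics {2T, 3T, ...}
  w_out <- conn$C_ie[, k5]
  out_targets <- nearest_column(default_grid, c(10e-3, 15e-3, 20e-3,
                                                25e-3, 30e-3))
  expect_true(all(w_out[out_targets] > 0.9))
  expect_lt(w_out[k5], 1e-3)                     # not its own column
  expect_lt(w_out[nearest_column(default_grid, 7.5e-3)], 1e-3)

  # harmonics beyond the grid edge are dropped: a 16 ms inhibitory column
  # has support only around its own period in C_ei
  k16 <- nearest_column(default_grid, 16e-3)
  expect_lt(sum(conn$C_ei[k16, ] > 0.5 ), 6)
  expect_true(all(which(conn$C_ei[k16, ] > 0.5) %in%
                    (k16 + (-2:2))))
})

test_that("input assembly respects baseline drives and sparsity", {
  conn <- build_connectivity(default_grid, params)
  zero <- list(S_ampa = numeric(250), S_nmda = numeric(250),
               S_gaba = numeric(250), S_th = numeric(250),
               Sh_ampa = numeric(250), Sh_nmda = numeric(250),
               Sh_gaba = numeric(250))
  cur <- compute_inputs(zero, conn, params)
  expect_equal(cur$I_e, rep(params$I0_e, 250))
  expect_equal(cur$I_i, rep(params$I0_i, 250))
  expect_equal(cur$Ih_e, rep(params$I0h_e + params$I0_sus, 250))
  expect_equal(cur$Ih_i, rep(params$I0h_i + params$I0_sus, 250))

  # only column k's NMDA gating nonzero: decoder inhibitory input above
  # baseline exactly where C_ei has support
  k <- nearest_column(default_grid, 5e-3)
  st <- zero
  st$S_nmda[k] <- 0.5
  cur <- compute_inputs(st, conn, params)
  touched <- which(cur$I_i > params$I0_i + 1e-12)
  expect_setequal(touched, which(conn$C_ei[, k] > 0))
})

test_that("noiseless zero-input network stays at its baseline", {
  p <- cortical_params(sigma = 0)
  conn <- build_connectivity(default_grid, p)
  A0 <- matrix(0, 250, 400)
  sim <- simulate_cortex(A0, conn, p, seed = 1L, settle = 0.2)
  late <- sim$time > 0.1
  # decoder excitatory stays essentially silent
  expect_lt(max(sim$H_e[, late]), 1)
  # sustainer inhibitory rests at a positive steady activation
  sus_i <- sim$Hh_i[, late]
  expect_gt(min(sus_i), 50)
  expect_lt(diff(range(sus_i)), 1)
  # decoder inhibitory essentially silent too
  expect_lt(max(sim$H_i[, late]), 1)
})

test_that("simulation is reproducible given a seed", {
  p <- cortical_params()
  conn <- build_connectivity(default_grid, p)
  A0 <- matrix(0.5, 250, 150)
  s1 <- simulate_cortex(A0, conn, p, seed = 42L, settle = 0.05)
  s2 <- simulate_cortex(A0, conn, p, seed = 42L, settle = 0.05)
  expect_identical(s1$H_e, s2$H_e)
  s3 <- simulate_cortex(A0, conn, p, seed = 43L, settle = 0.05)
  expect_false(identical(s1$H_e, s3$H_e))
})

test_that("rates stay bounded by the transfer of the largest current", {
  run <- cached_pitch_run()
  sim <- run$sim
  # bound: phi at a generous ceiling current given the conductivities
  I_max <- params$I0_e + params$J_th_ampa *
    max(params$tau_ampa * max(run$sacf$Ahat)) + params$J_ee_nmda + 0.1
  expect_lt(max(sim$H_e), transfer(I_max, "exc", params))
  expect_true(all(is.finite(sim$H_e)))
})
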