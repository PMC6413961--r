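make_an <- function(p, rate = 10000, markers = integer(0)) {
  structure(list(p = p, rate = rate, bank = channel_bank(), markers = markers),
            class = "an_response")
}

test_that("constant input settles at the flat fixed point sum_m p_m^2", {
  p <- matrix(rep(c(0.2, 0.4, 0.6), each = 4000), nrow = 3, byrow = TRUE)
  an <- make_an(p)
  sacf <- compute_sacf(an)
  target <- sum(c(0.2, 0.4, 0.6)^2)
  late <- sacf$A[, ncol(sacf$A)]
  expect_equal(late, rep(target, 250), tolerance = 1e-3)
})

test_that("periodic drive yields harmonic peaks on the lag grid", {
  rate <- 10000
  t <- seq_len(6000) / rate
  for (T_ms in c(4, 9)) {
    p <- matrix(0.5 + 0.45 * cos(2 * pi * t / (T_ms / 1000)), nrow = 1)
    sacf <- compute_sacf(make_an(rbind(p, p)))
    prof <- rowMeans(sacf$A[, -(1:500)])
    grid <- sacf$grid
    top3 <- order(prof, decreasing = TRUE)[1:3]
    # a sinusoidal drive has equal-height peaks at every multiple of T
    harmonics <- nearest_column(grid,
                                (1:floor(30 / T_ms)) * T_ms / 1000)
    expect_true(all(vapply(top3, function(i) min(abs(i - harmonics)) <= 1,
                           logical(1))), info = sprintf("T = %d ms", T_ms))
  }
})

test_that("SACF integrator matches a brute-force fine-step oracle", {
  # 200 ms snippet, 10x finer Euler integration of the same ODE
  set.seed(5)
  rate <- 10000
  nt <- 2000
  p <- matrix(pmin(1, pmax(0, 0.4 + 0.2 * sin(seq_len(nt) / 7) +
                             0.1 * rnorm(nt))), nrow = 1)
  p <- rbind(p, p * 0.8)
  an <- make_an(p)
  grid <- lag_grid()
  prm <- sacf_params()
  sacf <- compute_sacf(an, grid, prm, keep_native = TRUE)

  lag_idx <- c(10L, 100L, 240L)
  taus <- pmax(prm$tau_floor, prm$tau_scale * grid$lags)
  dt_f <- 1e-5
  for (li in lag_idx) {
    del <- grid$lags[li] * rate
    j0 <- floor(del); w <- del - j0
    drive <- numeric(nt)
    if (j0 + 1 < nt) {
      d1 <- c(rep(0, j0),
              .colSums(p[, 1:(nt - j0), drop = FALSE] *
                         p[, (j0 + 1):nt, drop = FALSE], 2, nt - j0))
      d2 <- c(rep(0, j0 + 1),
              .colSums(p[, 1:(nt - j0 - 1), drop = FALSE] *
                         p[, (j0 + 2):nt, drop = FALSE], 2, nt - j0 - 1))
      drive <- (1 - w) * d1 + w * d2
    }
    # brute force: Euler at dt/10 with zero-order-hold drive
    A <- 0
    out <- numeric(nt)
    for (i in seq_len(nt)) {
      for (s in 1:10) A <- A + dt_f / taus[li] * (-A + drive[i])
      out[i] <- A
    }
    rms <- sqrt(mean((sacf$native$A[li, ] - out)^2)) /
      sqrt(mean(out^2))
    expect_lt(rms, 0.01)
  }
})

test_that("regularisation is invariant to input gain", {
  rate <- 10000
  t <- seq_len(5000) / rate
  p <- matrix(0.5 + 0.4 * cos(2 * pi * t / 6e-3), nrow = 1)
  p <- rbind(p, 0.8 * p)
  sacf1 <- compute_sacf(make_an(p))
  sacf10 <- sacf1
  sacf10$A <- sacf1$A * 10       # louder input scales the raw SACF
  prm <- sacf_params(k = 1e-6)   # isolate the divisive stage from k
  r1 <- regularize(sacf1, prm, mode = "single")
  r10 <- regularize(sacf10, prm, mode = "single")
  expect_lt(max(abs(r10$Ahat - r1$Ahat)) / max(r1$Ahat), 1e-3)
})

test_that("degenerate regularisation inputs stay finite", {
  z <- make_an(matrix(0, 2, 2000))
  sacf <- compute_sacf(z)
  reg <- regularize(sacf, mode = "single")
  expect_true(all(reg$Ahat == 0))
  # flat nonzero input: flat output at the documented baseline 0
  f <- make_an(matrix(0.5, 2, 2000))
  regf <- regularize(compute_sacf(f), mode = "dyad")
  expect_true(all(regf$Ahat[, -(1:400)] == 0))
})

test_that("full-pipeline regularised output is level-robust", {
  w <- short_irn_sequence(noise_dur = 0.25, pitch_dur = 0.35)
  loud <- set_level(w, 90)
  s1 <- regularize(compute_sacf(auditory_nerve_probability(w)),
                   mode = "single")
  s2 <- regularize(compute_sacf(auditory_nerve_probability(loud)),
                   mode = "single")
  ch <- nearest_column(default_grid, 8e-3)
  peak1 <- max(rowMeans(s1$Ahat[, -(1:300)]))
  peak2 <- max(rowMeans(s2$Ahat[, -(1:300)]))
  expect_lt(abs(peak1 - peak2) / peak1, 0.05)
})

test_that("harmonic structure property holds for periodic stimuli", {
  # top-3 time-averaged regularised lags lie within {T, 2T, 3T, 4T}
  for (T_s in c(2.5e-3, 6e-3, 12e-3)) {
    tone <- set_level(generate_click_train(T_s, 0.4), 75)
    sacf <- regularize(compute_sacf(auditory_nerve_probability(tone)),
                       mode = "single")
    prof <- rowMeans(sacf$Ahat[, -(1:150)])
    top <- order(prof, decreasing = TRUE)[1:3]
    harm <- nearest_column(default_grid, (1:4) * T_s)
    expect_true(all(vapply(top, function(i) min(abs(i - harm)) <= 2,
                           logical(1))), info = sprintf("T = %g", T_s))
  }
})

test_that("duration shorter than the maximum lag errors", {
  p <- matrix(0.5, 2, 200)   # 20 ms at 10 kHz < 30 ms max lag
  expect_error(compute_sacf(make_an(p)), "duration")
})

test_that("lag grid invariants hold", {
  g <- lag_grid()
  expect_equal(g$n, 250L)
  expect_equal(g$lags[1], 0.5e-3)
  expect_equal(g$lags[250], 30e-3)
  expect_lt(diff(range(diff(g$lags))), 1e-15)
  taus <- pitchcortex:::sacf_tau(g, sacf_params())
  expect_true(all(taus > 0) && all(diff(taus) >= 0))
})
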