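#' Cortical model parameters
#'
#' All constants of the two-network (decoder/sustainer) mean-field model:
#' transfer-function parameters of the excitatory and inhibitory ensembles,
#' synaptic conductivities (nA), synaptic and population time constants,
#' baseline drives, synaptic noise, subcortical delays and the Euler step.
#' Defaults are the model's reference parameter set; any subset can be
#' overridden via `...`.
#'
#' @param ... Named overrides of the defaults, e.g. `tau_nmda = 0.025`.
#' @return A list of class `cortical_params`.
#' @details
#' Conductivity naming: `J_<src><dst>_<receptor>` for decoder-internal
#' weights (e.g. `J_ei_nmda` is the excitatory-to-inhibitory NMDA
#' conductivity), `Jh_` prefixes the sustainer-internal weights, `J_th_ampa`
#' the subcortical input, `J_e_nmda` the top-down (sustainer-to-decoder)
#' drive and `Jh_a_ampa` / `Jh_a_gaba` the bottom-up (decoder-to-sustainer)
#' drives. Time constants are in seconds, currents in nA, rates in Hz.
#' @export
cortical_params <- function(...) {
  p <- list(
    # transfer functions (excitatory / inhibitory)
    a_e = 310, b_e = 125, d_e = 0.16,
    a_i = 615, b_i = 177, d_i = 0.087,
    # conductivities, nA
    J_th_ampa = 2.7,      # subcortical input -> decoder excitatory
    J_e_nmda = 0.45,      # top-down, sustainer exc -> decoder inhibitory
    Jh_a_gaba = 0.45,     # bottom-up, decoder inh -> sustainer inhibitory
    Jh_a_ampa = 0.35,     # bottom-up, decoder exc -> sustainer excitatory
    J_ee_nmda = 0.14, J_ee_ampa = 0.00099,
    J_ei_nmda = 0.17, J_ei_ampa = 0.000065,
    J_ie_gaba = 0.53, J_ii_gaba = 0.11,
    Jh_ee_nmda = 0.25, Jh_ee_ampa = 0.00099,
    Jh_ei_ampa = 0.00099, Jh_ie_gaba = 0.80,
    c0_ie = 0.1,          # baseline (unspecific) inhibitory weight
    gamma = 0.641,        # NMDA gating coupling
    # time constants, s
    tau_ampa = 0.002, tau_gaba = 0.005, tau_nmda = 0.030, tau_pop0 = 0.010,
    delta_T = 1,          # sharpness of action-potential initiation, mV
    sigma = 0.0007,       # synaptic noise amplitude, nA
    # baseline drives, nA
    I0_e = 0.315, I0_i = 0.15, I0h_e = 0.26, I0h_i = 0.18, I0_sus = 0.24,
    # subcortical delays, s
    delay_single = 0.050, delay_dyad = 0.075,
    # integration
    dt = 0.001, tau_clamp = c(0.001, 0.100),
    # connectivity
    harmonic_sigma = 1.5, n_harmonics_ei = 3L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    stop(sprintf("unknown cortical parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  p[names(dots)] <- dots
  structure(p, class = "cortical_params")
}

#' Ensemble transfer function
#'
#' Current-to-rate transfer `phi(I) = (aI - b) / (1 - exp(-d(aI - b)))`, the
#' standard mean-field reduction of a leaky integrate-and-fire ensemble. The
#' removable singularity at `aI = b` is handled by a series expansion, giving
#' the L'Hopital limit `1/d` there.
#'
#' @param I Input current(s), nA.
#' @param which `"exc"` or `"inh"`.
#' @param params A [cortical_params()].
#' @return Firing rate(s) in Hz.
#' @export
transfer <- function(I, which = c("exc", "inh"), params = cortical_params()) {
  which <- match.arg(which)
  a <- if (which == "exc") params$a_e else params$a_i
  b <- if (which == "exc") params$b_e else params$b_i
  d <- if (which == "exc") params$d_e else params$d_i
  u <- a * I - b
  out <- numeric(length(u))
  small <- abs(d * u) < 1e-6
  out[small] <- 1 / d + u[small] / 2 + d * u[small]^2 / 12
  ub <- u[!small]
  out[!small] <- ub / (1 - exp(-d * ub))
  out
}

#' Derivative of the transfer function
#'
#' Exact analytic derivative of [transfer()],
#' `phi'(I) = a phi(I) (1/(aI-b) + d / (1 - exp(d(aI-b))))`, which is
#' strictly positive; near `aI = b` the series limit `a/2` applies.
#'
#' @inheritParams transfer
#' @return Derivative in Hz/nA.
#' @export
transfer_derivative <- function(I, which = c("exc", "inh"),
                                params = cortical_params()) {
  which <- match.arg(which)
  a <- if (which == "exc") params$a_e else params$a_i
  b <- if (which == "exc") params$b_e else params$b_i
  d <- if (which == "exc") params$d_e else params$d_i
  u <- a * I - b
  out <- numeric(length(u))
  small <- abs(d * u) < 1e-5
  out[small] <- a * (0.5 + d * u[small] / 6)
  ub <- u[!small]
  phib <- ub / (1 - exp(-d * ub))
  out[!small] <- a * phib * (1 / ub + d / (1 - exp(d * ub)))
  out
}

#' Adaptive population time constant
#'
#' `tau_pop(H) = tau0 * Delta_T * phi'(I) / H`, clamped to
#' `params$tau_clamp` (default \[1, 100\] ms). The expression diverges as the
#' rate approaches zero, so vanishing rates return the clamp maximum.
#'
#' @param H Population rate(s), Hz.
#' @param I Input current(s), nA.
#' @param which `"exc"` or `"inh"`.
#' @param params A [cortical_params()].
#' @return Effective time constant(s) in seconds.
#' @export
effective_tau <- function(H, I, which = c("exc", "inh"),
                          params = cortical_params()) {
  which <- match.arg(which)
  tau <- rep(params$tau_clamp[2], length(H))
  pos <- H > 1e-9
  tau[pos] <- params$tau_pop0 * params$delta_T *
    transfer_derivative(I[pos], which, params) / H[pos]
  pmin(pmax(tau, params$tau_clamp[1]), params$tau_clamp[2])
}

#' One Euler step of the synaptic gating dynamics
#'
#' AMPA/GABA gating follows `dS/dt = -S/tau + H + xi`; NMDA gating follows
#' `dS/dt = -S/tau + gamma (1 - S) H + xi`, where `xi` is white synaptic
#' noise entering the update as `sigma * sqrt(dt) * z` with standard-normal
#' `z` drawn independently per variable per step. Gating is clamped to be
#' non-negative (NMDA additionally to at most 1).
#'
#' @param S Gating vector.
#' @param H Presynaptic rate vector, Hz.
#' @param kind `"ampa"`, `"gaba"` or `"nmda"`.
#' @param params A [cortical_params()].
#' @param dt Step, s.
#' @param noise Optional pre-drawn standard-normal vector (scaled internally);
#'   `NULL` for a noiseless step.
#' @return The updated gating vector.
#' @export
synaptic_step <- function(S, H, kind = c("ampa", "gaba", "nmda"),
                          params = cortical_params(), dt = params$dt,
                          noise = NULL) {
  kind <- match.arg(kind)
  dS <- switch(kind,
    ampa = -S / params$tau_ampa + H,
    gaba = -S / params$tau_gaba + H,
    nmda = -S / params$tau_nmda + params$gamma * (1 - S) * H
  )
  S <- S + dt * dS
  if (!is.null(noise)) S <- S + params$sigma * sqrt(dt) * noise
  S[S < 0] <- 0
  if (kind == "nmda") S[S > 1] <- 1
  S
}

#' Harmonic connectivity of the decoder network
#'
#' Builds the four 250 x 250 weight matrices. `C_ee` is the identity (each
#' excitatory ensemble excites only its own column's circuits);
#' `C_ii = (1 - c0) I + c0` mixes specific and unspecific inhibition. The
#' harmonic matrices implement the decoding architecture: the inhibitory
#' ensemble at period T receives from the excitatory ensembles at
#' \{T, 2T, 3T\} (`C_ei`), and projects back onto the excitatory ensembles at
#' the lower harmonics \{2T, 3T, 4T, ...\} up to the grid edge (`C_ie`).
#' Each harmonic target contributes a narrow Gaussian weight profile (peak 1,
#' sd `harmonic_sigma` grid steps) around the nearest grid column, so that k
#' simultaneously active harmonics deliver approximately k unit-weight
#' inputs; harmonics falling beyond the grid edge are dropped.
#'
#' Matrix orientation: `C[n, k]` is the weight from source column k to target
#' column n, so inputs are computed as `C %*% S`.
#'
#' @param grid A [lag_grid()].
#' @param params A [cortical_params()].
#' @return A list of class `connectivity` with `C_ee`, `C_ei`, `C_ie`,
#'   `C_ii`.
#' @export
build_connectivity <- function(grid = lag_grid(), params = cortical_params()) {
  n <- grid$n
  lags <- grid$lags
  sig <- params$harmonic_sigma
  cols <- seq_len(n)

  gauss_row <- function(period) {
    # continuous column position of `period` on the grid
    pos <- (period - lags[1]) / grid$step + 1
    if (pos > n + 3 * sig || pos < 1 - 3 * sig) return(NULL)
    w <- exp(-(cols - pos)^2 / (2 * sig^2))
    w[w < 1e-4] <- 0
    w
  }

  C_ee <- diag(n)
  C_ii <- matrix(params$c0_ie, n, n)
  diag(C_ii) <- 1

  C_ei <- matrix(0, n, n)   # exc k -> inh n
  C_ie <- matrix(0, n, n)   # inh k -> exc n
  for (k in cols) {
    Tk <- lags[k]
    # inhibitory ensemble k listens to excitatory ensembles at {T, 2T, 3T}
    for (h in seq_len(params$n_harmonics_ei)) {
      w <- gauss_row(h * Tk)
      if (!is.null(w)) C_ei[k, ] <- pmax(C_ei[k, ], w)
    }
    # inhibitory ensemble k silences excitatory ensembles at {2T, 3T, ...};
    # harmonics just past the edge still contribute their on-grid tail
    h_max <- floor((max(lags) + 3 * sig * grid$step) / Tk)
    if (h_max >= 2) {
      for (h in 2:h_max) {
        w <- gauss_row(h * Tk)
        if (!is.null(w)) C_ie[, k] <- pmax(C_ie[, k], w)
      }
    }
  }
  structure(list(C_ee = C_ee, C_ei = C_ei, C_ie = C_ie, C_ii = C_ii,
                 grid = grid),
            class = "connectivity")
}

#' Synaptic input currents of both networks
#'
#' Assembles the total input current of every ensemble from the current
#' gating state: decoder-internal recurrency through the connectivity
#' matrices, subcortical AMPA drive of the decoder excitatory ensembles,
#' top-down NMDA drive of the decoder inhibitory ensembles, block-internal
#' sustainer recurrency, bottom-up AMPA/GABA drives of the sustainer, and
#' the constant baseline currents (with the additional sustainer drive
#' `I0_sus` applied to both sustainer populations).
#'
#' @param state Named list of gating vectors: `S_ampa`, `S_nmda` (decoder
#'   excitatory), `S_gaba` (decoder inhibitory), `S_th` (subcortical),
#'   `Sh_ampa`, `Sh_nmda` (sustainer excitatory), `Sh_gaba` (sustainer
#'   inhibitory).
#' @param conn A [build_connectivity()] result.
#' @param params A [cortical_params()].
#' @return A list with currents `I_e`, `I_i` (decoder) and `Ih_e`, `Ih_i`
#'   (sustainer), each length 250, in nA.
#' @export
compute_inputs <- function(state, conn, params = cortical_params()) {
  exc_drive <- params$J_ei_nmda * state$S_nmda + params$J_ei_ampa * state$S_ampa
  gaba_sum <- sum(state$S_gaba)

  I_e <- params$I0_e +
    params$J_th_ampa * state$S_th +
    params$J_ee_nmda * state$S_nmda + params$J_ee_ampa * state$S_ampa -
    params$J_ie_gaba * drop(conn$C_ie %*% state$S_gaba)

  # C_ii %*% S = (1 - c0) S + c0 * sum(S), computed in closed form
  I_i <- params$I0_i +
    params$J_e_nmda * state$Sh_nmda +
    drop(conn$C_ei %*% exc_drive) -
    params$J_ii_gaba * ((1 - params$c0_ie) * state$S_gaba +
                          params$c0_ie * gaba_sum)

  Ih_e <- params$I0h_e + params$I0_sus +
    params$Jh_ee_nmda * state$Sh_nmda + params$Jh_ee_ampa * state$Sh_ampa -
    params$Jh_ie_gaba * state$Sh_gaba +
    params$Jh_a_ampa * state$S_ampa

  Ih_i <- params$I0h_i + params$I0_sus +
    params$Jh_ei_ampa * state$Sh_ampa -
    params$Jh_a_gaba * state$S_gaba

  list(I_e = I_e, I_i = I_i, Ih_e = Ih_e, Ih_i = Ih_i)
}

# Baseline fixed point of the uniform (input-free, noiseless) network,
# found by damped fixed-point iteration on a single column (all columns are
# identical without input). Used to initialise simulations at rest.
baseline_state <- function(params) {
  s <- list(H_e = 0, H_i = 0, Hh_e = 0, Hh_i = 50,
            S_ampa = 0, S_nmda = 0, S_gaba = 0, S_th = 0,
            Sh_ampa = 0, Sh_nmda = 0, Sh_gaba = 0)
  for (it in 1:400) {
    # decoder rates are ~0 at rest, so the harmonic C_ie inhibition (driven
    # by decoder-inhibitory gating) is negligible in the scalar reduction;
    # the in-simulation settle phase absorbs the residual
    I_e <- params$I0_e + params$J_ee_nmda * s$S_nmda +
      params$J_ee_ampa * s$S_ampa
    I_i <- params$I0_i + params$J_e_nmda * s$Sh_nmda -
      params$J_ii_gaba * s$S_gaba
    Ih_e <- params$I0h_e + params$I0_sus +
      params$Jh_ee_nmda * s$Sh_nmda + params$Jh_ee_ampa * s$Sh_ampa -
      params$Jh_ie_gaba * s$Sh_gaba + params$Jh_a_ampa * s$S_ampa
    Ih_i <- params$I0h_i + params$I0_sus +
      params$Jh_ei_ampa * s$Sh_ampa - params$Jh_a_gaba * s$S_gaba
    mix <- 0.2
    s$H_e <- (1 - mix) * s$H_e + mix * transfer(I_e, "exc", params)
    s$H_i <- (1 - mix) * s$H_i + mix * transfer(I_i, "inh", params)
    s$Hh_e <- (1 - mix) * s$Hh_e + mix * transfer(Ih_e, "exc", params)
    s$Hh_i <- (1 - mix) * s$Hh_i + mix * transfer(Ih_i, "inh", params)
    s$S_ampa <- params$tau_ampa * s$H_e
    s$S_gaba <- params$tau_gaba * s$H_i
    g <- params$gamma * params$tau_nmda * s$H_e
    s$S_nmda <- g / (1 + g)
    s$Sh_ampa <- params$tau_ampa * s$Hh_e
    s$Sh_gaba <- params$tau_gaba * s$Hh_i
    gh <- params$gamma * params$tau_nmda * s$Hh_e
    s$Sh_nmda <- gh / (1 + gh)
  }
  s
}

#' Simulate the decoder and sustainer networks
#'
#' Forward-Euler integration (default step 1 ms) of the ensemble rates with
#' adaptive population time constants, and of all synaptic gating variables,
#' driven by the regularised SACF. The network is initialised at its
#' input-free fixed point and settled for `settle` seconds before the
#' stimulus-locked input starts at simulation time 0.
#'
#' @param sacf A regularised `sacf_output` (with `Ahat`), or a bare
#'   lag x time matrix at the cortical step.
#' @param conn A [build_connectivity()] result.
#' @param params A [cortical_params()].
#' @param seed Integer seed for the synaptic noise.
#' @param settle Settling time before stimulus onset, s.
#' @param inject Optional function `(t_index) -> list(e =, i =)` adding
#'   currents (nA, length-250 vectors or scalars) to the decoder populations;
#'   used for controlled current-injection experiments.
#' @return A list of class `cortical_sim` with rate trajectories `H_e`,
#'   `H_i`, `Hh_e`, `Hh_i` (250 x steps), the time axis `time` (s, stimulus
#'   onset at 0), `markers` (s), `params` and `seed`.
#' @export
simulate_cortex <- function(sacf, conn, params = cortical_params(),
                            seed = 1L, settle = 0.3, inject = NULL) {
  if (inherits(sacf, "sacf_output")) {
    if (is.null(sacf$Ahat)) stop("regularize() the SACF first", call. = FALSE)
    Ahat <- sacf$Ahat
    markers <- (sacf$markers - 1L) * sacf$dt
    if (abs(sacf$dt - params$dt) > 1e-12) {
      stop("SACF output step must match the cortical step", call. = FALSE)
    }
  } else {
    Ahat <- sacf
    markers <- numeric(0)
  }
  n <- conn$grid$n
  if (nrow(Ahat) != n) stop("input rows must match the lag grid", call. = FALSE)
  dt <- params$dt
  n_settle <- round(settle / dt)
  n_stim <- ncol(Ahat)
  n_tot <- n_settle + n_stim

  b <- baseline_state(params)
  H_e <- rep(b$H_e, n); H_i <- rep(b$H_i, n)
  Hh_e <- rep(b$Hh_e, n); Hh_i <- rep(b$Hh_i, n)
  st <- list(S_ampa = rep(b$S_ampa, n), S_nmda = rep(b$S_nmda, n),
             S_gaba = rep(b$S_gaba, n), S_th = rep(b$S_th, n),
             Sh_ampa = rep(b$Sh_ampa, n), Sh_nmda = rep(b$Sh_nmda, n),
             Sh_gaba = rep(b$Sh_gaba, n))

  R_e <- matrix(0, n, n_tot); R_i <- matrix(0, n, n_tot)
  Rh_e <- matrix(0, n, n_tot); Rh_i <- matrix(0, n, n_tot)

  noisy <- params$sigma > 0
  with_seed(seed, {
    for (t in seq_len(n_tot)) {
      A_t <- if (t > n_settle) Ahat[, t - n_settle] else numeric(n)
      cur <- compute_inputs(st, conn, params)
      if (!is.null(inject)) {
        extra <- inject(t - n_settle)
        if (!is.null(extra$e)) cur$I_e <- cur$I_e + extra$e
        if (!is.null(extra$i)) cur$I_i <- cur$I_i + extra$i
      }

      phi_e <- transfer(cur$I_e, "exc", params)
      phi_i <- transfer(cur$I_i, "inh", params)
      phih_e <- transfer(cur$Ih_e, "exc", params)
      phih_i <- transfer(cur$Ih_i, "inh", params)

      H_e <- H_e + dt / effective_tau(H_e, cur$I_e, "exc", params) * (phi_e - H_e)
      H_i <- H_i + dt / effective_tau(H_i, cur$I_i, "inh", params) * (phi_i - H_i)
      Hh_e <- Hh_e + dt / effective_tau(Hh_e, cur$Ih_e, "exc", params) * (phih_e - Hh_e)
      Hh_i <- Hh_i + dt / effective_tau(Hh_i, cur$Ih_i, "inh", params) * (phih_i - Hh_i)
      H_e[H_e < 0] <- 0; H_i[H_i < 0] <- 0
      Hh_e[Hh_e < 0] <- 0; Hh_i[Hh_i < 0] <- 0

      z <- if (noisy) matrix(stats::rnorm(6L * n), n, 6L) else NULL
      st$S_ampa <- synaptic_step(st$S_ampa, H_e, "ampa", params, dt,
                                 if (noisy) z[, 1] else NULL)
      st$S_nmda <- synaptic_step(st$S_nmda, H_e, "nmda", params, dt,
                                 if (noisy) z[, 2] else NULL)
      st$S_gaba <- synaptic_step(st$S_gaba, H_i, "gaba", params, dt,
                                 if (noisy) z[, 3] else NULL)
      st$Sh_ampa <- synaptic_step(st$Sh_ampa, Hh_e, "ampa", params, dt,
                                  if (noisy) z[, 4] else NULL)
      st$Sh_nmda <- synaptic_step(st$Sh_nmda, Hh_e, "nmda", params, dt,
                                  if (noisy) z[, 5] else NULL)
      st$Sh_gaba <- synaptic_step(st$Sh_gaba, Hh_i, "gaba", params, dt,
                                  if (noisy) z[, 6] else NULL)
      # subcortical gating follows noiseless AMPA dynamics driven by Ahat
      st$S_th <- st$S_th + dt * (-st$S_th / params$tau_ampa + A_t)
      st$S_th[st$S_th < 0] <- 0

      if (!all(is.finite(H_e)) || !all(is.finite(H_i)) ||
          !all(is.finite(Hh_e)) || !all(is.finite(Hh_i))) {
        bad <- which(!is.finite(c(H_e, H_i, Hh_e, Hh_i)))[1] %% n
        stop(sprintf("non-finite state at step %d (column %d)", t, bad),
             call. = FALSE)
      }
      R_e[, t] <- H_e; R_i[, t] <- H_i; Rh_e[, t] <- Hh_e; Rh_i[, t] <- Hh_i
    }
  })

  structure(list(H_e = R_e, H_i = R_i, Hh_e = Rh_e, Hh_i = Rh_i,
                 time = (seq_len(n_tot) - 1L - n_settle) * dt,
                 dt = dt, grid = conn$grid, markers = markers,
                 params = params, seed = as.integer(seed)),
            class = "cortical_sim")
}

#' @export
print.cortical_sim <- function(x, ...) {
  cat(sprintf("<cortical_sim> %d columns x %d steps (%.2f s, dt = %g ms)\n",
              nrow(x$H_e), ncol(x$H_e), ncol(x$H_e) * x$dt, 1000 * x$dt))
  invisible(x)
}
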