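# Independent fine-step (0.1 ms Euler) reference integrator for the
# decoder/sustainer equations, written separately from simulate_cortex();
# used to bound the integration error of the production 1 ms Euler path.
fine_sim <- function(Ahat, conn, p, dt_f = 1e-4, settle = 0.4) {
  n <- 250; n_settle <- round(settle / dt_f); nc <- ncol(Ahat)
  sub <- round(1e-3 / dt_f)
  n_tot <- n_settle + nc * sub
  H_e <- H_i <- Hh_e <- rep(0, n); Hh_i <- rep(81.3, n)
  S_am <- S_nm <- S_gb <- S_th <- Sh_am <- Sh_nm <- rep(0, n)
  Sh_gb <- rep(0.005 * 81.3, n)
  out <- matrix(0, 4, nc)
  phi <- function(I, a, b, d) { u <- a * I - b
    ifelse(abs(d * u) < 1e-6, 1 / d + u / 2, u / (1 - exp(-d * u))) }
  dphi <- function(I, a, b, d) { u <- a * I - b
    ifelse(abs(d * u) < 1e-5, a * (0.5 + d * u / 6),
           a * phi(I, a, b, d) * (1 / u + d / (1 - exp(d * u)))) }
  for (t in seq_len(n_tot)) {
    A_t <- if (t > n_settle) Ahat[, ((t - n_settle - 1) %/% sub) + 1] else numeric(n)
    I_e <- p$I0_e + p$J_th_ampa * S_th + p$J_ee_nmda * S_nm +
      p$J_ee_ampa * S_am - p$J_ie_gaba * drop(conn$C_ie %*% S_gb)
    I_i <- p$I0_i + p$J_e_nmda * Sh_nm +
      drop(conn$C_ei %*% (p$J_ei_nmda * S_nm + p$J_ei_ampa * S_am)) -
      p$J_ii_gaba * ((1 - p$c0_ie) * S_gb + p$c0_ie * sum(S_gb))
    Ih_e <- p$I0h_e + p$I0_sus + p$Jh_ee_nmda * Sh_nm +
      p$Jh_ee_ampa * Sh_am - p$Jh_ie_gaba * Sh_gb + p$Jh_a_ampa * S_am
    Ih_i <- p$I0h_i + p$I0_sus + p$Jh_ei_ampa * Sh_am - p$Jh_a_gaba * S_gb
    tau <- function(H, I, a, b, d) pmin(pmax(
      ifelse(H > 1e-9, p$tau_pop0 * p$delta_T * dphi(I, a, b, d) / H, 0.1),
      0.001), 0.1)
    H_e <- pmax(H_e + dt_f / tau(H_e, I_e, p$a_e, p$b_e, p$d_e) *
                  (phi(I_e, p$a_e, p$b_e, p$d_e) - H_e), 0)
    H_i <- pmax(H_i + dt_f / tau(H_i, I_i, p$a_i, p$b_i, p$d_i) *
                  (phi(I_i, p$a_i, p$b_i, p$d_i) - H_i), 0)
    Hh_e <- pmax(Hh_e + dt_f / tau(Hh_e, Ih_e, p$a_e, p$b_e, p$d_e) *
                   (phi(Ih_e, p$a_e, p$b_e, p$d_e) - Hh_e), 0)
    Hh_i <- pmax(Hh_i + dt_f / tau(Hh_i, Ih_i, p$a_i, p$b_i, p$d_i) *
                   (phi(Ih_i, p$a_i, p$b_i, p$d_i) - Hh_i), 0)
    S_am <- pmax(S_am + dt_f * (-S_am / p$tau_ampa + H_e), 0)
    S_nm <- pmin(pmax(S_nm + dt_f * (-S_nm / p$tau_nmda +
                                       p$gamma * (1 - S_nm) * H_e), 0), 1)
    S_gb <- pmax(S_gb + dt_f * (-S_gb / p$tau_gaba + H_i), 0)
    Sh_am <- pmax(Sh_am + dt_f * (-Sh_am / p$tau_ampa + Hh_e), 0)
    Sh_nm <- pmin(pmax(Sh_nm + dt_f * (-Sh_nm / p$tau_nmda +
                                         p$gamma * (1 - Sh_nm) * Hh_e), 0), 1)
    Sh_gb <- pmax(Sh_gb + dt_f * (-Sh_gb / p$tau_gaba + Hh_i), 0)
    S_th <- pmax(S_th + dt_f * (-S_th / p$tau_ampa + A_t), 0)
    if (t > n_settle && (t - n_settle) %% sub == 0) {
      j <- (t - n_settle) %/% sub
      out[, j] <- c(mean(H_e), mean(H_i), mean(Hh_e), mean(Hh_i))
    }
  }
  out
}
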