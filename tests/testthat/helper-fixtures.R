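# Fixtures and independent oracles shared across the test files. All fixtures
# are built in code; oracles (split-operator wave packet, driven two-level
# TDSE, characteristic-polynomial eigensolver) are deliberately independent of
# the package's propagation code paths.

# Three-state fixture (ground + two coupled excited states) used for the
# FP / RP-AXE / RP-SXE comparisons: a two-mode LVC model whose S1-S2 vertical
# gap is 1.2 eV with a few-tenths-of-an-eV spread over the Wigner ensemble,
# mild interstate coupling, and z-polarized transition dipoles of comparable
# strength so a broadband z pulse excites a coherent S1/S2 superposition.
fixture_two_state <- function() {
  freqs <- c(0.010, 0.016)
  kap <- function(ev, k) ev_to_au(ev) * sqrt(freqs[k])
  kappa <- rbind(c(0, 0),
                 c(kap(0.20, 1), kap(0.08, 2)),
                 c(kap(-0.15, 1), kap(0.10, 2)))
  lambda <- array(0, c(3, 3, 2))
  lambda[2, 3, 2] <- lambda[3, 2, 2] <- kap(0.08, 2)
  dip0 <- array(0, c(3, 3, 3))
  dip0[1, 2, ] <- dip0[2, 1, ] <- c(0, 0, 0.5)
  dip0[1, 3, ] <- dip0[3, 1, ] <- c(0, 0, 0.4)
  dip0[2, 3, ] <- dip0[3, 2, ] <- c(0.6, 0, 0)
  for (i in 1:3) dip0[i, i, ] <- c(0.08 * i, 0, -0.03 * i)
  list(model = lvc_model(freqs, ev_to_au(c(0, 6.8, 8.0)), kappa, lambda, dip0),
       reference = harmonic_reference(freqs),
       pulse = gaussian_pulse(7.4, 2.83, c(0, 0, 1)))
}

# 1D avoided-crossing scattering fixture: a Wigner-sampled wave packet sent
# through the crossing at mean momentum p0. Intermediate Landau-Zener regime.
fixture_scattering <- function(A = 0.005, c = 0.03, x0 = -15, p0 = 1,
                               sigma_x = 5) {
  list(model = avoided_crossing_model(A = A, c = c),
       reference = harmonic_reference(1 / (2 * sigma_x^2),
                                      reference_geometry = x0),
       p0 = p0,
       # dt = 0.25 au; electronic substeps scaled with the much smaller step
       cfg = propagator_config(dt_fs = 0.25 * 0.02418884, n_substeps = 5L,
                               t_final_fs = 32 * 0.02418884 * 1.0,
                               energy_tolerance_eV = 0.5))
}

scattering_ensemble <- function(fx, n, seed) {
  s <- sample_wigner(fx$reference, n, seed)
  s$P[, 1] <- s$P[, 1] + fx$p0
  s
}

# --- Independent oracles -----------------------------------------------------

# Eigenvalues of a symmetric 3x3 matrix from the characteristic polynomial
# (polyroot), independent of eigen()
charpoly_eigenvalues <- function(M) {
  stopifnot(nrow(M) == 3)
  tr <- sum(diag(M))
  m2 <- (sum(diag(M))^2 - sum(M * M)) / 2  # sum of principal 2x2 minors
  dt <- det(M)
  r <- polyroot(c(-dt, m2, -tr, 1))
  sort(Re(r))
}

# Exact two-state wave-packet propagation on the 1D avoided-crossing model by
# the split-operator method on a position grid. Returns adiabatic populations
# at t_final for a Gaussian packet started in the lower adiabatic state.
split_operator_lower_population <- function(A, c, x0, p0, sigma_x, t_final,
                                            n_grid = 4096, x_max = 120,
                                            dt = 0.25) {
  x <- seq(-x_max, x_max, length.out = n_grid + 1)[1:n_grid]
  dx <- x[2] - x[1]
  k <- 2 * pi * c(0:(n_grid / 2 - 1), -(n_grid / 2):-1) / (n_grid * dx)
  theta <- 0.5 * atan2(c, A * x)        # mixing angle of [[Ax, c],[c, -Ax]]
  # lower adiabatic state of [[Ax, c],[c,-Ax]]: eigenvector for -sqrt(..)
  lo1 <- sin(theta)
  lo2 <- -cos(theta)
  env <- exp(-(x - x0)^2 / (4 * sigma_x^2) + 1i * p0 * x)
  psi1 <- env * lo1
  psi2 <- env * lo2
  nrm <- sqrt(sum(Mod(psi1)^2 + Mod(psi2)^2) * dx)
  psi1 <- psi1 / nrm; psi2 <- psi2 / nrm
  kin <- exp(-1i * k^2 / 2 * dt / 2)
  # potential propagator for [[a, c],[c, -a]]: exp(-iVdt) =
  # cos(d t) I - i sin(d t)/d * V, d = sqrt(a^2 + c^2)
  a <- A * x
  d <- sqrt(a^2 + c^2)
  cosd <- cos(d * dt); sind <- sin(d * dt) / d
  U11 <- cosd - 1i * sind * a
  U22 <- cosd + 1i * sind * a
  U12 <- -1i * sind * c
  n_steps <- round(t_final / dt)
  for (s in seq_len(n_steps)) {
    psi1 <- fft(kin * fft(psi1), inverse = TRUE) / n_grid
    psi2 <- fft(kin * fft(psi2), inverse = TRUE) / n_grid
    t1 <- U11 * psi1 + U12 * psi2
    psi2 <- U12 * psi1 + U22 * psi2
    psi1 <- t1
    psi1 <- fft(kin * fft(psi1), inverse = TRUE) / n_grid
    psi2 <- fft(kin * fft(psi2), inverse = TRUE) / n_grid
  }
  p_lo <- sum(Mod(lo1 * psi1 + lo2 * psi2)^2) * dx
  p_lo
}

# Brute-force RK4 integration of the driven two-level Schroedinger equation
# for a real cos-carrier field whose positive-frequency spectrum is the
# package's Gaussian envelope. Returns the final excited amplitude modulus.
driven_two_level_amplitude <- function(omega10, mu, pulse, dt = 0.02) {
  s <- pulse$sigma_au
  wL <- pulse$omega_L_au
  E0 <- pulse$amplitude
  Afield <- E0 * s * sqrt(2 / pi)
  Et <- function(t) Afield * exp(-s^2 * t^2 / 2) * cos(wL * t)
  deriv <- function(t, cvec) {
    V <- -mu * Et(t)
    c(-1i * (V * cvec[2]), -1i * (omega10 * cvec[2] + V * cvec[1]))
  }
  tmax <- 8 / s
  cvec <- c(1 + 0i, 0 + 0i)
  t <- -tmax
  n <- ceiling(2 * tmax / dt)
  for (i in seq_len(n)) {
    k1 <- deriv(t, cvec)
    k2 <- deriv(t + dt / 2, cvec + dt / 2 * k1)
    k3 <- deriv(t + dt / 2, cvec + dt / 2 * k2)
    k4 <- deriv(t + dt, cvec + dt * k3)
    cvec <- cvec + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  Mod(cvec[2])
}

# Monte-Carlo standard error of a weighted mean (normalized form)
weighted_mean_se <- function(x, w) {
  W <- sum(w)
  m <- sum(w * x) / W
  sqrt(sum(w^2 * (x - m)^2)) / W
}
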