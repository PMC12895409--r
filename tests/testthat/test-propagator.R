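# Single-trajectory engine: velocity Verlet, local-diabatic electronic
# propagation, population-flux hopping, decoherence, and full-cycle properties.

test_that("velocity Verlet is exact on a flat surface and symplectic on a harmonic one", {
  flat <- diabatic_model(2, 1,
    potential = function(R) diag(c(0.1, 0.4)),
    gradient = function(R) array(0, c(2, 2, 1)),
    dipole = function(R) array(0, c(2, 2, 3)))
  cfg <- propagator_config(dt_fs = 0.1, t_final_fs = 1)
  st <- make_initial_state(flat, R = 0, P = 0.3, active = 1)
  st1 <- nuclear_step(st, flat, cfg)
  expect_equal(st1$R, 0.3 * cfg$dt_au, tolerance = 1e-14)
  expect_equal(st1$P, 0.3)

  # 1000 steps on omega = 1 harmonic surface: energy drift < 1e-6 a.u.
  harm <- lvc_model(1, c(0, 1))
  cfgh <- propagator_config(dt_fs = 0.01 * 0.02418884, n_substeps = 1L,
                            t_final_fs = 10 * 0.02418884)
  amp <- 0.3
  sth <- make_initial_state(harm, R = amp, P = 0, active = 1)
  e0 <- sum(sth$P^2) / 2 + sth$es$energies[1]
  for (i in 1:1000) sth <- nuclear_step(sth, harm, cfgh)
  e1 <- sum(sth$P^2) / 2 + sth$es$energies[1]
  expect_lt(abs(e1 - e0), 1e-6)
  # and the phase-space point follows the exact oscillation
  expect_equal(sth$R, amp * cos(10), tolerance = 1e-3)

  # zero momentum at the minimum stays put
  st0 <- make_initial_state(harm, R = 0, P = 0, active = 1)
  st0b <- nuclear_step(st0, harm, cfgh)
  expect_equal(st0b$R, 0, tolerance = 1e-14)
  expect_equal(st0b$P, 0, tolerance = 1e-14)
})

test_that("electronic propagation reproduces closed-form two-level dynamics", {
  # pure phase evolution: diagonal constant H
  E <- c(0, 0.3)
  v0 <- c(1, 1) / sqrt(2) + 0i
  for (tt in c(5, 12.4, 30)) {
    v <- propagate_piecewise(v0, diag(E), diag(E), tt, 51L)
    expect_equal(v, v0 * exp(-1i * E * tt), tolerance = 1e-12)
    expect_equal(Re(Conj(v[1]) * v[2]), 0.5 * cos(0.3 * tt), tolerance = 1e-12)
  }
  # Rabi transfer under a constant off-diagonal coupling
  cc <- 0.02
  H <- matrix(c(0, cc, cc, 0), 2, 2)
  for (tt in c(10, 40, 77)) {
    v <- propagate_piecewise(c(1 + 0i, 0), H, H, tt, 51L)
    expect_equal(Mod(v[2])^2, sin(cc * tt)^2, tolerance = 1e-6)
  }
  # unitary to machine precision per substep
  set.seed(3)
  H0 <- crossprod(matrix(rnorm(9), 3))
  H1 <- crossprod(matrix(rnorm(9), 3))
  v0 <- complex(real = rnorm(3), imaginary = rnorm(3))
  v0 <- v0 / sqrt(sum(Mod(v0)^2))
  v <- propagate_piecewise(v0, H0, H1, 12.4, 51L)
  expect_equal(sum(Mod(v)^2), 1, tolerance = 1e-12)
})

test_that("electronic_step leaves populations exact in the adiabatic limit", {
  m <- avoided_crossing_model(A = 0.01, c = 0.005)
  es1 <- evaluate_model(m, -4)
  es2 <- phase_align(evaluate_model(m, -4), es1)  # same geometry: S = identity
  cfg <- propagator_config()
  v0 <- c(sqrt(0.3), sqrt(0.7)) + 0i
  v <- electronic_step(v0, es1, es2, cfg)
  expect_equal(Mod(v)^2, Mod(v0)^2, tolerance = 1e-12)
  expect_error(electronic_step(v0, es1, evaluate_model(m, -4), cfg),
               "no overlap")
})

test_that("population-flux hop probabilities apportion gains correctly", {
  expect_equal(hop_probabilities(c(1, 0) + 0i, c(1, 0) + 0i, 1), c(0, 0))
  # active 0.8 -> 0.6, single gainer takes it all
  cb <- sqrt(c(0.8, 0.2)) + 0i
  ca <- sqrt(c(0.6, 0.4)) + 0i
  expect_equal(hop_probabilities(cb, ca, 1), c(0, 0.25))
  # two gainers split proportionally
  cb3 <- sqrt(c(0.8, 0.15, 0.05)) + 0i
  ca3 <- sqrt(c(0.6, 0.30, 0.10)) + 0i
  expect_equal(hop_probabilities(cb3, ca3, 1), c(0, 0.1875, 0.0625))
  # zero active population: all zero
  expect_equal(hop_probabilities(c(0, 1) + 0i, c(0.5, 0.5) + 0i, 1), c(0, 0))
  # probabilities never exceed 1 in total
  set.seed(5)
  for (rep in 1:50) {
    p0 <- abs(rnorm(3)); p0 <- p0 / sum(p0)
    p1 <- abs(rnorm(3)); p1 <- p1 / sum(p1)
    pr <- hop_probabilities(sqrt(p0) + 0i, sqrt(p1) + 0i, 1)
    expect_true(all(pr >= 0) && sum(pr) <= 1 + 1e-12)
  }
})

test_that("hops conserve energy exactly and frustrated hops do nothing", {
  m <- avoided_crossing_model(A = 0.02, c = 0.002)
  # downhill hop: gap recovered as kinetic energy
  st <- make_initial_state(m, R = 5, P = sqrt(2 * 0.2), active = 2)
  gap <- st$es$energies[2] - st$es$energies[1]
  st2 <- attempt_hop(st, probs = c(1, 0), u = 0.5)
  expect_true(st2$hop$accepted)
  expect_equal(st2$active, 1L)
  expect_equal(sum(st2$P^2) / 2, 0.2 + gap, tolerance = 1e-12)
  e_tot <- function(s) sum(s$P^2) / 2 + s$es$energies[s$active]
  expect_equal(e_tot(st2), e_tot(st), tolerance = 1e-12)
  # uphill hop without enough kinetic energy is frustrated
  stu <- make_initial_state(m, R = 5, P = sqrt(2 * 0.05), active = 1)
  stu2 <- attempt_hop(stu, probs = c(0, 1), u = 0.5)
  expect_false(stu2$hop$accepted)
  expect_equal(stu2$active, 1L)
  expect_equal(stu2$P, stu$P)
  # zero probabilities never change the state
  st3 <- attempt_hop(st, probs = c(0, 0), u = 0.01)
  expect_null(st3$hop)
  expect_equal(st3$active, st$active)
})

test_that("decoherence corrections damp inactive amplitudes as specified", {
  m <- avoided_crossing_model(A = 0.02, c = 0.002)
  mk <- function(p_kin) {
    st <- make_initial_state(m, R = 2.5, P = sqrt(2 * p_kin), active = 2,
                             coeffs = sqrt(c(0.5, 0.5)) + 0i)
    st
  }
  # scheme none: untouched
  stn <- apply_decoherence(mk(0.05), decoherence_config("none"), 12.4)
  expect_equal(stn$coeffs, sqrt(c(0.5, 0.5)) + 0i)
  # EDC: direct evaluation of the damping factor, gap 0.1, Ekin 0.05, C = 0.1
  m2 <- diabatic_model(2, 1,
    potential = function(R) diag(c(0, 0.1)),
    gradient = function(R) array(0, c(2, 2, 1)),
    dipole = function(R) array(0, c(2, 2, 3)))
  st <- make_initial_state(m2, R = 0, P = sqrt(2 * 0.05), active = 2,
                           coeffs = sqrt(c(0.5, 0.5)) + 0i)
  std <- apply_decoherence(st, decoherence_config("EDC", edc_C = 0.1), 12.4)
  expect_equal(Mod(std$coeffs[1]), sqrt(0.5) * exp(-12.4 / 30), tolerance = 1e-12)
  expect_equal(sum(Mod(std$coeffs)^2), 1, tolerance = 1e-12)
  # EDC with zero kinetic energy: infinite time constant, no damping
  st0 <- make_initial_state(m2, R = 0, P = 0, active = 2,
                            coeffs = sqrt(c(0.5, 0.5)) + 0i)
  st0d <- apply_decoherence(st0, decoherence_config("EDC"), 12.4)
  expect_equal(st0d$coeffs, st0$coeffs)
  # PFM surrogate with identical forces on both states (flat parallel
  # surfaces): offsets never grow, coherence undamped
  stp0 <- make_initial_state(m2, R = 0, P = sqrt(2 * 0.05), active = 2,
                             coeffs = sqrt(c(0.5, 0.5)) + 0i)
  stp <- apply_decoherence(stp0, decoherence_config("PFM"), 12.4)
  expect_equal(Mod(stp$coeffs)^2, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(stp$aux$dp, c(0, 0))
})

test_that("norm stays unit and energy conserved along full trajectories", {
  gl <- glycine_like_model()
  s <- sample_wigner(gl$reference, 4, seed = 21)
  cfg <- propagator_config()
  for (scheme in c("none", "EDC", "PFM")) {
    rec <- propagate_trajectory(
      make_initial_state(gl$model, s$Q[1, ], s$P[1, ], active = 4),
      gl$model, cfg, decoherence_config(scheme), seed = 31)
    expect_true(rec$valid)
    expect_lt(max(abs(rowSums(Mod(rec$coeffs)^2) - 1)), 1e-8)
    etot <- rec$ekin + rec$energies[cbind(seq_len(nrow(rec$energies)), rec$active)]
    expect_lt(au_to_ev(max(abs(etot - etot[1]))), 0.5)
  }
})

test_that("single-surface dynamics never hops and keeps populations constant", {
  m <- lvc_model(c(0.01, 0.02), c(0, 0.25, 0.3))  # no interstate coupling
  ref <- harmonic_reference(c(0.01, 0.02))
  s <- sample_wigner(ref, 3, seed = 4)
  cfg <- propagator_config()
  rec <- propagate_trajectory(
    make_initial_state(m, s$Q[1, ], s$P[1, ], active = 2),
    m, cfg, decoherence_config("none"), seed = 8)
  expect_true(rec$valid)
  expect_equal(unique(rec$active), 2L)
  expect_equal(nrow(rec$hops), 0L)
  expect_lt(max(abs(Mod(rec$coeffs[, 2])^2 - 1)), 1e-10)
})

test_that("propagation is deterministic for a fixed seed", {
  gl <- glycine_like_model()
  s <- sample_wigner(gl$reference, 1, seed = 2)
  cfg <- propagator_config(t_final_fs = 6)
  st <- make_initial_state(gl$model, s$Q[1, ], s$P[1, ], active = 4)
  r1 <- propagate_trajectory(st, gl$model, cfg, decoherence_config("PFM"), seed = 77)
  r2 <- propagate_trajectory(st, gl$model, cfg, decoherence_config("PFM"), seed = 77)
  expect_identical(r1$coeffs, r2$coeffs)
  expect_identical(r1$R, r2$R)
  expect_identical(r1$hops, r2$hops)
})

test_that("surface-hopping statistics match an exact wave-packet reference", {
  fx <- fixture_scattering()
  p_lo_exact <- split_operator_lower_population(
    A = 0.005, c = 0.03, x0 = -15, p0 = fx$p0, sigma_x = 5, t_final = 32)
  s <- scattering_ensemble(fx, 500, seed = 14)
  # bare hopping: the hopping statistics themselves are under test, and a
  # decoherence correction deliberately alters the coefficient flow
  dcfg <- decoherence_config("none")
  n_lo <- 0
  for (j in seq_len(s$n)) {
    rec <- propagate_trajectory(
      make_initial_state(fx$model, s$Q[j, ], s$P[j, ], active = 1),
      fx$model, fx$cfg, dcfg, seed = 1000 + j)
    if (rec$active[rec$n_done + 1] == 1) n_lo <- n_lo + 1
  }
  expect_lt(abs(n_lo / s$n - p_lo_exact), 0.05)
})
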