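# Ensemble construction, Table-of-weights, pulse independence and balancing.

test_that("FP ensemble draws active states from the pump populations", {
  # single excited state: active always that state
  m1 <- lvc_model(0.01, c(0, 0.25), dip0 = {
    d <- array(0, c(2, 2, 3)); d[1, 2, ] <- d[2, 1, ] <- c(0, 0, 1); d
  })
  ref <- harmonic_reference(0.01)
  s <- sample_wigner(ref, 50, seed = 3)
  p <- gaussian_pulse(au_to_ev(0.25), 2.0)
  spec <- build_fp(s, m1, p, seed = 5)
  expect_true(all(spec$members$active0 == 2))
  expect_equal(Mod(spec$init_coeffs[1, ]), c(0, 1))

  # two equally excited states: fractions 0.5 within binomial error
  fx <- fixture_two_state()
  meq <- lvc_model(c(0.010, 0.016), ev_to_au(c(0, 7.0, 7.0 + 1e-4)),
                   dip0 = {
                     d <- array(0, c(3, 3, 3))
                     d[1, 2, ] <- d[2, 1, ] <- c(0, 0, 0.5)
                     d[1, 3, ] <- d[3, 1, ] <- c(0, 0, 0.5)
                     d
                   })
  s2 <- sample_wigner(fx$reference, 10000, seed = 8)
  sp2 <- build_fp(s2, meq, gaussian_pulse(7.0, 2.83), seed = 9)
  frac <- mean(sp2$members$active0 == 2)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("FP weights scale quadratically with the field and sum to the mean excitation", {
  fx <- fixture_two_state()
  s <- sample_wigner(fx$reference, 40, seed = 12)
  sp1 <- build_fp(s, fx$model, fx$pulse, seed = 1)
  p2 <- gaussian_pulse(fx$pulse$omega_L_eV, fx$pulse$delta_omega_eV,
                       fx$pulse$polarization, amplitude = 2)
  sp2 <- build_fp(s, fx$model, p2, seed = 1)
  expect_equal(sp2$members$weight, 4 * sp1$members$weight, tolerance = 1e-12)
  # sum of weights = mean over geometries of the total excited population
  expect_equal(sum(sp1$members$weight), mean(sp1$members$t0_population) *
                 nrow(sp1$members) / s$n, tolerance = 1e-12)
  # normalized coefficients unchanged by the field strength
  expect_equal(sp2$init_coeffs, sp1$init_coeffs, tolerance = 1e-12)
})

test_that("AXE enumerates every excited state per geometry, pulse-independently", {
  fx <- fixture_two_state()
  s <- sample_wigner(fx$reference, 100, seed = 2)
  spec <- build_axe(s, 4)
  expect_equal(nrow(spec$members), 300)
  expect_true(all(table(spec$members$g) == 3))
  # delta initial coefficients
  expect_equal(Mod(spec$init_coeffs[cbind(seq_len(300), spec$members$a)]),
               rep(1, 300))
  # attaching two different pulses changes weights, not members
  spec3 <- build_axe(s, 3)
  w1 <- attach_pulse_weights(spec3, fx$model, fx$pulse)
  p2 <- gaussian_pulse(6.9, 1.59, c(0, 0, 1))
  w2 <- attach_pulse_weights(spec3, fx$model, p2)
  expect_identical(w1$members[c("g", "a", "active0")],
                   w2$members[c("g", "a", "active0")])
  expect_false(isTRUE(all.equal(w1$members$weight, w2$members$weight)))
  # a pulse that cannot excite leaves all weights zero (members kept)
  py <- gaussian_pulse(7.4, 2.83, polarization = c(0, 1, 0))
  wy <- attach_pulse_weights(spec3, fx$model, py)
  expect_equal(nrow(wy$members), 200)
  expect_equal(wy$members$weight, rep(0, 200))
})

test_that("SXE acceptance follows the oscillator strengths", {
  # constant f ratio 1:4 via dipole ratio 1:2 at equal transition energy
  m <- lvc_model(0.01, c(0, 0.3, 0.3 + 1e-9), dip0 = {
    d <- array(0, c(3, 3, 3))
    d[1, 2, ] <- d[2, 1, ] <- c(0.3, 0, 0)
    d[1, 3, ] <- d[3, 1, ] <- c(0.6, 0, 0)
    d
  })
  ref <- harmonic_reference(0.01)
  s <- sample_wigner(ref, 20000, seed = 6)
  spec <- build_sxe(s, m, seed = 7)
  counts <- table(factor(spec$members$a, levels = 2:3))
  # brighter state accepted with probability 1, dimmer with ~1/4
  expect_equal(unname(counts[["3"]]), 20000)
  expect_lt(abs(counts[["2"]] / counts[["3"]] - 0.25), 0.25 * 0.05)
  expect_equal(spec$alpha_bar, nrow(spec$members) / 20000)

  # dark state never sampled
  mdark <- lvc_model(0.01, c(0, 0.3, 0.35), dip0 = {
    d <- array(0, c(3, 3, 3)); d[1, 3, ] <- d[3, 1, ] <- c(0.5, 0, 0); d
  })
  sd <- sample_wigner(ref, 500, seed = 6)
  specd <- build_sxe(sd, mdark, seed = 7)
  expect_true(all(specd$members$a == 3))

  # all-equal strengths in a window are always accepted
  expect_true(all(specd$members$p_bar == 1))
})

test_that("SXE energy windows stratify the acceptance", {
  # two states far apart in energy with very different brightness; without
  # windows the dim state is rare, with a separating window both are kept
  m <- lvc_model(0.01, ev_to_au(c(0, 6.5, 9.0)), dip0 = {
    d <- array(0, c(3, 3, 3))
    d[1, 2, ] <- d[2, 1, ] <- c(0.1, 0, 0)
    d[1, 3, ] <- d[3, 1, ] <- c(1.0, 0, 0)
    d
  })
  ref <- harmonic_reference(0.01)
  s <- sample_wigner(ref, 2000, seed = 10)
  one <- build_sxe(s, m, seed = 11)
  two <- build_sxe(s, m, windows = 8.30, seed = 11)
  n_dim_one <- sum(one$members$a == 2)
  n_dim_two <- sum(two$members$a == 2)
  expect_lt(n_dim_one, 100)        # heavily biased against the dim state
  expect_equal(n_dim_two, 2000)    # per-window renormalization rescues it
  expect_equal(length(two$N_bar), 2)
})

test_that("attached weights implement the scheme definitions", {
  fx <- fixture_two_state()
  s <- sample_wigner(fx$reference, 60, seed = 13)
  # FP row: w_g = (sum_k |c_k|^2) / N_g
  fp <- attach_pulse_weights(build_fp(s, fx$model, fx$pulse, seed = 1),
                             fx$model, fx$pulse)
  expect_equal(fp$members$weight, fp$members$t0_population / s$n,
               tolerance = 1e-12)
  # SXE row: w = (alpha / N_t) |c_a|^2 / p_a
  sxe <- attach_pulse_weights(build_sxe(s, fx$model, seed = 2),
                              fx$model, fx$pulse)
  i <- which(sxe$members$p_bar == 1)[1]
  g <- sxe$members$g[i]
  a <- sxe$members$a[i]
  pa <- Mod(first_order_amplitudes(evaluate_model(fx$model, s$Q[g, ]),
                                   fx$pulse)$values[a])^2
  expect_equal(sxe$members$weight[i],
               sxe$alpha_bar / nrow(sxe$members) * pa, tolerance = 1e-12)
})

test_that("AXE and SXE weighted averages estimate the same expectation", {
  fx <- fixture_two_state()
  s <- sample_wigner(fx$reference, 2000, seed = 17)
  axe <- attach_pulse_weights(build_axe(s, 3), fx$model, fx$pulse)
  sxe <- attach_pulse_weights(build_sxe(s, fx$model, seed = 18),
                              fx$model, fx$pulse)
  # a fixed, bounded per-member function of (geometry, state)
  h <- function(members) tanh(s$Q[members$g, 1] / 5) * members$a
  ma <- sum(axe$members$weight * h(axe$members)) / sum(axe$members$weight)
  ms <- sum(sxe$members$weight * h(sxe$members)) / sum(sxe$members$weight)
  se <- weighted_mean_se(h(sxe$members), sxe$members$weight) +
    weighted_mean_se(h(axe$members), axe$members$weight)
  expect_lt(abs(ma - ms), 2 * se + 1e-12)
})

test_that("balancing preserves initial-state ratios (FP/SXE) and drops AXE geometries", {
  fx <- fixture_two_state()
  s <- sample_wigner(fx$reference, 30, seed = 19)
  axe <- build_axe(s, 3)
  # all valid: unchanged
  all_ok <- balance_ensemble(axe, rep(TRUE, nrow(axe$members)))
  expect_equal(nrow(all_ok$members), nrow(axe$members))
  # one invalid member removes its whole geometry
  v <- rep(TRUE, nrow(axe$members))
  bad <- which(axe$members$g == 7 & axe$members$a == 3)
  v[bad] <- FALSE
  b <- balance_ensemble(axe, v)
  expect_false(any(b$members$g == 7))
  expect_equal(nrow(b$members), nrow(axe$members) - 2)

  # FP: 10% invalid all in state 3 with initial ratio 1:1 -> state-2 thinned
  members <- data.frame(g = 1:200, a = NA_integer_,
                        active0 = rep(c(2, 3), each = 100),
                        t0_population = 1, weight = 1 / 200,
                        p_bar = NA_real_, window = NA_integer_)
  spec <- structure(list(scheme = "FP", members = members,
                         init_coeffs = matrix(0 + 0i, 200, 3),
                         samples = sample_wigner(fx$reference, 200, seed = 1),
                         n_states = 3, N_g = 200),
                    class = "ensemble_spec")
  v <- rep(TRUE, 200)
  v[members$active0 == 3][1:20] <- FALSE
  bb <- balance_ensemble(spec, v, seed = 4)
  tab <- table(bb$members$active0)
  expect_equal(unname(tab[["2"]]), 80)
  expect_equal(unname(tab[["3"]]), 80)
})
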