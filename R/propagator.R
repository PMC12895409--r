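# Single-trajectory surface-hopping engine: velocity-Verlet nuclear steps on
# the active adiabatic surface, local-diabatic electronic propagation with
# unitary substeps, population-flux hopping with uniform momentum rescaling,
# and per-trajectory decoherence corrections (energy-based or a frozen-Gaussian
# projected-forces surrogate). Everything a later electronic-only repropagation
# needs is stored step by step in the trajectory record.

RECORD_SCHEMA_VERSION <- 1L

#' Propagation parameters
#'
#' Defaults are the standard operating point of the method: nuclear step
#' 0.3 fs, 51 electronic substeps per nuclear step, 14.1 fs of dynamics, and an
#' energy-conservation tolerance of 0.5 eV beyond which a trajectory is
#' discarded.
#'
#' @param dt_fs nuclear time step in fs.
#' @param n_substeps electronic substeps per nuclear step.
#' @param t_final_fs total propagation time in fs.
#' @param energy_tolerance_eV allowed total-energy drift before a trajectory is
#'   marked invalid.
#' @param seed integer seed for the hopping random stream.
#' @return an object of class `propagator_config`.
#' @export
propagator_config <- function(dt_fs = 0.3, n_substeps = 51L, t_final_fs = 14.1,
                              energy_tolerance_eV = 0.5, seed = 1L) {
  if (dt_fs <= 0) stop("dt_fs must be > 0")
  if (n_substeps < 1) stop("n_substeps must be >= 1")
  structure(list(dt_fs = dt_fs, n_substeps = as.integer(n_substeps),
                 t_final_fs = t_final_fs,
                 energy_tolerance_eV = energy_tolerance_eV,
                 seed = as.integer(seed),
                 dt_au = fs_to_au(dt_fs),
                 n_steps = as.integer(round(t_final_fs / dt_fs))),
            class = "propagator_config")
}

#' Decoherence correction parameters
#'
#' * `"none"`: bare surface hopping (known to overestimate coherences).
#' * `"EDC"`: energy-based decoherence; each inactive amplitude decays with
#'   time constant `tau_i = (1 + edc_C / E_kin) / |E_i - E_b|`.
#' * `"PFM"`: frozen-Gaussian surrogate of the projected forces-and-momenta
#'   correction: per inactive state, auxiliary position/momentum offsets along
#'   the unit velocity integrate the projected force difference to the active
#'   state, and the coherence is damped by the Gaussian-overlap factor
#'   `exp(-(w/4) ds^2 - dp^2/(4 w))` each step; offsets reset at hops and when
#'   the state population falls below `eta`.
#'
#' @param scheme one of `"none"`, `"EDC"`, `"PFM"`.
#' @param omega_pfm Gaussian width/frequency parameter in hartree (default the
#'   geometric-mean vibrational frequency 4.825e-3).
#' @param eta population threshold below which a state's auxiliary variables
#'   are not propagated.
#' @param edc_C kinetic-energy constant of the EDC formula, hartree.
#' @return an object of class `decoherence_config`.
#' @export
decoherence_config <- function(scheme = c("none", "EDC", "PFM"),
                               omega_pfm = 4.825e-3, eta = 1e-4, edc_C = 0.1) {
  scheme <- match.arg(scheme)
  if (omega_pfm <= 0) stop("omega_pfm must be > 0")
  if (eta < 0 || eta >= 1) stop("eta must be in [0, 1)")
  structure(list(scheme = scheme, omega_pfm = omega_pfm, eta = eta,
                 edc_C = edc_C),
            class = "decoherence_config")
}

#' Assemble the state of one trajectory at a time point
#'
#' @param model a `diabatic_model`.
#' @param R,P mass-weighted positions and momenta (a.u.).
#' @param active initial active adiabatic state (1-based; 1 = ground).
#' @param coeffs complex amplitude vector or `amplitude_vector` (length
#'   `n_states`); defaults to a delta on the active state.
#' @return an object of class `trajectory_state`.
#' @export
make_initial_state <- function(model, R, P, active, coeffs = NULL) {
  es <- evaluate_model(model, R)
  ns <- model$n_states
  if (is.null(coeffs)) {
    v <- complex(real = numeric(ns))
    v[active] <- 1
  } else {
    v <- if (inherits(coeffs, "amplitude_vector")) coeffs$values else as.complex(coeffs)
    if (length(v) != ns) stop("coefficient vector length must equal n_states")
  }
  structure(list(t_au = 0, R = as.numeric(R), P = as.numeric(P),
                 active = as.integer(active), coeffs = v, es = es,
                 aux = list(ds = numeric(ns), dp = numeric(ns))),
            class = "trajectory_state")
}

#' Velocity-Verlet nuclear step on the active surface
#'
#' Advances positions and momenta by one nuclear time step using the
#' Hellmann-Feynman gradient of the active adiabatic state at both ends
#' (symplectic velocity Verlet, unit masses), evaluates the electronic
#' structure at the new geometry and phase-aligns it with the previous step.
#' Electronic coefficients are not touched.
#'
#' @param state a `trajectory_state` whose `es` matches its `R`.
#' @param model a `diabatic_model`.
#' @param cfg a `propagator_config`.
#' @return the advanced `trajectory_state`.
#' @export
nuclear_step <- function(state, model, cfg) {
  dt <- cfg$dt_au
  F0 <- -state$es$gradients[state$active, ]
  if (any(!is.finite(F0))) stop("non-finite forces on the active surface")
  Rn <- state$R + state$P * dt + 0.5 * F0 * dt^2
  es_new <- phase_align(evaluate_model(model, Rn), state$es)
  F1 <- -es_new$gradients[state$active, ]
  Pn <- state$P + 0.5 * (F0 + F1) * dt
  state$R <- Rn
  state$P <- Pn
  state$es <- es_new
  state$t_au <- state$t_au + dt
  state
}

# Loewdin orthogonalization T = S (S'S)^(-1/2) of the inter-step overlap matrix
lowdin <- function(S) {
  M <- crossprod(S)
  ee <- eigen(M, symmetric = TRUE)
  if (min(ee$values) < 1e-12)
    stop("singular overlap matrix: trivial crossing unresolved at this time step")
  S %*% (ee$vectors %*% (t(ee$vectors) / sqrt(ee$values)))
}

# Core local-diabatic electronic update over one nuclear step.
# c is expressed in the adiabatic basis at t; the local diabatic frame is the
# t-adiabatic basis held fixed, in which H(t) = diag(E0) and
# H(t+dt) = T diag(E1) T'; H is interpolated linearly across the substeps and
# each substep applies an exact unitary exponential. The result is transformed
# to the adiabatic basis at t+dt.
ld_step <- function(coeffs, E0, E1, Tm, dt, n_substeps) {
  H1 <- Tm %*% (E1 * t(Tm))
  c_dia <- cpp_interp_propagate(coeffs, diag(E0, length(E0)), H1, dt, n_substeps)
  drop(crossprod(Tm, c_dia))
}

#' Electronic coefficient propagation over one nuclear step
#'
#' Integrates the electronic Schroedinger equation between two consecutive,
#' phase-aligned electronic-structure points in the local diabatic basis
#' obtained by Loewdin-orthogonalizing the inter-step overlap matrix. The
#' propagation is unitary to machine precision.
#'
#' @param coeffs complex amplitude vector (adiabatic basis at the previous
#'   step) or an `amplitude_vector`.
#' @param es_prev,es_next consecutive `es_point`s; `es_next$S` must have been
#'   filled by [phase_align()].
#' @param cfg a `propagator_config` (supplies `dt_au` and `n_substeps`).
#' @return the complex amplitude vector in the adiabatic basis at the new step.
#' @export
electronic_step <- function(coeffs, es_prev, es_next, cfg) {
  if (is.null(es_next$S)) stop("es_next carries no overlap to the previous step")
  v <- if (inherits(coeffs, "amplitude_vector")) coeffs$values else as.complex(coeffs)
  Tm <- lowdin(es_next$S)
  ld_step(v, es_prev$energies, es_next$energies, Tm, cfg$dt_au, cfg$n_substeps)
}

#' Piecewise-exact propagation under a linearly interpolated Hamiltonian
#'
#' Low-level access to the substep propagator: evolves a complex coefficient
#' vector under `H(s) = (1-s) H0 + s H1` using `n_substeps` midpoint
#' exponentials. Useful for validating against closed-form two-level dynamics.
#'
#' @param coeffs complex vector.
#' @param H0,H1 real symmetric matrices (a.u.).
#' @param dt total time (a.u.).
#' @param n_substeps number of substeps.
#' @return the propagated complex vector.
#' @export
propagate_piecewise <- function(coeffs, H0, H1, dt, n_substeps = 51L) {
  drop(cpp_interp_propagate(as.complex(coeffs), H0, H1, dt,
                            as.integer(n_substeps)))
}

#' Hopping probabilities from the population flux
#'
#' The probability to leave the active state over a nuclear step is the
#' relative loss of its population, `max(0, (p_b(t) - p_b(t+dt)) / p_b(t))`,
#' apportioned among the states whose population increased in proportion to
#' their gains.
#'
#' @param coeffs_before,coeffs_after complex amplitude vectors before and after
#'   the electronic step.
#' @param active active state index.
#' @return vector of per-state hop probabilities (zero for the active state);
#'   sums to at most 1.
#' @export
hop_probabilities <- function(coeffs_before, coeffs_after, active) {
  p0 <- Mod(as.complex(coeffs_before))^2
  p1 <- Mod(as.complex(coeffs_after))^2
  probs <- numeric(length(p0))
  if (p0[active] <= 0) return(probs)
  p_leave <- max(0, (p0[active] - p1[active]) / p0[active])
  if (p_leave == 0) return(probs)
  gains <- pmax(0, p1 - p0)
  gains[active] <- 0
  if (sum(gains) == 0) return(probs)
  p_leave * gains / sum(gains)
}

#' Attempt a stochastic hop with energy-conserving momentum rescaling
#'
#' Draws a uniform variate against the cumulative hop probabilities. On an
#' accepted hop the full momentum vector is rescaled uniformly (along the
#' velocity direction) so total energy is conserved exactly; an energetically
#' forbidden (frustrated) hop leaves state and momentum unchanged.
#'
#' @param state a `trajectory_state` whose `es` matches its geometry.
#' @param probs per-state hop probabilities from [hop_probabilities()].
#' @param u uniform random number in `[0, 1)`; drawn from the session RNG when
#'   omitted.
#' @return the (possibly) updated `trajectory_state`, with a `hop` entry
#'   describing the event (`NULL` when no target was selected).
#' @export
attempt_hop <- function(state, probs, u = runif(1)) {
  state$hop <- NULL
  cum <- cumsum(probs)
  k <- which(u < cum)[1]
  if (is.na(k)) return(state)
  gap <- state$es$energies[k] - state$es$energies[state$active]
  ekin <- sum(state$P^2) / 2
  if (ekin > 0 && ekin >= gap) {
    state$hop <- list(from = state$active, to = k, accepted = TRUE)
    state$P <- state$P * sqrt((ekin - gap) / ekin)
    state$active <- as.integer(k)
  } else {
    state$hop <- list(from = state$active, to = k, accepted = FALSE)
  }
  state
}

# One decoherence application on a coefficient vector.
# dec carries the stored step context: active state, |E_i - E_b| gaps, kinetic
# energy, projected force differences (F_i - F_b) . vhat, and whether a hop
# happened this step. aux holds the PFM offsets. Shared verbatim between
# propagation and repropagation so that replays are bit-identical.
decohere_step <- function(coeffs, aux, dec, dcfg, dt) {
  if (dcfg$scheme == "none") return(list(coeffs = coeffs, aux = aux))
  b <- dec$active
  ns <- length(coeffs)
  inactive <- setdiff(seq_len(ns), b)
  if (dcfg$scheme == "EDC") {
    if (dec$ekin > 0) {
      for (i in inactive) {
        if (dec$gaps[i] > 0) {
          tau <- (1 / dec$gaps[i]) * (1 + dcfg$edc_C / dec$ekin)
          coeffs[i] <- coeffs[i] * exp(-dt / tau)
        }
      }
    }
  } else { # PFM frozen-Gaussian surrogate
    if (isTRUE(dec$hop)) {
      aux$ds[] <- 0
      aux$dp[] <- 0
    }
    pops <- Mod(coeffs)^2
    w <- dcfg$omega_pfm
    for (i in inactive) {
      if (pops[i] < dcfg$eta) {
        aux$ds[i] <- 0
        aux$dp[i] <- 0
        next
      }
      aux$dp[i] <- aux$dp[i] + dec$fproj[i] * dt
      aux$ds[i] <- aux$ds[i] + aux$dp[i] * dt
      coeffs[i] <- coeffs[i] *
        exp(-(w / 4) * aux$ds[i]^2 - aux$dp[i]^2 / (4 * w))
    }
    aux$ds[b] <- 0
    aux$dp[b] <- 0
  }
  # restore unit norm through the active amplitude
  p_in <- sum(Mod(coeffs[inactive])^2)
  p_b <- Mod(coeffs[b])^2
  if (p_b > 0) {
    coeffs[b] <- coeffs[b] * sqrt(max(0, 1 - p_in) / p_b)
  } else if (p_in > 0) {
    coeffs <- coeffs / sqrt(p_in)
  }
  list(coeffs = coeffs, aux = aux)
}

#' Apply the configured decoherence correction to a trajectory state
#'
#' Damps inactive amplitudes according to the chosen scheme and restores unit
#' norm through the active amplitude. See [decoherence_config()] for the
#' formulas.
#'
#' @param state a `trajectory_state` (uses its coefficients, active state,
#'   energies, momenta and PFM auxiliary offsets).
#' @param dcfg a `decoherence_config`.
#' @param dt time interval of the application, a.u.
#' @return the updated `trajectory_state`.
#' @export
apply_decoherence <- function(state, dcfg, dt) {
  dec <- step_decoherence_data(state$es, state$active, state$P,
                               hop = FALSE)
  res <- decohere_step(state$coeffs, state$aux, dec, dcfg, dt)
  state$coeffs <- res$coeffs
  state$aux <- res$aux
  state
}

# Decoherence context derived from an electronic-structure point. ekin is
# computed as sum(P^2)/2 directly (not via |P|) so a repropagation replay from
# the stored value is bit-identical.
step_decoherence_data <- function(es, active, P, hop) {
  p2 <- sum(P^2)
  vhat <- if (p2 > 0) P / sqrt(p2) else numeric(length(P))
  # forces F_i = -grad E_i; projected difference (F_i - F_b) . vhat
  fproj <- as.numeric((-es$gradients + rep(es$gradients[active, ],
                                           each = nrow(es$gradients))) %*% vhat)
  list(active = active,
       gaps = abs(es$energies - es$energies[active]),
       ekin = p2 / 2,
       fproj = fproj,
       hop = hop)
}

#' Propagate one surface-hopping trajectory
#'
#' Runs the nuclear / electronic / hop / decoherence cycle from `t = 0` to
#' `t_final`, storing at every step everything a later electronic-only
#' repropagation needs: energies, local-diabatic propagator matrices, adiabatic
#' dipole matrices, active state, kinetic energy and projected force
#' differences. A trajectory whose total (kinetic + active potential) energy
#' drifts beyond the configured tolerance is marked invalid and truncated.
#'
#' @param initial a `trajectory_state` from [make_initial_state()].
#' @param model the `diabatic_model`.
#' @param cfg a `propagator_config`.
#' @param dcfg a `decoherence_config`.
#' @param seed integer seed for this trajectory's hopping stream (defaults to
#'   `cfg$seed`).
#' @return an object of class `trajectory_record`.
#' @export
propagate_trajectory <- function(initial, model, cfg,
                                 dcfg = decoherence_config("none"),
                                 seed = cfg$seed) {
  ns <- model$n_states
  nm <- model$n_modes
  n <- cfg$n_steps
  dt <- cfg$dt_au
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  Rm <- matrix(NA_real_, n + 1, nm)
  Pm <- matrix(NA_real_, n + 1, nm)
  act <- integer(n + 1)
  En <- matrix(NA_real_, n + 1, ns)
  ekin <- rep(NA_real_, n + 1)
  Cm <- matrix(NA_complex_, n + 1, ns)
  Tl <- vector("list", n)
  Fp <- matrix(NA_real_, n + 1, ns)
  hopflag <- rep(FALSE, n + 1)
  Dm <- array(NA_real_, c(n + 1, ns, ns, 3))
  hops <- list()

  st <- initial
  valid <- TRUE
  reason <- NA_character_
  store <- function(i) {
    Rm[i, ] <<- st$R
    Pm[i, ] <<- st$P
    act[i] <<- st$active
    En[i, ] <<- st$es$energies
    ekin[i] <<- sum(st$P^2) / 2
    Cm[i, ] <<- st$coeffs
    Dm[i, , , ] <<- st$es$dipole_adiabatic
  }
  store(1)
  e0 <- ekin[1] + En[1, st$active]
  tol <- ev_to_au(cfg$energy_tolerance_eV)
  n_done <- 0L

  for (i in seq_len(n)) {
    ok <- tryCatch({
      st <- nuclear_step(st, model, cfg)
      TRUE
    }, error = function(e) {
      valid <<- FALSE
      reason <<- conditionMessage(e)
      FALSE
    })
    if (!ok) break
    Tm <- lowdin(st$es$S)
    cnew <- ld_step(Cm[i, ], En[i, ], st$es$energies, Tm, dt, cfg$n_substeps)
    probs <- hop_probabilities(Cm[i, ], cnew, st$active)
    st$coeffs <- cnew
    st <- attempt_hop(st, probs, u = runif(1))
    hopped <- !is.null(st$hop)
    if (hopped) hops[[length(hops) + 1L]] <-
        data.frame(step = i, t_fs = au_to_fs(i * dt),
                   from = st$hop$from, to = st$hop$to,
                   accepted = st$hop$accepted)
    accepted <- hopped && st$hop$accepted
    dec <- step_decoherence_data(st$es, st$active, st$P, hop = accepted)
    res <- decohere_step(st$coeffs, st$aux, dec, dcfg, dt)
    st$coeffs <- res$coeffs
    st$aux <- res$aux
    Tl[[i]] <- Tm
    Fp[i + 1, ] <- dec$fproj
    hopflag[i + 1] <- accepted
    store(i + 1)
    n_done <- i
    etot <- ekin[i + 1] + En[i + 1, st$active]
    if (abs(etot - e0) > tol) {
      valid <- FALSE
      reason <- sprintf("energy drift %.3f eV at step %d", au_to_ev(abs(etot - e0)), i)
      break
    }
  }

  structure(list(
    t_fs = au_to_fs(dt) * (0:n), n_steps = n, n_done = n_done,
    R = Rm, P = Pm, active = act, energies = En, ekin = ekin,
    coeffs = Cm, T_list = Tl, fproj = Fp, hop_flag = hopflag,
    dipoles = Dm,
    hops = if (length(hops)) do.call(rbind, hops) else
      data.frame(step = integer(), t_fs = numeric(), from = integer(),
                 to = integer(), accepted = logical()),
    valid = valid, invalid_reason = reason,
    model_id = model$id, cfg = cfg, dcfg = dcfg, seed = as.integer(seed),
    schema_version = RECORD_SCHEMA_VERSION),
    class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat(sprintf("<trajectory_record: %d/%d steps, %d state(s), active %d -> %d, %d accepted hop(s), %s>\n",
              x$n_done, x$n_steps, ncol(x$coeffs), x$active[1],
              x$active[x$n_done + 1], sum(x$hops$accepted),
              if (x$valid) "valid" else paste0("INVALID: ", x$invalid_reason)))
  invisible(x)
}
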