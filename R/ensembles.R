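# The three initial-condition ensembles and their importance weights:
#   FP  - full propagation: every geometry carries the normalized pump-generated
#         superposition from t = 0; weight = mean excited population / N_g.
#   AXE - all-excited-state ensemble: one delta-initialized trajectory per
#         geometry and per excited state; pulse enters only through weights.
#   SXE - stochastically selected excited-state ensemble: (g, a) pairs accepted
#         with probability proportional to the oscillator strength f_0a, with
#         per-energy-window renormalization; the weight undoes the bias.
# AXE and SXE member lists and trajectories are pulse-independent by
# construction; attach_pulse_weights() is the only pulse-dependent step.

new_ensemble_spec <- function(scheme, members, init_coeffs, samples, n_states,
                              extra = list()) {
  structure(c(list(scheme = scheme, members = members,
                   init_coeffs = init_coeffs, samples = samples,
                   n_states = n_states, N_g = samples$n), extra),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec %s: %d member(s) over %d geometries, %d state(s)%s>\n",
              x$scheme, nrow(x$members), x$N_g, x$n_states,
              if (all(is.na(x$members$weight))) ", weights unattached" else ""))
  invisible(x)
}

# Pump-generated amplitudes at one geometry; NULL if the pulse excites nothing
pgc_at_geometry <- function(model, R, pulse) {
  es <- evaluate_model(model, R)
  amps <- first_order_amplitudes(es, pulse)
  pop <- sum(Mod(amps$values[-1])^2)
  list(es = es, amps = amps, t0_population = pop)
}

#' Build the full-propagation (FP) ensemble
#'
#' For every Wigner geometry, computes the first-order pump-generated
#' amplitudes, normalizes their excited part, draws the initial active state
#' with probability proportional to the pump-generated populations, and assigns
#' the geometry weight `w_g = (sum_k |c_k(0)|^2) / N_g`. Geometries where the
#' pulse excites nothing are dropped.
#'
#' @param samples a `wigner_sample`.
#' @param model a `diabatic_model`.
#' @param pulse a `gaussian_pulse`.
#' @param seed integer seed for the active-state draws.
#' @return an `ensemble_spec` with scheme `"FP"`.
#' @export
build_fp <- function(samples, model, pulse, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ns <- model$n_states
  rows <- list()
  cmat <- list()
  dropped <- 0L
  for (g in seq_len(samples$n)) {
    pg <- pgc_at_geometry(model, samples$Q[g, ], pulse)
    if (pg$t0_population <= 0) {
      dropped <- dropped + 1L
      next
    }
    cn <- normalize_excited(pg$amps)
    pops <- Mod(pg$amps$values)^2
    a0 <- sample.int(ns, 1L, prob = pops)
    rows[[length(rows) + 1L]] <-
      data.frame(g = g, a = NA_integer_, active0 = a0,
                 t0_population = pg$t0_population,
                 weight = pg$t0_population / samples$n,
                 p_bar = NA_real_, window = NA_integer_)
    cmat[[length(rows)]] <- cn$values
  }
  if (dropped > 0)
    message(dropped, " geometrie(s) dropped: pulse excites no population there")
  if (length(rows) == 0)
    stop("pulse excites no population at any sampled geometry")
  new_ensemble_spec("FP", do.call(rbind, rows),
                    do.call(rbind, cmat), samples, ns,
                    extra = list(pulse_id = hash_object(unclass(pulse)),
                                 seed = as.integer(seed)))
}

#' Build the all-excited-state (AXE) ensemble
#'
#' One member per geometry and per excited state, delta-initialized
#' (`c_i(0) = delta_ia`). Weights are left unattached until a pulse is supplied
#' via [attach_pulse_weights()], which keeps the member list and trajectories
#' pulse-independent.
#'
#' @param samples a `wigner_sample`.
#' @param n_states number of electronic states of the model.
#' @return an `ensemble_spec` with scheme `"AXE"` and
#'   `(n_states - 1) * N_g` members.
#' @export
build_axe <- function(samples, n_states) {
  if (n_states < 2) stop("n_states must be >= 2")
  members <- expand.grid(a = 2:n_states, g = seq_len(samples$n))[, c("g", "a")]
  members <- data.frame(g = members$g, a = members$a, active0 = members$a,
                        t0_population = NA_real_, weight = NA_real_,
                        p_bar = NA_real_, window = NA_integer_)
  cmat <- matrix(0 + 0i, nrow(members), n_states)
  cmat[cbind(seq_len(nrow(members)), members$a)] <- 1 + 0i
  new_ensemble_spec("AXE", members, cmat, samples, n_states)
}

#' Build the stochastically selected excited-state (SXE) ensemble
#'
#' Each candidate pair (geometry `g`, excited state `a`) is assigned to an
#' energy window by its vertical transition energy and accepted with
#' probability `p_a = f_0a / N_w`, where `N_w` is the maximum oscillator
#' strength observed in that window (per-window renormalization; a single
#' window when no boundaries are given). Dark states (`f = 0`) are never
#' selected. The acceptance records (`p_bar`, per-window `N_bar`, and
#' `alpha_bar = N_t / N_g`) are stored for the importance weights.
#'
#' @param samples a `wigner_sample`.
#' @param model a `diabatic_model`.
#' @param windows numeric vector of internal energy boundaries in eV
#'   stratifying the transition energies (e.g. `8.30`); empty for one window.
#' @param seed integer seed for the acceptance draws.
#' @return an `ensemble_spec` with scheme `"SXE"`.
#' @export
build_sxe <- function(samples, model, windows = numeric(0), seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ns <- model$n_states
  cand_f <- matrix(NA_real_, samples$n, ns - 1)
  cand_w <- matrix(NA_real_, samples$n, ns - 1)
  for (g in seq_len(samples$n)) {
    es <- evaluate_model(model, samples$Q[g, ])
    cand_f[g, ] <- oscillator_strengths(es)
    cand_w[g, ] <- au_to_ev(es$transition_energies[-1])
  }
  win <- matrix(findInterval(cand_w, sort(windows)) + 1L, samples$n, ns - 1)
  n_win <- max(win)
  N_bar <- vapply(seq_len(n_win), function(w) {
    fs <- cand_f[win == w]
    if (length(fs) == 0) NA_real_ else max(fs)
  }, 0)
  rows <- list()
  for (g in seq_len(samples$n)) {
    for (a in 2:ns) {
      w <- win[g, a - 1]
      if (is.na(N_bar[w]) || N_bar[w] <= 0) next
      p <- cand_f[g, a - 1] / N_bar[w]
      if (runif(1) < p)
        rows[[length(rows) + 1L]] <-
          data.frame(g = g, a = a, active0 = a, t0_population = NA_real_,
                     weight = NA_real_, p_bar = p, window = w)
    }
  }
  if (length(rows) == 0)
    stop("empty SXE acceptance: increase the number of geometries")
  members <- do.call(rbind, rows)
  cmat <- matrix(0 + 0i, nrow(members), ns)
  cmat[cbind(seq_len(nrow(members)), members$a)] <- 1 + 0i
  new_ensemble_spec("SXE", members, cmat, samples, ns,
                    extra = list(alpha_bar = nrow(members) / samples$n,
                                 N_bar = N_bar, windows = sort(windows),
                                 seed = as.integer(seed)))
}

#' Attach pulse-dependent importance weights to an ensemble
#'
#' Computes the pump-generated populations `|c_a(0)|^2` at every member's
#' geometry and fills the scheme's weight:
#' FP `w_g = (sum_k |c_k|^2) / N_g`;
#' AXE `w_ga = |c_a|^2 / N_g`;
#' SXE `w_ga = (alpha / N_t) |c_a|^2 / p_a`.
#' This is the only pulse-dependent step for AXE and SXE.
#'
#' @param spec an `ensemble_spec`.
#' @param model the `diabatic_model` the ensemble was built on.
#' @param pulse a `gaussian_pulse`.
#' @return the spec with weights, per-member pump amplitudes (`pgc` matrix,
#'   excited-normalized) and `t0_population` filled, and the pulse hash
#'   recorded.
#' @export
attach_pulse_weights <- function(spec, model, pulse) {
  nmem <- nrow(spec$members)
  ns <- spec$n_states
  pgc <- matrix(NA_complex_, nmem, ns)
  # amplitudes are per-geometry; compute once per distinct geometry
  for (g in unique(spec$members$g)) {
    idx <- which(spec$members$g == g)
    pg <- pgc_at_geometry(model, spec$samples$Q[g, ], pulse)
    spec$members$t0_population[idx] <- pg$t0_population
    if (pg$t0_population > 0) {
      cn <- normalize_excited(pg$amps)
      for (i in idx) pgc[i, ] <- cn$values
    } else {
      pgc[idx, ] <- 0 + 0i
    }
    pa <- Mod(pg$amps$values)^2
    for (i in idx) {
      w <- switch(spec$scheme,
        FP = pg$t0_population / spec$N_g,
        AXE = pa[spec$members$a[i]] / spec$N_g,
        SXE = (spec$alpha_bar / nmem) *
          pa[spec$members$a[i]] / spec$members$p_bar[i])
      spec$members$weight[i] <- w
    }
  }
  spec$pgc <- pgc
  spec$pulse_id <- hash_object(unclass(pulse))
  spec
}

#' Balance an ensemble after validity filtering
#'
#' Invalid (energy-non-conserving) trajectories are removed; the remainder is
#' balanced so the statistics are not biased by which initial active state
#' failed. For FP and SXE, valid members started in the other initial states
#' are randomly down-sampled so the initial active-state ratios before and
#' after filtering are preserved. For AXE, a geometry with any invalid member
#' loses all its members, keeping the per-geometry state structure intact.
#'
#' @param spec an `ensemble_spec`.
#' @param valid logical vector, one entry per member, from propagation.
#' @param seed integer seed for the down-sampling draws.
#' @return the spec with `members`, `init_coeffs` (and `pgc`, if present)
#'   subset to the balanced set; the kept member indices are stored in
#'   `$kept`.
#' @export
balance_ensemble <- function(spec, valid, seed = 1L) {
  stopifnot(length(valid) == nrow(spec$members))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  m <- spec$members
  if (spec$scheme == "AXE") {
    bad_g <- unique(m$g[!valid])
    keep <- which(!(m$g %in% bad_g))
  } else {
    states <- sort(unique(m$active0))
    n0 <- table(factor(m$active0, levels = states))
    nv <- table(factor(m$active0[valid], levels = states))
    scale <- min(as.numeric(nv) / as.numeric(n0))
    keep <- integer(0)
    for (s in states) {
      cand <- which(valid & m$active0 == s)
      k <- round(scale * n0[[as.character(s)]])
      keep <- c(keep, if (length(cand) <= k) cand else sort(sample(cand, k)))
    }
    keep <- sort(keep)
  }
  spec$members <- m[keep, , drop = FALSE]
  spec$init_coeffs <- spec$init_coeffs[keep, , drop = FALSE]
  if (!is.null(spec$pgc)) spec$pgc <- spec$pgc[keep, , drop = FALSE]
  spec$kept <- keep
  spec
}

# Deterministic, order-independent per-member seed from a base seed
member_seed <- function(base_seed, idx) {
  as.integer((as.double(base_seed) %% 65536 * 32749 + idx * 2654435.0) %%
               2147483629 + 1)
}

#' Propagate all trajectories of an ensemble
#'
#' Runs [propagate_trajectory()] for every member from its Wigner phase-space
#' point, with the member's initial active state and initial coefficients
#' (delta for AXE/SXE, the normalized pump superposition for FP). Each member
#' gets its own hopping seed derived from `base_seed` and the member index, so
#' the ensemble is reproducible and order-independent.
#'
#' @param spec an `ensemble_spec`.
#' @param model,cfg,dcfg model and propagation/decoherence configurations.
#' @param base_seed integer base seed.
#' @return list of `trajectory_record`, one per member.
#' @export
propagate_ensemble <- function(spec, model, cfg,
                               dcfg = decoherence_config("none"),
                               base_seed = 1L) {
  lapply(seq_len(nrow(spec$members)), function(i) {
    g <- spec$members$g[i]
    st <- make_initial_state(model, spec$samples$Q[g, ], spec$samples$P[g, ],
                             active = spec$members$active0[i],
                             coeffs = spec$init_coeffs[i, ])
    propagate_trajectory(st, model, cfg, dcfg,
                         seed = member_seed(base_seed, i))
  })
}
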