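# Electronic-only repropagation: re-solve the electronic Schroedinger equation
# (with decoherence) along a frozen, precomputed trajectory from new
# pulse-generated initial coefficients. The nuclear path, active-state sequence
# and every geometric quantity are read from the stored record and never
# modified; no hops are re-drawn. This is exact when the source trajectory
# never hopped, and an approximation otherwise (hops occurring while the
# repropagated coherence is still large are counted and flagged).

#' Repropagate electronic coefficients along a frozen trajectory
#'
#' Replays exactly the electronic-step + decoherence cycle of
#' [propagate_trajectory()] using the stored local-diabatic propagator
#' matrices, energies, active states, kinetic energies and projected forces of
#' the record. With `new_initial` equal to the record's own initial
#' coefficients and the same decoherence configuration, the result reproduces
#' the stored coefficients bit-exactly.
#'
#' @param record a valid `trajectory_record`.
#' @param new_initial an `amplitude_vector` or complex vector of length
#'   `n_states` (typically the excited-normalized pump superposition at the
#'   record's initial geometry).
#' @param dcfg a `decoherence_config` applied during the replay.
#' @param coherence_flag threshold: accepted hops occurring while the
#'   repropagated coherence `max_{i<j} |C_i* C_j|` still exceeds this value are
#'   counted in `flagged_hops` (regimes where the frozen-trajectory
#'   approximation is least controlled).
#' @return an object of class `repropagation_run` with the coefficient time
#'   series `coeffs` (steps x states), `t_fs`, `flagged_hops` and provenance.
#' @export
repropagate <- function(record, new_initial, dcfg = record$dcfg,
                        coherence_flag = 0.05) {
  if (!isTRUE(record$valid))
    stop("cannot repropagate an invalid trajectory record")
  need <- c("energies", "T_list", "active", "ekin", "fproj", "hop_flag")
  missing <- need[vapply(need, function(f) is.null(record[[f]]), TRUE)]
  if (length(missing))
    stop("record lacks stored datasets: ", paste(missing, collapse = ", "))
  v <- if (inherits(new_initial, "amplitude_vector")) new_initial$values
       else as.complex(new_initial)
  ns <- ncol(record$coeffs)
  if (length(v) != ns) stop("new_initial has length ", length(v),
                            ", record has ", ns, " states")
  n <- record$n_steps
  dt <- record$cfg$dt_au
  Cm <- matrix(NA_complex_, n + 1, ns)
  Cm[1, ] <- v
  aux <- list(ds = numeric(ns), dp = numeric(ns))
  flagged <- 0L
  for (i in seq_len(n)) {
    cnew <- ld_step(Cm[i, ], record$energies[i, ], record$energies[i + 1, ],
                    record$T_list[[i]], dt, record$cfg$n_substeps)
    b <- record$active[i + 1]
    if (record$hop_flag[i + 1]) {
      coh <- max(Mod(outer(Conj(cnew), cnew))[upper.tri(diag(ns))])
      if (coh > coherence_flag) flagged <- flagged + 1L
    }
    dec <- list(active = b,
                gaps = abs(record$energies[i + 1, ] - record$energies[i + 1, b]),
                ekin = record$ekin[i + 1],
                fproj = record$fproj[i + 1, ],
                hop = record$hop_flag[i + 1])
    res <- decohere_step(cnew, aux, dec, dcfg, dt)
    Cm[i + 1, ] <- res$coeffs
    aux <- res$aux
  }
  structure(list(coeffs = Cm, t_fs = record$t_fs, flagged_hops = flagged,
                 dcfg = dcfg, model_id = record$model_id,
                 source_seed = record$seed),
            class = "repropagation_run")
}

#' @export
print.repropagation_run <- function(x, ...) {
  cat(sprintf("<repropagation_run: %d steps, %d state(s), %d flagged hop(s)>\n",
              nrow(x$coeffs) - 1L, ncol(x$coeffs), x$flagged_hops))
  invisible(x)
}

#' Repropagate a whole ensemble for a given pump pulse
#'
#' For every member of the ensemble, computes the first-order pump amplitudes
#' at its stored initial geometry, normalizes the excited part, and
#' repropagates the electronic coefficients along the member's frozen record.
#' Also attaches the pulse-dependent Table-of-weights via
#' [attach_pulse_weights()]. No nuclear propagation is performed: two pulses
#' over the same records differ only in this (cheap) electronic replay and in
#' the weights.
#'
#' @param spec the `ensemble_spec` the records were propagated from.
#' @param records list of `trajectory_record`, one per member.
#' @param pulse a `gaussian_pulse`.
#' @param model the `diabatic_model` (checked against the records' model hash).
#' @param dcfg a `decoherence_config` for the replay.
#' @return list with `runs` (list of `repropagation_run`) and `spec` (with
#'   weights attached).
#' @export
repropagate_ensemble <- function(spec, records, pulse, model,
                                 dcfg = decoherence_config("none")) {
  if (length(records) != nrow(spec$members))
    stop("need one record per ensemble member")
  for (i in seq_along(records)) {
    if (!identical(records[[i]]$model_id, model$id))
      stop(sprintf("record for member (g=%d, a=%s) was propagated on a different model",
                   spec$members$g[i], as.character(spec$members$a[i])))
  }
  spec <- attach_pulse_weights(spec, model, pulse)
  runs <- lapply(seq_along(records), function(i) {
    if (spec$members$t0_population[i] <= 0) {
      # pulse excites nothing here: zero-weight member, replay the delta
      repropagate(records[[i]], spec$init_coeffs[i, ], dcfg)
    } else {
      repropagate(records[[i]], spec$pgc[i, ], dcfg)
    }
  })
  list(runs = runs, spec = spec)
}
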