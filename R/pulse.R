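# Broadband Gaussian pump model and the first-order-perturbation electronic
# amplitudes it creates (the pump-generated coherences, PGCs). The pulse acts
# only through its spectral envelope at the vertical transition energies: the
# nuclei are assumed frozen during the (sub-fs) light-matter interaction.

#' Broadband Gaussian pump pulse
#'
#' Spectral envelope `E(w) = E0 exp(-(w - wL)^2 / (2 sigma^2)) p`, with
#' `sigma = dw / (2 sqrt(ln 2))` so that `dw` is the full width at half maximum
#' of the spectral intensity `|E(w)|^2`.
#'
#' @param omega_L_eV central frequency in eV.
#' @param delta_omega_eV fwhm of `|E(w)|^2` in eV.
#' @param polarization 3-vector, normalized internally to unit length.
#' @param amplitude peak spectral field strength `E0` (a.u., default 1).
#' @return an object of class `gaussian_pulse` carrying both the eV inputs and
#'   their atomic-unit equivalents (`omega_L_au`, `sigma_au`).
#' @export
gaussian_pulse <- function(omega_L_eV, delta_omega_eV,
                           polarization = c(0, 0, 1), amplitude = 1) {
  if (delta_omega_eV <= 0) stop("delta_omega_eV must be > 0")
  p <- as.numeric(polarization)
  if (length(p) != 3 || sum(p^2) == 0) stop("polarization must be a nonzero 3-vector")
  p <- p / sqrt(sum(p^2))
  sigma_eV <- delta_omega_eV / (2 * sqrt(log(2)))
  structure(list(amplitude = amplitude,
                 omega_L_eV = omega_L_eV, delta_omega_eV = delta_omega_eV,
                 sigma_eV = sigma_eV,
                 omega_L_au = ev_to_au(omega_L_eV), sigma_au = ev_to_au(sigma_eV),
                 polarization = p),
            class = "gaussian_pulse")
}

#' @export
print.gaussian_pulse <- function(x, ...) {
  cat(sprintf("<gaussian_pulse: wL = %.3f eV, dw = %.3f eV (%.2f fs), p = (%.3f, %.3f, %.3f)>\n",
              x$omega_L_eV, x$delta_omega_eV, fwhm_duration(x),
              x$polarization[1], x$polarization[2], x$polarization[3]))
  invisible(x)
}

#' Vector spectral envelope of the pump at a given frequency
#'
#' @param pulse a `gaussian_pulse`.
#' @param omega frequency, atomic units (may be a vector).
#' @return for scalar `omega`, the 3-vector `E(w) p`; for vector input, a
#'   `length(omega) x 3` matrix.
#' @export
spectral_envelope <- function(pulse, omega) {
  mag <- pulse$amplitude *
    exp(-(omega - pulse$omega_L_au)^2 / (2 * pulse$sigma_au^2))
  if (length(omega) == 1L) mag * pulse$polarization
  else outer(mag, pulse$polarization)
}

#' Intensity fwhm duration of the pump in femtoseconds
#'
#' The Fourier transform of the Gaussian spectral envelope is Gaussian in time;
#' the fwhm of `|E(t)|^2` relates to the spectral-intensity fwhm `dw` by
#' `dt * dw = 4 ln 2 * hbar`, i.e. `dt = 4 ln 2 * hbar / dw` with
#' `hbar = 0.6582119 eV fs`.
#'
#' @param pulse a `gaussian_pulse`.
#' @return duration in fs.
#' @export
fwhm_duration <- function(pulse) {
  4 * log(2) * HBAR_EVFS / pulse$delta_omega_eV
}

#' Amplitude vector container
#'
#' @param values complex amplitudes, one per electronic state (state 1 =
#'   ground).
#' @param convention one of `"pump"` (raw first-order amplitudes),
#'   `"excited_normalized"`, `"repropagated"`.
#' @param t0_population total excited population `sum_{k>=2} |c_k(0)|^2` of the
#'   pre-normalization vector; stored by [normalize_excited()] and used as the
#'   full-propagation ensemble weight.
#' @return an object of class `amplitude_vector`.
#' @export
amplitude_vector <- function(values, convention = "pump", t0_population = NA_real_) {
  structure(list(values = as.complex(values), convention = convention,
                 t0_population = t0_population),
            class = "amplitude_vector")
}

#' @export
print.amplitude_vector <- function(x, ...) {
  cat(sprintf("<amplitude_vector (%s): ", x$convention))
  cat(format(x$values, digits = 4), sep = ", ")
  cat(">\n")
  invisible(x)
}

#' First-order pump-generated amplitudes at one geometry
#'
#' First-order perturbation theory for an ultrashort pump with frozen nuclei:
#' `c_k(0) = i d_0k(R) . E(w_k0(R))` for every excited state `k`, where `d_0k`
#' is the adiabatic transition dipole from the ground state and `w_k0` the
#' vertical transition energy at this geometry. The ground-state slot is left
#' at zero: only the excited part of the wave function is propagated.
#'
#' @param point an `es_point` from [evaluate_model()].
#' @param pulse a `gaussian_pulse`.
#' @return an `amplitude_vector` with convention `"pump"`.
#' @export
first_order_amplitudes <- function(point, pulse) {
  ns <- length(point$energies)
  vals <- complex(real = numeric(ns))
  for (k in 2:ns) {
    Evec <- spectral_envelope(pulse, point$transition_energies[k])
    vals[k] <- 1i * sum(point$dipole_adiabatic[1, k, ] * Evec)
  }
  amplitude_vector(vals, convention = "pump")
}

#' Normalize the excited-state part of a pump-generated amplitude vector
#'
#' Divides the excited amplitudes by the square root of the total excited
#' population so that `sum_{k>=2} |c_k|^2 = 1`, zeroing the ground-state slot,
#' and records the pre-normalization excited population (`t0_population`), the
#' geometry-dependent weight ingredient of the full-propagation ensemble.
#'
#' @param amps an `amplitude_vector`.
#' @return an `amplitude_vector` with convention `"excited_normalized"`.
#' @export
normalize_excited <- function(amps) {
  v <- amps$values
  pop <- sum(Mod(v[-1])^2)
  if (pop <= 0) stop("pulse excites nothing at this geometry")
  v[1] <- 0
  v[-1] <- v[-1] / sqrt(pop)
  amplitude_vector(v, convention = "excited_normalized", t0_population = pop)
}
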