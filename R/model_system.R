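# Analytic model electronic structure: diabatic model Hamiltonians, their
# adiabatization, Hellmann-Feynman gradients, dipoles, and Wigner sampling of a
# harmonic ground state. These stand in for on-the-fly quantum chemistry so the
# dynamics machinery can be exercised and validated on closed-form surfaces.
#
# Conventions: states are indexed 1..n_states with state 1 the electronic ground
# state (S0); coordinates are mass-weighted and in atomic units throughout, so
# H = P^2/2 + V(R) with unit masses.

#' Harmonic reference for Wigner sampling
#'
#' Defines the harmonic electronic ground state whose vibrational ground-state
#' Wigner distribution provides the initial nuclear phase-space samples.
#'
#' @param frequencies per-mode angular frequencies in atomic units (all > 0).
#' @param reference_geometry mass-weighted equilibrium coordinates (defaults to
#'   the origin).
#' @return an object of class `harmonic_reference`.
#' @export
harmonic_reference <- function(frequencies, reference_geometry = NULL) {
  frequencies <- as.numeric(frequencies)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("all frequencies must be finite and > 0")
  if (is.null(reference_geometry)) reference_geometry <- numeric(length(frequencies))
  if (length(reference_geometry) != length(frequencies))
    stop("reference_geometry must have one entry per mode")
  structure(list(n_modes = length(frequencies),
                 frequencies = frequencies,
                 reference_geometry = as.numeric(reference_geometry)),
            class = "harmonic_reference")
}

#' Construct a diabatic model Hamiltonian
#'
#' A model is defined by its symmetric diabatic potential matrix, the gradient
#' of every matrix element, and an element-wise symmetric matrix of dipole
#' 3-vectors, all as functions of the mass-weighted coordinates `R`.
#'
#' @param n_states number of electronic states (state 1 = ground).
#' @param n_modes number of nuclear coordinates.
#' @param potential function `R -> n_states x n_states` symmetric matrix (a.u.).
#' @param gradient function `R -> n_states x n_states x n_modes` array with the
#'   derivative of each potential matrix element along each mode.
#' @param dipole function `R -> n_states x n_states x 3` array of dipole vectors.
#' @param params parameter list used to derive a reproducible model hash
#'   (provenance guard for repropagation).
#' @return an object of class `diabatic_model`.
#' @export
diabatic_model <- function(n_states, n_modes, potential, gradient, dipole,
                           params = NULL) {
  m <- structure(list(n_states = as.integer(n_states),
                      n_modes = as.integer(n_modes),
                      potential = potential, gradient = gradient,
                      dipole = dipole, params = params),
                 class = "diabatic_model")
  m$id <- hash_object(if (is.null(params)) list(body(potential), body(dipole))
                      else params)
  m
}

# md5 of a canonical serialization; used for model/pulse provenance hashes
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' @export
print.diabatic_model <- function(x, ...) {
  cat(sprintf("<diabatic_model: %d states, %d mode(s), id %s>\n",
              x$n_states, x$n_modes, substr(x$id, 1, 8)))
  invisible(x)
}

#' One-dimensional two-state avoided crossing model
#'
#' Linear diabatic crossing `V11 = A x`, `V22 = -A x` with constant coupling
#' `V12 = c`: adiabatic surfaces `+/- sqrt(A^2 x^2 + c^2)` with minimal gap `2c`
#' at the origin. The default dipole matrix has a unit transition dipole along
#' x, which makes both states radiatively coupled when used with a pump.
#'
#' @param A diabatic slope (a.u.).
#' @param c constant diabatic coupling (a.u.).
#' @return a `diabatic_model`.
#' @export
avoided_crossing_model <- function(A = 0.01, c = 0.005) {
  force(A); force(c)
  diabatic_model(
    n_states = 2L, n_modes = 1L,
    potential = function(R) matrix(c(A * R[1], c, c, -A * R[1]), 2, 2),
    gradient = function(R) array(c(A, 0, 0, -A), c(2, 2, 1)),
    dipole = function(R) {
      d <- array(0, c(2, 2, 3))
      d[1, 2, 1] <- d[2, 1, 1] <- 1
      d
    },
    params = list(type = "avoided_crossing", A = A, c = c))
}

#' Linear vibronic coupling (LVC) model
#'
#' `V(Q) = (sum_k w_k^2 Q_k^2 / 2) I + diag(eps_i + sum_k kappa_ik Q_k)
#'  + [lambda_ij,k Q_k]_{i != j}` in mass-weighted coordinates (so the harmonic
#' frequency of each mode is `w_k` under `H = P^2/2 + V`), with a constant plus
#' optionally linear dipole matrix. State 1 is the unshifted harmonic ground
#' state when `eps[1] = 0` and `kappa[1, ] = 0`, matching the Wigner sampler of
#' [harmonic_reference()].
#'
#' @param frequencies per-mode frequencies `w_k` (a.u.).
#' @param eps vertical energies per state (a.u.).
#' @param kappa `n_states x n_modes` matrix of linear intrastate couplings.
#' @param lambda `n_states x n_states x n_modes` array of linear interstate
#'   couplings (symmetric in its first two indices, zero diagonal); may be NULL.
#' @param dip0 `n_states x n_states x 3` constant dipole array (element-wise
#'   symmetric).
#' @param dip1 optional `n_states x n_states x 3 x n_modes` linear dipole
#'   coefficients.
#' @return a `diabatic_model`.
#' @export
lvc_model <- function(frequencies, eps, kappa = NULL, lambda = NULL,
                      dip0 = NULL, dip1 = NULL) {
  frequencies <- as.numeric(frequencies)
  nm <- length(frequencies)
  ns <- length(eps)
  if (is.null(kappa)) kappa <- matrix(0, ns, nm)
  kappa <- matrix(as.numeric(kappa), ns, nm)
  if (is.null(lambda)) lambda <- array(0, c(ns, ns, nm))
  lambda <- array(as.numeric(lambda), c(ns, ns, nm))
  if (is.null(dip0)) dip0 <- array(0, c(ns, ns, 3))
  for (k in seq_len(nm)) {
    if (max(abs(lambda[, , k] - t(lambda[, , k]))) > 1e-12)
      stop("lambda must be symmetric in its state indices")
  }
  force(eps)
  pot <- function(R) {
    V <- diag(eps + as.vector(kappa %*% R), ns) +
      0.5 * sum(frequencies^2 * R^2) * diag(ns)
    for (k in seq_len(nm)) V <- V + lambda[, , k] * R[k]
    V
  }
  grad <- function(R) {
    G <- array(0, c(ns, ns, nm))
    for (k in seq_len(nm))
      G[, , k] <- diag(kappa[, k], ns) + frequencies[k]^2 * R[k] * diag(ns) +
        lambda[, , k]
    G
  }
  dip <- function(R) {
    D <- dip0
    if (!is.null(dip1))
      for (k in seq_len(nm)) D <- D + dip1[, , , k] * R[k]
    D
  }
  diabatic_model(ns, nm, pot, grad, dip,
                 params = list(type = "lvc", frequencies = frequencies,
                               eps = eps, kappa = kappa, lambda = lambda,
                               dip0 = dip0, dip1 = dip1))
}

#' Glycine-like four-state model preset
#'
#' A three-mode LVC fixture that mimics the qualitative electronic structure of
#' a small amino acid: two lower excited states with transition dipoles from the
#' ground state polarized along z and moderate strength, one brighter third
#' excited state polarized in the molecular (x-y) plane, and an excited-state
#' transition dipole along x that makes coherences visible in the molecular
#' dipole. Parameter values are fixture choices on a few-fs gap scale, not
#' quantum-chemistry results.
#'
#' @return a list with elements `model` (a `diabatic_model`) and `reference`
#'   (the matching `harmonic_reference` for Wigner sampling).
#' @export
glycine_like_model <- function() {
  freqs <- c(0.010, 0.014, 0.018)
  eps <- ev_to_au(c(0, 6.4, 7.6, 8.9))
  # intrastate/interstate linear couplings scaled as kappa' * sqrt(w) with
  # kappa' of a few tenths of an eV (dimensionless-coordinate convention), so
  # the vertical-gap spread over the Wigner ensemble is a few tenths of an eV
  kap <- function(ev, k) ev_to_au(ev) * sqrt(freqs[k])
  kappa <- rbind(c(0, 0, 0),
                 c(kap(0.20, 1), 0, kap(0.10, 3)),
                 c(kap(-0.15, 1), kap(0.12, 2), 0),
                 c(kap(0.10, 1), kap(-0.12, 2), kap(0.15, 3)))
  lambda <- array(0, c(4, 4, 3))
  lambda[2, 3, 3] <- lambda[3, 2, 3] <- kap(0.10, 3)
  lambda[3, 4, 2] <- lambda[4, 3, 2] <- kap(0.15, 2)
  dip0 <- array(0, c(4, 4, 3))
  dip0[1, 2, ] <- dip0[2, 1, ] <- c(0, 0, 0.35)   # S0-S1, z-polarized, weak
  dip0[1, 3, ] <- dip0[3, 1, ] <- c(0, 0, 0.50)   # S0-S2, z-polarized
  dip0[1, 4, ] <- dip0[4, 1, ] <- c(0.80, 0.50, 0) # S0-S3, in-plane, bright
  dip0[2, 3, ] <- dip0[3, 2, ] <- c(0.60, 0, 0)   # S1-S2 transition dipole
  for (i in 1:4) dip0[i, i, ] <- c(0.1 * i, -0.05 * i, 0.02)
  dip1 <- array(0, c(4, 4, 3, 3))
  dip1[1, 2, 3, 1] <- dip1[2, 1, 3, 1] <- 0.02    # mild geometry dependence
  dip1[1, 3, 3, 2] <- dip1[3, 1, 3, 2] <- -0.02
  list(model = lvc_model(freqs, eps, kappa, lambda, dip0, dip1),
       reference = harmonic_reference(freqs))
}

#' Adiabatize a diabatic model at one geometry
#'
#' Diagonalizes the diabatic potential matrix, forms adiabatic energies in
#' ascending order, per-state Hellmann-Feynman gradients
#' `g_i,k = u_i' dV/dQ_k u_i`, and the dipole matrix rotated to the adiabatic
#' basis.
#'
#' @param model a `diabatic_model`.
#' @param R mass-weighted coordinates (length `model$n_modes`).
#' @return an object of class `es_point` with fields `energies`, `eigenvectors`
#'   (columns = adiabatic states in the diabatic basis), `gradients`
#'   (`n_states x n_modes`), `dipole_adiabatic` (`n_states x n_states x 3`),
#'   `transition_energies` (`E_a - E_1`) and `S` (overlap to the previous
#'   aligned point, filled by [phase_align()]).
#' @export
evaluate_model <- function(model, R) {
  R <- as.numeric(R)
  if (length(R) != model$n_modes)
    stop("R has length ", length(R), ", model expects ", model$n_modes)
  V <- model$potential(R)
  if (any(!is.finite(V)))
    stop("non-finite potential entries at R = (", paste(signif(R, 6), collapse = ", "), ")")
  ee <- eigen(V, symmetric = TRUE)
  ord <- order(ee$values)           # eigen() returns decreasing order
  E <- ee$values[ord]
  U <- ee$vectors[, ord, drop = FALSE]
  ns <- model$n_states
  G <- model$gradient(R)
  grads <- matrix(0, ns, model$n_modes)
  for (k in seq_len(model$n_modes))
    grads[, k] <- colSums(U * (G[, , k] %*% U))
  D <- model$dipole(R)
  Dad <- array(0, c(ns, ns, 3))
  for (a in 1:3) Dad[, , a] <- t(U) %*% D[, , a] %*% U
  structure(list(R = R, energies = E, eigenvectors = U, gradients = grads,
                 dipole_adiabatic = Dad,
                 transition_energies = E - E[1], S = NULL,
                 model_id = model$id),
            class = "es_point")
}

#' Align the sign gauge of an adiabatic point with the previous time step
#'
#' Adiabatic eigenvectors carry an arbitrary sign; continuity of the local
#' diabatic propagation requires the overlap matrix
#' `S = U_prev' U_next` to have a positive diagonal. When the diagonal is not
#' dominant (a near-trivial crossing at this step size), states are reassigned
#' by maximal overlap and a warning is raised.
#'
#' @param current,previous `es_point` objects from the same model.
#' @return `current` with signs (and, under degeneracy, state order) fixed and
#'   the aligned overlap matrix stored in `$S`.
#' @export
phase_align <- function(current, previous) {
  if (!identical(current$model_id, previous$model_id))
    stop("points come from different models")
  S <- t(previous$eigenvectors) %*% current$eigenvectors
  ns <- ncol(S)
  if (any(abs(diag(S)) < 0.5)) {
    # greedy maximal-overlap assignment (degeneracy / possible trivial crossing)
    perm <- integer(ns)
    avail <- rep(TRUE, ns)
    for (i in seq_len(ns)) {
      j <- which.max(abs(S[i, ]) * avail)
      perm[i] <- j
      avail[j] <- FALSE
    }
    if (!identical(perm, seq_len(ns)) ) {
      current$energies <- current$energies[perm]
      current$eigenvectors <- current$eigenvectors[, perm, drop = FALSE]
      current$gradients <- current$gradients[perm, , drop = FALSE]
      current$dipole_adiabatic <- current$dipole_adiabatic[perm, perm, , drop = FALSE]
      current$transition_energies <- current$energies - current$energies[1]
      S <- S[, perm, drop = FALSE]
    }
    if (any(abs(diag(S)) < 0.5))
      warning("overlap diagonal below 0.5: possible trivial crossing at this step")
  }
  sgn <- ifelse(diag(S) < 0, -1, 1)
  current$eigenvectors <- sweep(current$eigenvectors, 2, sgn, `*`)
  S <- sweep(S, 2, sgn, `*`)
  for (a in 1:3)
    current$dipole_adiabatic[, , a] <-
      outer(sgn, sgn) * current$dipole_adiabatic[, , a]
  current$S <- S
  current
}

#' Oscillator strengths from the ground state
#'
#' Length-gauge convention `f_0a = (2/3) * w_a0 * |d_0a|^2` in atomic units,
#' for every excited state `a`.
#'
#' @param point an `es_point`.
#' @return numeric vector of length `n_states - 1` (excited states in order).
#' @export
oscillator_strengths <- function(point) {
  ns <- length(point$energies)
  w <- point$transition_energies[-1]
  if (any(w <= 0)) stop("degenerate or inverted ground/excited energies")
  d2 <- vapply(2:ns, function(a) sum(point$dipole_adiabatic[1, a, ]^2), 0)
  (2 / 3) * w * d2
}

#' Sample the ground-state Wigner distribution of a harmonic reference
#'
#' For each mode `k` the T = 0 vibrational ground-state Wigner function is the
#' Gaussian product with position width `1/sqrt(2 w_k)` around the reference
#' geometry and momentum width `sqrt(w_k / 2)`, sampled independently.
#'
#' @param ref a `harmonic_reference`.
#' @param n number of phase-space samples.
#' @param seed integer seed making the draw reproducible.
#' @return an object of class `wigner_sample`: list with `Q` and `P`
#'   (`n x n_modes` matrices) and the generating `seed`.
#' @export
sample_wigner <- function(ref, n, seed = 1L) {
  if (!inherits(ref, "harmonic_reference")) stop("ref must be a harmonic_reference")
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  nm <- ref$n_modes
  Q <- matrix(rnorm(n * nm), n, nm)
  P <- matrix(rnorm(n * nm), n, nm)
  sdq <- 1 / sqrt(2 * ref$frequencies)
  sdp <- sqrt(ref$frequencies / 2)
  Q <- sweep(sweep(Q, 2, sdq, `*`), 2, ref$reference_geometry, `+`)
  P <- sweep(P, 2, sdp, `*`)
  structure(list(Q = Q, P = P, n = n, seed = as.integer(seed)),
            class = "wigner_sample")
}

#' @export
print.wigner_sample <- function(x, ...) {
  cat(sprintf("<wigner_sample: %d samples, %d mode(s), seed %d>\n",
              x$n, ncol(x$Q), x$seed))
  invisible(x)
}

#' Write or read a phase-space sample as a plain columnar table
#'
#' One row per sample, columns `Q1..Qm, P1..Pm`, tab-separated.
#'
#' @param sample a `wigner_sample`.
#' @param path file path.
#' @return `read_samples` returns a `wigner_sample` (seed recorded as NA).
#' @export
write_samples <- function(sample, path) {
  df <- cbind(as.data.frame(sample$Q), as.data.frame(sample$P))
  names(df) <- c(paste0("Q", seq_len(ncol(sample$Q))),
                 paste0("P", seq_len(ncol(sample$P))))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  nm <- sum(startsWith(names(df), "Q"))
  structure(list(Q = as.matrix(df[, seq_len(nm), drop = FALSE]),
                 P = as.matrix(df[, nm + seq_len(nm), drop = FALSE]),
                 n = nrow(df), seed = NA_integer_),
            class = "wigner_sample")
}

#' Read a model definition from a structured config file
#'
#' YAML file with a `type` field (`lvc` or `avoided_crossing` or
#' `glycine_like`) and the corresponding parameter entries; LVC arrays are given
#' as nested lists in state-major order.
#'
#' @param path YAML file path.
#' @return a `diabatic_model` (for `glycine_like`, the preset list).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  switch(cfg$type,
    avoided_crossing = avoided_crossing_model(A = cfg$A, c = cfg$c),
    glycine_like = glycine_like_model(),
    lvc = {
      ns <- length(cfg$eps)
      nm <- length(cfg$frequencies)
      lvc_model(frequencies = as.numeric(cfg$frequencies),
                eps = as.numeric(cfg$eps),
                kappa = if (!is.null(cfg$kappa))
                  matrix(unlist(cfg$kappa), ns, nm, byrow = TRUE),
                lambda = if (!is.null(cfg$lambda))
                  array(unlist(cfg$lambda), c(ns, ns, nm)),
                dip0 = if (!is.null(cfg$dip0))
                  array(unlist(cfg$dip0), c(ns, ns, 3)),
                dip1 = if (!is.null(cfg$dip1))
                  array(unlist(cfg$dip1), c(ns, ns, 3, nm)))
    },
    stop("unknown model type: ", cfg$type))
}
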