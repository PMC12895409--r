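# Ensemble expectation values. Every observable is a weighted average of
# per-trajectory quadratic forms A_j(t) = sum_{i,i'} c_i* c_i' M_ii'(t), which
# splits exactly into a population part (diagonal of M) and a coherence part
# (off-diagonal). The raw average uses the scheme weights as they are; the
# display normalization divides by the total weight so aggregates are directly
# comparable with individual-member series.

#' Per-member expectation value of an operator along a trajectory
#'
#' `A_j(t) = sum_{i,i'} c_i(t)* c_i'(t) M_ii'(t)` with the population
#' (diagonal) and coherence (off-diagonal) contributions returned separately;
#' `total = pop + coh` holds exactly.
#'
#' @param coeffs_series complex matrix, time steps x states.
#' @param matrix_series the operator's adiabatic matrix along the trajectory:
#'   either a constant `ns x ns` matrix or a `steps x ns x ns` array.
#' @return list with numeric vectors `total`, `pop`, `coh` (real parts; the
#'   operator is assumed Hermitian with real adiabatic matrix elements).
#' @export
member_expectation <- function(coeffs_series, matrix_series) {
  nt <- nrow(coeffs_series)
  ns <- ncol(coeffs_series)
  const_M <- is.matrix(matrix_series)
  if (const_M) {
    if (!all(dim(matrix_series) == c(ns, ns))) stop("operator dimension mismatch")
  } else if (!all(dim(matrix_series)[2:3] == c(ns, ns)) ||
             dim(matrix_series)[1] != nt) {
    stop("operator dimension mismatch")
  }
  total <- pop <- numeric(nt)
  for (t in seq_len(nt)) {
    M <- if (const_M) matrix_series else matrix_series[t, , ]
    v <- coeffs_series[t, ]
    total[t] <- Re(Conj(v) %*% M %*% v)
    pop[t] <- sum(Mod(v)^2 * diag(M))
  }
  list(total = total, pop = pop, coh = total - pop)
}

#' Weighted ensemble average of per-member series
#'
#' Raw: `<A>(t) = sum_j w_j A_j(t)` (the estimator of the ensemble expectation
#' value). Display-normalized: divided by `sum_j w_j`, which makes the
#' aggregate of the identity operator equal to 1 and the curves comparable
#' with individual members.
#'
#' @param results per-member series: a members x time matrix, or a list of
#'   equal-length numeric vectors.
#' @param weights per-member weights (e.g. `spec$members$weight`).
#' @param normalized logical; divide by the total weight.
#' @return numeric time series.
#' @export
scheme_average <- function(results, weights, normalized = TRUE) {
  A <- if (is.list(results)) do.call(rbind, results) else results
  stopifnot(nrow(A) == length(weights))
  out <- colSums(A * weights)
  if (normalized) {
    W <- sum(weights)
    if (W == 0) stop("total weight is zero: cannot normalize")
    out <- out / W
  }
  out
}

# Coefficient series of a member: from a repropagation run or from the record
coeff_series <- function(x) {
  if (inherits(x, "repropagation_run")) x$coeffs else x$coeffs
}

#' Standard observable tables for an ensemble
#'
#' Produces the quantities typically plotted: adiabatic populations
#' `P_i(t) = |c_i(t)|^2`, pairwise coherences `Re(c_i* c_i')`, and the three
#' molecular dipole components evaluated with the stored adiabatic dipole
#' matrices, each as display-normalized weighted ensemble averages (per-member
#' series optionally included).
#'
#' @param members list of coefficient carriers: `trajectory_record`s (full
#'   propagation) or `repropagation_run`s.
#' @param weights per-member weights.
#' @param records list of `trajectory_record`s supplying dipole matrices and
#'   the time axis; defaults to `members` when those are records.
#' @param pairs 2-column matrix of state-index pairs for coherences; default
#'   all pairs `i < i'`.
#' @param keep_members logical, include the per-member matrices.
#' @return list with `t_fs`, `populations` (time x states), `coherences`
#'   (time x pairs, named `"i-j"`), `dipole` (time x 3, with `dipole_pop` and
#'   `dipole_coh` parts), and optionally `member_populations`,
#'   `member_coherences`.
#' @export
standard_series <- function(members, weights, records = NULL, pairs = NULL,
                            keep_members = FALSE) {
  if (is.null(records)) {
    if (!all(vapply(members, inherits, TRUE, "trajectory_record")))
      stop("records must be supplied when members are repropagation runs")
    records <- members
  }
  nmem <- length(members)
  stopifnot(length(weights) == nmem, length(records) == nmem)
  ns <- ncol(coeff_series(members[[1]]))
  nt <- nrow(coeff_series(members[[1]]))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ns, 2))
  }
  popA <- array(NA_real_, c(nmem, nt, ns))
  cohA <- array(NA_real_, c(nmem, nt, nrow(pairs)))
  dipT <- dipP <- array(NA_real_, c(nmem, nt, 3))
  for (j in seq_len(nmem)) {
    Cm <- coeff_series(members[[j]])
    popA[j, , ] <- Mod(Cm)^2
    for (p in seq_len(nrow(pairs)))
      cohA[j, , p] <- Re(Conj(Cm[, pairs[p, 1]]) * Cm[, pairs[p, 2]])
    for (a in 1:3) {
      me <- member_expectation(Cm, records[[j]]$dipoles[, , , a])
      dipT[j, , a] <- me$total
      dipP[j, , a] <- me$pop
    }
  }
  W <- sum(weights)
  wavg <- function(A) apply(A * weights, c(2, 3), sum) / W
  out <- list(
    t_fs = records[[1]]$t_fs,
    populations = `colnames<-`(wavg(popA), paste0("S", 0:(ns - 1))),
    coherences = `colnames<-`(wavg(cohA),
                              paste(pairs[, 1] - 1, pairs[, 2] - 1, sep = "-")),
    dipole = `colnames<-`(wavg(dipT), c("x", "y", "z")),
    dipole_pop = `colnames<-`(wavg(dipP), c("x", "y", "z")))
  out$dipole_coh <- out$dipole - out$dipole_pop
  if (keep_members) {
    out$member_populations <- popA
    out$member_coherences <- cohA
  }
  out
}

#' Internal-consistency gap of a surface-hopping ensemble
#'
#' The (unweighted) ensemble mean of the quantum populations `|c_i(t)|^2`
#' should match the fraction of trajectories whose active state is `i`.
#' Returns the absolute gap per state over time; with a decoherence correction
#' this stays small, without one it grows (overcoherence).
#'
#' @param records list of `trajectory_record`s (or `repropagation_run`s plus
#'   `active` taken from `source_records`).
#' @param source_records optional list of records supplying active-state
#'   sequences when `records` are repropagation runs.
#' @return matrix time x states of `|mean |c_i|^2 - active fraction|`.
#' @export
internal_consistency <- function(records, source_records = NULL) {
  if (is.null(source_records)) source_records <- records
  nmem <- length(records)
  ns <- ncol(coeff_series(records[[1]]))
  nt <- nrow(coeff_series(records[[1]]))
  popsum <- matrix(0, nt, ns)
  fracsum <- matrix(0, nt, ns)
  for (j in seq_len(nmem)) {
    popsum <- popsum + Mod(coeff_series(records[[j]]))^2
    aj <- source_records[[j]]$active
    fracsum <- fracsum + outer(aj, seq_len(ns), `==`)
  }
  abs(popsum - fracsum) / nmem
}

#' Plot population / coherence / dipole panels for an ensemble
#'
#' Three stacked base-graphics panels of the series produced by
#' [standard_series()].
#'
#' @param series output of [standard_series()].
#' @param main overall title.
#' @return invisibly, `series`.
#' @export
plot_observables <- function(series, main = "") {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(series$t_fs, series$populations, type = "l", lty = 1,
                    xlab = "t (fs)", ylab = "population", main = main)
  graphics::legend("topright", colnames(series$populations), lty = 1,
                   col = seq_len(ncol(series$populations)), bty = "n")
  graphics::matplot(series$t_fs, series$coherences, type = "l", lty = 1,
                    xlab = "t (fs)", ylab = "Re coherence")
  graphics::legend("topright", colnames(series$coherences), lty = 1,
                   col = seq_len(ncol(series$coherences)), bty = "n")
  graphics::matplot(series$t_fs, series$dipole, type = "l", lty = 1,
                    xlab = "t (fs)", ylab = "dipole (a.u.)")
  graphics::legend("topright", c("x", "y", "z"), lty = 1, col = 1:3, bty = "n")
  invisible(series)
}
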