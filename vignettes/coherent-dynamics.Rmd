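---
title: "Pump-generated coherences in surface hopping: full propagation and electronic repropagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pump-generated coherences in surface hopping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tshrp)
```

## The problem

An ultrashort, spectrally broad pump pulse does not excite a molecule into a
single electronic state: it creates a coherent superposition of several
excited states, with off-diagonal electronic density-matrix elements —
*pump-generated coherences* (PGCs) — that oscillate at the transition
frequencies between the states and decay within a few femtoseconds through
both nuclear-wave-packet separation and ensemble dephasing. Observables such
as the molecular dipole inherit these oscillations, so any simulation of
few-femtosecond pump–probe dynamics must carry the coherences, not just the
populations.

Trajectory surface hopping (TSH) is the workhorse mixed quantum–classical
method for such dynamics: classical nuclei follow the gradient of a single
*active* adiabatic surface $b(t)$ while the electronic amplitudes
$c_i(t)$ obey the time-dependent Schrödinger equation along the trajectory,
and stochastic hops between surfaces keep the two descriptions consistent.
This package implements a TSH framework in which the pump enters only through
first-order perturbation theory at $t = 0$, and offers two routes to include
the PGCs:

* **Full propagation (FP).** Each trajectory starts from the normalized
  excited-state superposition the pulse creates at its geometry, and the
  coupled electron–nuclear dynamics is run from there. Every trajectory —
  and every expensive matrix element along it — then depends on the pulse.
* **Repropagation (RP).** Trajectories are first run *without* initial
  coherences, delta-initialized in single excited states, which makes them
  pulse-independent. The electronic Schrödinger equation is then re-integrated
  (with decoherence) along these *frozen* trajectories from the
  pulse-generated initial amplitudes. Changing the pump costs only this cheap
  electronic replay plus a reweighting.

The repropagation is exact when no hops occur, because then the nuclear path
does not depend on the electronic amplitudes at all. When hops do occur while
the repropagated coherence is still sizable, the approximation is less
controlled; [repropagate()] counts such events (`flagged_hops`) so the regime
can be monitored.

## Ensembles and weights

Initial nuclear conditions are drawn from the ground-state Wigner
distribution of a harmonic reference (exact for a harmonic surface at
$T = 0$: per mode, position s.d. $1/\sqrt{2\omega}$, momentum s.d.
$\sqrt{\omega/2}$, independent Gaussians). Three ensembles estimate the same
pulse-dependent expectation value
$\langle A(t)\rangle = \sum_j w_j A_j(t)$, with
$A_j(t) = \sum_{ii'} c_i^* c_{i'} \langle\psi_i|\hat A|\psi_{i'}\rangle$
splitting exactly into a population (diagonal) and a coherence
(off-diagonal) part:

| scheme | member $j$ | initial amplitudes | weight $w_j$ |
|---|---|---|---|
| FP  | geometry $g$ | normalized pump superposition | $N_g^{-1}\sum_k |\tilde c_k^{(g)}(0)|^2$ |
| RP-AXE | $(g, a)$, all excited $a$ | $\delta_{ia}$ | $N_g^{-1}\,|\tilde c_a^{(g)}(0)|^2$ |
| RP-SXE | $(g, a)$ accepted | $\delta_{ia}$ | $\bar\alpha\,\bar N_t^{-1}\,|\tilde c_a^{(g)}(0)|^2/\bar p_a^{(g)}$ |

Here $\tilde c_k^{(g)}(0) = i\,\vec d_{0k}\!\cdot\!\vec E(\omega_{k0})$ are
the first-order amplitudes (frozen nuclei during the pulse), the FP active
state is drawn proportionally to $|\tilde c_i(0)|^2$, the all-excited-state
ensemble (AXE) enumerates every excited state per geometry, and the
stochastically selected ensemble (SXE) accepts $(g, a)$ with probability
$\bar p_a = f_{0a}/\bar N$ proportional to the oscillator strength
$f_{0a} = \tfrac23\,\omega_{a0}|\vec d_{0a}|^2$ (length gauge). The SXE
weight undoes that sampling bias. Design choices made where the contract was
open:

* $\bar N$ is the per-energy-window maximum of $f_{0a}$ over the sampled set
  (the minimal admissible normalizer), and $\bar\alpha = \bar N_t/N_g$ is
  evaluated at the finite sample size rather than as a limit.
* Energy-window stratification: transition energies can be split into
  windows (e.g. at 8.30 eV), each with its own $\bar N$. This rescues states
  that are much dimmer than a bright state elsewhere in the spectrum — with a
  single window their acceptance count collapses and the compensating weights
  make convergence hinge on a handful of trajectories.
* Display normalization divides $\sum_j w_j A_j$ by $\sum_j w_j$, which makes
  the aggregate of the identity exactly 1 and the curves directly comparable
  with individual-member series; the raw weighted sum remains available
  (`normalized = FALSE`).
* Under FP a geometry the pulse cannot excite is dropped (its weight would be
  zero); under AXE/SXE such members are kept with zero weight, preserving
  pulse independence of the member list.
* Balancing after validity filtering: FP/SXE randomly down-sample valid
  members of the other initial states so initial active-state ratios are
  preserved; AXE drops whole geometries, keeping its per-geometry state
  structure intact.

## Propagation machinery

* **Nuclear steps**: velocity Verlet on the active-surface Hellmann–Feynman
  gradient, mass-weighted coordinates, unit masses; default
  $\Delta t = 0.3$ fs to $t_{\mathrm{final}} = 14.1$ fs. Trajectories whose
  total energy drifts more than 0.5 eV are discarded (then balanced, above).
* **Electronic steps**: integrated in a *local diabatic* basis — the
  inter-step overlap $S = U_\mathrm{prev}^{\!\top} U_\mathrm{next}$ is
  sign-aligned (diagonal $\ge 0$; under near-degeneracy states are reassigned
  by maximal overlap and a warning raised below $|S_{ii}| = 0.5$), Löwdin
  orthogonalized, $T = S(S^{\top}S)^{-1/2}$, and the Hamiltonian is
  interpolated linearly across 51 substeps, each applying an exact midpoint
  exponential (unitary to machine precision; a singular $S^\top S$ — an
  unresolved trivial crossing — is an error, not a silent fix).
* **Hopping**: population-flux form. The probability to leave the active
  state over a step is its relative population loss
  $\max(0, (p_b(t) - p_b(t{+}\Delta t))/p_b(t))$, apportioned among the
  states that gained population in proportion to their gains. On an accepted
  hop the full momentum vector is rescaled uniformly (equivalently, along
  the velocity direction) to conserve total energy exactly; energetically
  frustrated hops leave state and momentum unchanged. This convention needs
  no nonadiabatic-coupling vectors and is the least parameterized choice.
* **Decoherence** (per trajectory, inactive amplitudes damped, active
  renormalized to restore unit norm):
  * *EDC* (energy-based): $\tau_i = (1 + C/E_\mathrm{kin})/|E_i - E_b|$ with
    $C = 0.1\,E_h$; no damping at zero kinetic energy.
  * *PFM surrogate* (frozen-Gaussian projected forces and momenta): per
    inactive state with population $\ge \eta = 10^{-4}$, auxiliary offsets
    $(\delta s_i, \delta p_i)$ along the unit velocity integrate the
    projected force difference $(\vec F_i - \vec F_b)\cdot\hat v$, and the
    amplitude is damped each step by the Gaussian-overlap factor
    $\exp[-(\omega/4)\delta s_i^2 - \delta p_i^2/(4\omega)]$ with
    $\omega = 4.825\times 10^{-3}\,E_h$ (a geometric-mean vibrational
    frequency); offsets reset at hops and below $\eta$. This scheme preserves
    initial PGCs on parallel surfaces and damps coherence where forces
    differ; it sits behind a scheme interface so a different correction can
    be dropped in. Momentum injection is not implemented.
* **Repropagation** replays exactly the electronic-step + decoherence cycle
  using only quantities stored in the record (energies, $T$ matrices, active
  states, kinetic energies, projected force differences). Nothing is
  re-derived from the nuclear coordinates, which makes the frozen-trajectory
  contract auditable, and a replay from the record's own initial amplitudes
  is bit-identical to the stored coefficients for every decoherence scheme.
  Hops are never re-drawn.
* **Randomness**: each trajectory derives its own seed from a base seed and
  the member index, so ensembles are reproducible and order-independent; the
  Wigner sampler, the FP active-state draw, the SXE acceptance and the
  balancing draws all take explicit seeds.

## Model systems: what they emulate, and what they do not

No ab initio surfaces are involved: the electronic structure is supplied by
analytic diabatic models (`avoided_crossing_model()`, `lvc_model()`,
`glycine_like_model()`), adiabatized on the fly. The linear-vibronic-coupling
form is
$V(Q) = \tfrac12\sum_k \omega_k^2 Q_k^2\,I + \mathrm{diag}(\epsilon_i +
\sum_k \kappa_{ik} Q_k) + [\lambda_{ij,k} Q_k]$, in mass-weighted
coordinates, so mode $k$ oscillates at $\omega_k$ under $H = P^2/2 + V$ —
the same oscillator the Wigner sampler describes.

The `glycine_like_model()` preset mimics the qualitative electronic
structure of a small amino acid: three vibrational modes
($\omega = 0.010, 0.014, 0.018$ a.u.), three excited states at 6.4, 7.6 and
8.9 eV, the two lower transitions polarized along $z$ with moderate dipoles,
a brighter in-plane third transition, and an excited–excited transition
dipole along $x$ that makes the $S_1$–$S_2$ coherence visible in the
molecular dipole. Couplings are entered as $\kappa' \sqrt{\omega}$ with
$\kappa'$ of one to a few tenths of an eV — standard magnitudes in the
dimensionless-coordinate convention — chosen once so that the vertical-gap
spread over the Wigner ensemble is a few tenths of an eV. That spread sets
the ensemble dephasing time to a few femtoseconds, and the 1.2 eV $S_1$–$S_2$
gap sets a coherence period of ≈3.5 fs, so a broadband pump
($\Delta\omega = 2.83$ eV, intensity-fwhm duration ≈0.65 fs) covering both
states produces coherences that oscillate and decay within the 14.1 fs
simulation window. These are fixture choices, not quantum-chemistry results.

What passing tests on these fixtures do **not** show about real molecules:
the reference surfaces here are globally harmonic-plus-linear, so there is no
anharmonicity, no true conical-intersection topology in full dimensionality,
and no breakdown of the harmonic Wigner sampling (for an anharmonic ground
state the exact vibrational Wigner function would differ). Transferring
conclusions to ab initio surfaces requires only replacing the model-system
module, which is why it is isolated behind `evaluate_model()`.

## Numerical choices and degenerate inputs

Energies ascend and eigenvectors are orthogonal at every evaluated geometry;
degenerate eigenvalues are tie-broken by continuity (maximal overlap with the
previous step). Oscillator strengths reject non-positive transition energies.
`normalize_excited()` refuses a vector with zero excited population ("pulse
excites nothing at this geometry"). Hop probabilities are zero when the
active population vanishes. EDC at zero kinetic energy applies no damping;
PFM renormalization falls back to whole-vector scaling if the active
amplitude is exactly zero. Record stores are schema-versioned, uncompressed
RDS files (bit-exact round trip) with JSON sidecars and md5 manifests;
repropagation refuses records whose model hash differs from the model in
hand.

## Problem sizes used in the shipped tests

The validation suite exercises: 500-geometry FP vs RP-AXE vs RP-SXE
comparisons on a three-state fixture (agreement of normalized populations,
coherences and dipoles within twice the Monte-Carlo standard errors over the
first 8 fs); 100-trajectory no-hop exactness at $10^{-10}$; 500-trajectory
internal-consistency checks (EDC and PFM gaps below 0.05 at the end of a
Landau–Zener-type crossing); a 500-trajectory transmission comparison against
an exact split-operator wave-packet reference (within 0.05); Rabi and phase
closed forms at $10^{-6}$/$10^{-12}$; and a weak-field driven two-level
integration matching the first-order amplitudes to 1%. These sizes were
chosen as the smallest that leave the Monte-Carlo error comfortably below
each tolerance.

## Known limitations

Hops during repropagation are never re-drawn — precisely the approximation
the scheme is built on; use `flagged_hops` to detect wave packets born at or
near strong-coupling regions, where the approach is untested. The PFM
correction here is a frozen-Gaussian surrogate with the standard state
variables and parameters, not a literal transcription of any published
algorithm. Momentum rescaling is isotropic rather than along
nonadiabatic-coupling vectors, and frustrated hops do not reverse velocity.
The SXE estimator is unbiased but can converge slowly when the pulse strongly
excites a dim state; stratify by energy windows or fall back to the AXE in
that regime.
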