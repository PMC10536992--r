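---
title: "Methods: symplectic dynamics of artificially pair-decoupled systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symplectic dynamics of artificially pair-decoupled systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sefmd)
```

## The pair-decoupling model

`sefmd` simulates classical nuclear dynamics in which chosen pairs of
degrees of freedom are artificially decorrelated.  The decoupling acts on
the second derivatives of the potential: every Hessian element coupling
the two chosen groups is scaled by a coefficient $\alpha \in [0, 1]$,

$$\tilde h_{ij} = \alpha\, h_{ij}, \qquad h_{ij} =
\frac{\partial^2 V}{\partial q_i \partial q_j},$$

while diagonal elements are untouched (so $\mathrm{tr}\,\tilde h =
\mathrm{tr}\,h$ exactly).  At $\alpha = 0$ with groups that partition all
degrees of freedom, $\tilde h$ is block diagonal and the dynamics of the
blocks separates exactly; at $\alpha = 1$ nothing changes.  For
whole-atom decoupling the scaling is applied to the $3\times3$ Cartesian
blocks of the atom pair: the normal-mode Hessian is rotated to
mass-weighted Cartesian coordinates, scaled, and rotated back
(`cartesian_atom_decoupled_hessian()`).

Three modelling assumptions matter:

* **The decoupled system has no potential.** $\tilde h$ is generally not
  the Hessian of any scalar function, so there is no $\tilde V$ to
  differentiate and no gradient to call.  This is why a dedicated
  integrator exists at all.
* **The equilibrium of the coupled system is not a stationary point of
  the decoupled one.**  No re-optimization is attempted; runs start from
  the coupled equilibrium with the force estimate set to zero, as if the
  start were a minimum of the decoupled system too.
* **Decoupling is instantaneous decorrelation, not removal of
  interaction.**  At equilibrium the pair feels the normal forces; only
  the *response to displacements* is scaled.

## The SEF integrators

The force is obtained by integrating the Hessian along the trajectory,

$$\dot{\tilde F} = -\tilde h(\hat q)\, p ,$$

inside a symplectic kick–drift composition in mass-scaled coordinates
(unit mass).  The state is $(q, p, \tilde F, \hat q)$: $\hat q$ is an
auxiliary position that tracks the time argument of the momentum, and
coincides with $q$ at every full step for the schemes shipped here.  One
step is a sequence of stages:

* **kick** ($b$ coefficients): $p \leftarrow p + b\,\tau \tilde F$;
* **drift** of span $s$ ($a$ coefficients): $q \leftarrow q + s\,p$,
  $\hat q \leftarrow \hat q + s\,p$, and
  $\tilde F \leftarrow \tilde F - s\, \tilde h(\hat q + s p/2)\, p$.

**SEF2** is the leapfrog arrangement $a = (1/2, 1/2)$, $b = (0, 1)$ — the
unique second-order solution with $b_1 = 0$ — costing 2 Hessian
evaluations per step.  **SEF4** is the symmetric product of three SEF2
blocks with Forest–Ruth weights $\theta = 1/(2 - 2^{1/3})$, i.e. blocks of
length $\theta\tau$, $(1-2\theta)\tau$, $\theta\tau$.  Its merged drift
coefficients equal the standard Forest–Ruth $a_k$, $b_k$ tables.
Gradient-based references SE2 (position Verlet) and SE4 (Forest–Ruth) use
the same compositions with exact forces.

Two design choices here were genuinely open and deserve a record:

* **Where the Hessian is sampled.**  The force integration needs a
  quadrature of $\int \tilde h(\hat q(t))\,p(t)\,dt$ over each drift.
  Sampling at the drift *endpoint* keeps the quadratic-limit properties
  but costs an order: the per-substep bias is $O(s^2)$ and accumulates
  secularly, and the measured global order on a Morse oscillator drops to
  one.  Sampling at the drift *midpoint* makes every drift stage
  self-adjoint, so each SEF2 block is time-symmetric and the measured
  orders are 2.0 (SEF2) and 4.0 (SEF4) (`check_order_conditions()`).
  On quadratic surfaces the sample point is irrelevant and the force
  estimate is exact either way.
* **Why SEF4 keeps six drift segments.**  Merging the adjacent drifts of
  the three SEF2 blocks into the four-substep Forest–Ruth table — which
  would give 4 Hessian evaluations per step — caps the measured order at
  two for *every* placement of a single sample per merged drift (we
  scanned the symmetric one-parameter families numerically).  The
  backward-error picture explains it: Yoshida-style composition cancels
  the $O(\tau^3)$ defect only if the composed object is the same
  second-order map at three scaled steps, and merging drifts changes the
  force quadrature of that map.  SEF4 therefore executes the composition
  literally: 6 Hessian evaluations per step, the price of genuine fourth
  order.  SEF2 keeps the textbook 2 evaluations per step.

Further variants of the fourth-order coefficients built on the
Brewer–Hulme–Manolopoulos tables are typographically corrupted in our
source material and are not registered.

## Standard protocol and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `dt` | 10 | au of time (0.242 fs) | resolves vibrations up to $\omega \approx 0.03$ au (≈ 6600 cm⁻¹) with $\omega\,dt \lesssim 0.3$ |
| `n_steps` | 3000 | steps (0.73 ps) | enough for ≈ 46 cm⁻¹ FFT resolution |
| `discard_steps` | 0 (2000 of 5000 for weak decoupling) | steps | ≈ 0.5 ps of decorrelation so weakly decoupled fragments forget the coupled start |
| `T_half` (reversibility) | 6000 | au | round trip of 2 × 6000 au |
| monodromy `eps` | 1e-6 | mass-scaled au | central differences; convergence validated by halving |
| `alpha` | — | dimensionless | user-supplied per group pair; never inferred |

Initial conditions follow the zero-point-energy rule: every vibrational
mode starts at $Q_j = 0$ with $P_j = +\sqrt{\omega_j}$, so its kinetic
energy is $\omega_j/2$.  The sign of each momentum is physically
arbitrary; all-positive is the deterministic default, overridable per
mode.  The force estimate starts at zero.

## Normal modes, frames and freezing

Propagation always runs in mass-scaled normal coordinates: translations
and rotations are projected out (explicit Eckart construction of up to
six translation/rotation vectors in mass-weighted coordinates,
Gram–Schmidt orthonormalized), and the mass-weighted Hessian is
diagonalized in an orthonormal basis of the complement, which yields
exactly $3N - n_{\mathrm{proj}}$ vibrational modes with no zero-mode
bookkeeping.  A molecule is linear when a rotation vector's norm falls
below the `tol_linear` threshold (then $n_{\mathrm{proj}} = 5$).
Negative curvatures beyond `tol_imaginary` are flagged as imaginary
frequencies and block zero-point initialization; they are never silently
dropped.  The propagation frame matters because the SEF force estimate
cannot describe free translations or rotations (flat, strongly anharmonic
directions).

"Cartesian" in the rotate–scale–rotate atom-decoupling step means
*mass-weighted* Cartesian: the transform is then orthogonal on the
vibrational subspace, so symmetry is preserved exactly and $\alpha = 1$
returns the input to machine precision.  Note the subspace caveat: the
rotation back projects onto the vibrational space, so the composite is
$P S P$ with $P$ the vibrational projector — tested against the explicit
triple product, not against naive full-space intuition.

Frozen modes ("kept at equilibrium") are clamped after every step:
coordinate, momentum, force-estimate and auxiliary-position components
set to exactly zero.  All indices in the R API are 1-based.

## Diagnostics

* **Energy.**  `propagate()` records $E = |p|^2/2 + V(q)$ on the *fully
  coupled* surface.  With $\alpha \ne 1$ this physical energy is not the
  conserved quantity of the decoupled dynamics — on quadratic surfaces
  the conserved quantity is $|p|^2/2 + q^\top \tilde H q/2$, and the
  acceptance checks measure drift on exactly that, while the fully
  coupled energy oscillates boundedly.  Drift is summarized as the OLS
  slope of energy against step index.
* **Symplecticity.**  The monodromy matrix $M(t) = \partial z(t) /
  \partial z(0)$ is built column-wise from central finite differences of
  displaced trajectories.  A geometry displacement also displaces the
  initial force estimate by $-\varepsilon\,\tilde h(q_0)\,e_j$ — the
  force estimate is a function of the initial geometry, and omitting this
  term makes each displaced run see a shifted effective potential, which
  would report spurious symplecticity violations even on quadratics.  The
  deviation is $\Upsilon = \max |M^\top J M - J|$, the most stringent
  elementwise reading (a Frobenius variant is available).
* **Reversibility.**  Propagate to $T$, flip all momenta (the force
  estimate is carried through unchanged; its integration direction
  reverses through the flipped momenta), propagate to $2T$, and report
  the RMS over coordinate components of the position round-trip error.
  The functional form inside the round-trip measure is our reading
  (RMS over the $F = 3N_{at}$ Cartesian components); the underlying
  protocol (momentum flip at $T$, measure at $2T$) is standard.  On
  quadratics this is zero to roundoff for the time-symmetric schemes.

## Power spectra

The per-mode spectrum is the squared finite-time Fourier transform of the
mode momentum, $I_j(\omega) = |\hat p_j(\omega)|^2/(2\pi T)$, rectangular
window, grid spacing $\Delta\omega = 2\pi/T$; the total spectrum is the
pointwise sum over non-frozen modes.  The one-sided spectrum is folded so
that the discrete integral identity

$$\sum_\omega I_j(\omega)\,\Delta\omega = \overline{p_j^2}
 = 2 \times \text{mean kinetic energy of mode } j$$

holds exactly (discrete Parseval); this is the testable form of the
statement that the integrated spectrum is the average kinetic energy in a
band.  Zero padding (×4 by default in the README example) refines *peak
readout* only; Parseval checks use the raw grid.  Apodization is
deliberately absent by default — the short-simulation resolution claims
rest on the rectangular window — and intensities are arbitrary units,
not IR/Raman intensities.  Single-trajectory estimates are used
throughout (no phase-space averaging), matching the deterministic
zero-point initial conditions.

## What the bundled model systems emulate — and what they do not

The fixtures (`make_fixture()`, `make_spring_molecule()`) are built so
that every scenario class is exercised without external data:

* `harmonic_chain_k`: pinned chains with nearest-neighbour springs of
  $10^{-4}$ au (±10 % seeded jitter) and weak $2\times10^{-6}$ au
  long-range springs — coupled quadratic networks in the molecular
  frequency range (all modes ≤ ≈ 0.02 au, resolvable at `dt = 10`).
* `triatomic_morse_bend`: two Morse stretches (depth 0.1 hartree, width
  ≈ 0.07) with a bilinear coupling and a harmonic bend — mild
  anharmonicity typical of bonded stretches.
* `quartic_toy`: a three-mode quartic force field with seeded cubic and
  quartic constants — polynomial anharmonic coupling of normal modes.
* `coupled_pair_2d`: two modes (nominal 1316.8 / 2194.7 cm⁻¹) with a
  switchable bilinear coupling; `coupling = 0` gives the naturally
  separable limit in which decoupling must change nothing.
* `make_spring_molecule(n)`: unstrained central-force networks in 3-D
  whose Hessians have exactly six rigid-body zero modes, for normal-mode
  and Eckart tests (e.g. $3\cdot16-6 = 42$ vibrational modes).

The quadratic acceptance benchmark uses two coupled soft modes at ≈ 44
and 77 cm⁻¹ — the low-frequency torsional range where the roundoff-level
conservation statements are meaningful over a 3000-step window.  What
these systems do *not* emulate: fitted-surface extrapolation error,
near-degenerate Fermi resonances, floppy large-amplitude motion over
barriers, and densities of states of real 40+-mode molecules.  Passing
tests certify the integrator and the analysis chain, not the chemistry of
any particular molecule; chemistry enters through a user-supplied
`potential_surface()` (energy + gradient suffice; the Hessian falls back
to symmetrized central differences with an underflow guard and an
$O(\mathrm{step}^2)$ error).

Problem sizes in the test suite (3000-step runs, ≤ 3 DOF monodromy,
16-atom normal-mode systems) are chosen as the smallest sizes at which
each property is non-trivially exercised.

## Known limitations

* The decoupled force estimate is locally harmonic: strongly anharmonic
  (floppy) modes produce slow bounded oscillations of the physical energy
  and degrade time reversibility on anharmonic surfaces — by
  construction, not by bug.
* SEF4's fourth order costs 6 Hessian evaluations per step (see above);
  where Hessians are expensive, SEF2 is the economical choice.
* Monodromy via finite differences needs $4F$ (with convergence check
  $8F$) auxiliary trajectories; it is intended for few-DOF diagnostics,
  not production-size systems.
* No thermostats, no internal coordinates, no quantum corrections.
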