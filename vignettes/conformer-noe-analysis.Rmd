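---
title: "Quantifying a two-state side-chain flip from methyl NOEs and 15N relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a two-state side-chain flip from methyl NOEs and 15N relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A buried tryptophan indole that exchanges between two roughly perpendicular
orientations on the nanosecond timescale is invisible to crystallography at
a single condition (each crystal form freezes one orientation) but leaves
quantitative traces in solution NMR. `noemix` addresses the inverse
problem: given two candidate conformer structures, how much of each is
present in solution? Two independent observables constrain the answer —
the pattern of NOESY cross-peak volumes between the indole N–H proton and
the surrounding methyl groups, and the ¹⁵N relaxation of the indole N–H
itself. The packaged reference case is the FKBP12 active-site tryptophan,
whose flipped orientation is trapped in a proline variant of the 80′s
loop; the same machinery applies to any two-conformer methyl/probe system.

## NOE prediction and the methyl jump model

The initial build-up rate of an NOE between an isolated proton pair is
proportional to $6J(2\omega) - J(0)$; for a rigid isotropic tumbler this
factor is the same for every pair in the molecule, so *relative*
cross-peak volumes in one spectrum reduce to relative effective
$\langle r^{-6}\rangle$ interactions and all physical prefactors cancel
(`buildup_rate_factor()` exposes the factor itself; the package never
needs its absolute value).

A methyl group violates the point-pair picture: its three protons hop
between rotor sites, and that motion is far from isotropic. Treating the
methyl rotation as fast three-site jumps and factoring the internal motion
into a generalized order parameter gives the effective rate implemented in
`jump_effective_rate()`:

$$\sigma_{\mathrm{eff}} \;=\; \frac{1}{18}\sum_{i=1}^{3}\sum_{j=1}^{3}
\frac{3\cos^2\theta_{ij} - 1}{r_i^3\, r_j^3},$$

with $r_i$ the probe-to-proton distances and $\theta_{ij}$ the angle at
the probe between protons $i$ and $j$. A note on the denominator: this
expression is sometimes written with a single $r_j^3$, which is
dimensionally inconsistent for a pairwise dipolar average and fails the
far-field limit; the symmetric $r_i^3 r_j^3$ contraction used here reduces
to $1/d^6$ as the probe recedes along any direction and is verified in the
test suite against an independent rank-2 spherical-harmonic
addition-theorem oracle to $10^{-8}$ relative on 1000 random geometries.

Two common approximations are implemented alongside for comparison
(`centroid_rate()`): a single point at the methyl carbon, or at the mean
methyl proton position, with plain $1/r^6$. Far from the methyl, the jump
rate converges to the mean-proton rate at second order in (methyl
radius)/distance — the first-order term cancels because the protons are
symmetric about their centroid — while the carbon centroid retains a
first-order error from its ~0.36 Å axial offset from the proton plane
(about $6 \times 0.36/d$ relative, still 2–3% at 50 Å). Near contact the
approximations genuinely diverge, which is what makes the model comparison
informative.

### Methyl protons and geometry conventions

Crystal structures rarely contain refined methyl hydrogens, so
`build_methyl_protons()` constructs ideal ones: $|C{-}H| = 1.09$ Å,
H–C–antecedent angle 109.47°, 120° apart about the rotor axis, placed in
the staggered rotamer relative to the antecedent's reference substituent.
Only volume *ratios* matter downstream, so reasonable variations of these
constants rescale all rates nearly uniformly. If a structure does contain
methyl protons, `use_explicit = TRUE` uses them verbatim. Coordinates are
taken as orthogonal Å exactly as deposited; alternate locations default to
the highest-occupancy conformer; no symmetry expansion is performed.

### Table prediction

`predict_noe_table()` gates methyls by the methyl-carbon-to-probe distance
(default cutoff 7 Å — the convention under which the packaged reference
distances are tabulated, rather than the closest-proton distance), sums
chemically-shift-degenerate pairs through a user-supplied merge map
*before* normalization, supports per-entry exclusions, and normalizes to
the maximum entry. The absolute maximum raw rate is retained so that two
structures' tables can be placed on a common scale
(`cross_structure_scale()`).

## Two-conformer mixture fitting

With per-structure normalized tables $A$ and $B$ and inter-structure scale
$s$, the mixture prediction at population $p$ of conformer A is

$$u(k) = p\,s\,A(k) + (1-p)\,B(k),$$

renormalized to its own maximum, over the union of keys (an entry outside
one structure's cutoff contributes zero from that conformer — it stays in
the residual set rather than being dropped). `fit_population()` scans $p$
on a grid (default 1% steps), refines the argmin by golden-section search
to $10^{-4}$, and reports RMSD over all common entries and the Pearson
correlation. Conventions chosen where the analysis leaves room:

- The RMSD denominator counts all entries including the self-normalizing
  anchor (N = 9 for the reference table). On the reference data this
  reconstruction gives RMSD 0.0879 and r 0.9763 at p = 0.80 — consistent,
  at the printed rounding, with the published 0.086/0.976.
- The scale $s$ is a fixed input, not a fit parameter (the reference
  analysis fixes it at 0.28; `cross_structure_scale()` recomputes it per
  model when structures are available — from the reference carbon
  distances it is $(3.32/4.14)^6 \approx 0.266$).
- Grid ties break toward larger $p$ (toward conformer A); identical tables
  produce a flat scan, flagged `degenerate`, with the optimum reported at
  the grid midpoint.

`compare_models()` repeats the fit under the jump, carbon-centroid and
mean-proton models. On the reference data the jump model fits best (RMSD
0.087 vs 0.123 for the carbon centroid at its 82% optimum); the mean-proton
variant requires full coordinates and is exercised on synthetic scenes,
where volumes generated under the jump model are always fitted at least as
well by it as by either centroid.

## Extended model-free analysis of the probe ¹⁵N

`forward_relaxation()` implements the standard amide ¹⁵N dipolar + axially
symmetric CSA expressions for $R_1$, $R_2$ and the heteronuclear NOE, with
the spectral density

$$J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
\frac{(S_f^2 - S^2)\,\tau'}{1+(\omega\tau')^2}\right],
\qquad \frac{1}{\tau'} = \frac{1}{\tau_c} + \frac{1}{\tau_e},$$

where $S^2 = S_f^2 S_s^2$, the fast component is taken in the
extreme-narrowing limit (no dispersive term of its own), and $R_{ex} = 0$
by default for the indole fit (its resonances show no exchange
broadening). Two conventions deserve explicit mention:

- **Signed transition frequencies.** The ¹⁵N gyromagnetic ratio is
  negative, so the zero-quantum dipolar term samples
  $J(\omega_H + |\omega_N|)$ and the double-quantum term
  $J(\omega_H - |\omega_N|)$. `nucleus_constants()` carries the signed
  $\omega_N$ and the formulas evaluate $J$ at $|\omega_H \mp \omega_N|$
  accordingly. This matters: with three observables and three parameters
  the fit is exactly identified, and the magnitude-only convention shifts
  the fitted $\tau_e$ from ~1.45 ns to ~0.72 ns (the total $S^2$ is almost
  unchanged). The signed convention is the physically correct one and is
  the package default.
- **Bond length and CSA.** $r_{NH} = 1.02$ Å and CSA $= -126$ ppm (indole
  Nε1) are the defaults; $r_{NH}$ is the dominant systematic knob — its
  $r^{-6}$ leverage moves the fitted $S^2$ by roughly 6% per 0.01 Å — so
  it is exposed and recorded in the serialized fit.

`fit_modelfree()` does unweighted least squares (no uncertainties are
attached to the reference rates) by multi-start Nelder–Mead over a grid of
total-$S^2$ (0.1–0.9) and $\tau_e$ (0.05–3 ns) starting points, in
logit/log transformed coordinates so the box constraints are implicit.
Ties break by lowest $\chi^2$, then largest $S^2$. When the slow-component
amplitude $S_f^2 - S^2$ falls below $10^{-3}$, $\tau_e$ carries no
information and the fit is flagged `tau_e_indeterminate` (e.g. for rigid
synthetic input). On the reference observables ($R_1 = 1.50$ s⁻¹,
$R_2 = 5.56$ s⁻¹, NOE $= 0.634$, $\tau_c = 5.8$ ns) the fit returns
$S^2 = 0.632$, $\tau_e = 1.45$ ns with $\chi^2 \approx 10^{-16}$.

The sanity band used in the tests — a rigid amide at $\tau_c = 5.8$ ns and
14.1 T has $R_1$ between 1 and 3 s⁻¹ — guards the SI prefactors.

### Two-site jump order parameter and thermodynamics

For a bond vector hopping between orientations separated by $\theta_{ab}$,
$S^2 = 1 - 3 p_a p_b \sin^2\theta_{ab}$ (`jump_order_parameter()`): 0.53
for a 20% population across an 83° flip. The jump model omits fast
librations (which alone give well-ordered amides $S^2 \approx 0.85$), so
it is expected to undershoot the relaxation-derived $S^2$; multiplying the
two pictures is deliberately left to the user. `delta_g()` and
`delta_delta_g()` convert populations to free energies at $T = 298.15$ K
(R = 8.314 J mol⁻¹ K⁻¹); the population argument tracks one designated
state, which need not be the minor one in every variant (12:88 vs 67:33
gives $|\Delta\Delta G| = 6.7$ kJ/mol).

## Differential chemical shifts vs exchange broadening

Structure-based ¹⁵N shift predictors are too imprecise (σ ≈ 2.5 ppm) for
absolute comparisons, but conformer *differences* of predictions for the
same sequence cancel much of the systematic error. The package therefore
only consumes external predictor output (`read_shift_predictions()`, a
SPARTA+-style whitespace table) in a differential mode:
`differential_shift()` maps residue numbering between a reference and
comparison structures (including mutated-to-alanine bookkeeping via an
explicit mapping), and aggregates either per structure or against the mean
over comparison structures. `correlate_broadening()` then reports the
Pearson correlation against measured exchange linebroadening over residues
passing a significance threshold (default 0.4 Hz), with explicit
bookkeeping of used / flag-excluded / sub-threshold / unpaired residues.
Pearson on the raw pairs is a documented choice; no quantitative
$R_{ex} \propto \Delta\delta^2$ modelling is attempted.

## The synthetic benchmark

`make_scene()` builds what the reference system looks like geometrically:
a central probe N–H, and valine-like CA–CB–CG1 methyl fragments (so the
degeneracy-merge path is exercisable) at 3–8 Å from the probe with random
orientations and a 1.5 Å minimum separation (rejection sampling;
infeasible requests error). Conformer B rotates the probe bond by a
configured angle (default 83°) and rigidly displaces a subset of methyls
(default 3 of 8 by 1.5 Å). `simulate_noe_volumes()` mixes the two
conformers' predictions at a true population and applies multiplicative
log-normal noise (σ = 5% default — peak-volume errors scale with
intensity; the reference data carry no stated error model) before
renormalizing. `simulate_relaxation()` forward-computes observables from
known model-free parameters with optional Gaussian noise. All generators
are pure functions of (configuration, seed) and leave the caller's RNG
state untouched.

What the scene does *not* emulate: spin diffusion (the reference
experiments suppress it by deuteration, and no relaxation-matrix treatment
is implemented), anisotropic tumbling, and the specific packing of the
real protein — in particular, methyl axes are isotropically oriented, so
the characteristic failure of the mean-proton approximation for probes
along a methyl axis is much weaker in the scenes than in the real
geometry. Passing synthetic tests therefore validates the estimator
machinery (inversion, noise propagation, normalization), not the
approximation ranking on real structures, which is asserted from the
packaged reference table instead.

Problem sizes used in the shipped tests: 1000 random geometries for the
oracle equivalence, 200 replicates for the noisy population-recovery study
(run at the reference 80:20 condition, where 99%+ of replicates recover
the truth within ±0.05; at a 20:80 truth the same scene recovers the
median faithfully but single replicates scatter more widely), 40–100
random parameter draws for the model-free round trips.

## Known limitations

- Two conformers only; no three-state mixtures, no per-entry experimental
  weighting.
- No global $\tau_c$/diffusion-tensor optimization: $\tau_c$ is an input,
  as the reference analysis derives it from the backbone amide set.
- The 7 Å cutoff and carbon-gating conventions follow the packaged
  reference table; other data sets may need the `cutoff`/`exclude`
  arguments.
- Exactly-identified model-free fits interpolate the data; parameter
  uncertainties must come from the observables' errors (not modelled here
  beyond the simulation tools).
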