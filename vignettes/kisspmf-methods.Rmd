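---
title: "Methods: PMF reconstruction and base-contact annotation for kissing loops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMF reconstruction and base-contact annotation for kissing loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kisspmf)
```

## The problem

A kissing complex forms when the hairpin loops of two RNA stems (here
labelled L2, residues 20–26, and L3, residues 48–54, the numbering of a
purine-riboswitch aptamer) pair with each other. Umbrella sampling along
the distance *L* between the backbone centres of mass of the two loops
gives biased samples of *L* in a ladder of harmonically restrained windows;
the unbiased free-energy profile G(L) (the potential of mean force, PMF)
must then be reconstructed, its statistical error quantified, and the
forward/backward protocol dependence (hysteresis) diagnosed. Alongside the
thermodynamics, one wants to know *which contacts* hold the complex
together in each window: Watson–Crick pairs, non-canonical pairs, and
stacking, counted inter- and intra-loop. This package implements that
analysis layer; it runs no dynamics.

## The collective variable

*L* is the Euclidean distance between the mass-weighted centres of the
backbone atoms of the two loops. "Backbone" is not a uniquely defined set;
the default is `P, OP1, OP2, O5', C5', C4', C3', O3'`, with a switch to
drop the non-bridging phosphate oxygens (`backbone_atoms(FALSE)`) and a
switch to a geometric centroid — the original study says "centre of mass
of the backbone atoms" without enumerating them, so both knobs are exposed
and the literal mass-weighted reading is the default. 5'-terminal residues
lacking a phosphate contribute their remaining backbone atoms. Residue
numbering is the PDB's own; insertion codes are rejected and only the first
alternate location is kept.

## Base-contact annotation

A local frame is built at the unweighted centroid of each base's
six-membered ring (N1, C2, N3, C4, C5, C6; purines use their pyrimidine
ring): ẑ is the least-squares ring-plane normal (sign fixed
deterministically by the N1→C2→N3 winding; only |z| enters any criterion),
x̂ is the in-plane direction toward C2, ŷ = ẑ × x̂. With r_jk the position of
ring centre *k* in frame *j* and the ellipsoidal distance
D = x²/25 + y²/25 + z²/9 (semiaxes 5, 5, 3 Å), pairs are classified in
strict precedence — Watson–Crick, else non-canonical, else stacking, else
none — which makes the four categories mutually exclusive and exhaustive by
construction. The classification is symmetric in (j, k) and rigid-motion
invariant.

Numerical and interpretive choices:

* **Stacking z-window.** The printed criteria require |z| < 2 Å for
  *both* pairing and stacking, which no physical stack (|z| ≈ 3.4 Å) can
  satisfy and which would make the two categories collide. The default
  implements |z| ≥ 2 Å for stacking; `literal_stack_z = TRUE` restores the
  printed inequality for anyone wanting the literal behaviour.
* **Stacking radial cutoff.** "x² + y² < 5 Å" is dimensionally ambiguous;
  it is read as 5 Å² (radial offset < √5 ≈ 2.24 Å), and it is configurable.
* **WC model.** The Watson–Crick test is a product of two trivariate
  normal densities (full covariance, not three independent 1-D normals)
  exceeding 1e-8. The original calibration set (WC pairs of a ribosomal
  crystal structure) is not published as numbers, so the shipped model is
  calibrated — once per session, with a fixed internal seed — on idealized
  jittered WC geometries from the package's own generator. Absolute scores
  therefore do not match the original; the *decision structure* does. Users
  can recalibrate with `calibrate_wc_model()` from any annotated set. A
  consistency test guarantees every detected WC pair also satisfies the
  non-canonical geometric envelope (D < 2.5, |z| < 2).
* **Sequence neighbours** are included in all categories by default
  (intra-loop stacking between consecutive residues is the A-form signal);
  `exclude_adjacent_pairing = TRUE` removes |Δindex| = 1 pairs from the two
  pairing categories only. Whether the original analysis excluded them is
  unstated.

## Umbrella design and WHAM

Windows are uniform: canonically 44 centres from 12.5 to 34 Å
(0.5 Å spacing), stiffness k = 20 (kcal/mol)/Å². The bias convention is
U = ½k(L−L₀)² — the convention of the common biasing engines; the study
does not state it, so `full_k` is available for cross-checks. The
sequential initialization protocol (short stiffer-restraint pre-runs,
forward or backward iteration order) is represented as metadata only.

WHAM iterates
p(b) = Σᵢ nᵢ(b) / Σᵢ Nᵢ exp((fᵢ − Uᵢ(b))/kT),
fᵢ = −kT ln Σ_b p(b) exp(−Uᵢ(b)/kT)
from fᵢ = 0 until max |Δfᵢ| < 1e-7 kcal/mol (cap 1e5 iterations), with
kT = 0.0019872041 × 298 K by default. Defaults the source does not state
and which are therefore this package's decisions: bin width 0.1 Å on
[12, 34.5] Å; convergence tolerance; alignment pins the single bin
containing the reference distance (no interpolation — the coarsest valid
reading of "aligned at their CV starting value"). Empty bins carry
G = +∞ and are excluded from minima, alignment and error propagation. The
solution is deterministic, invariant to window order and to splitting a
window into two with identical bias, and reduces exactly to
−kT ln(hist/N) for a single unbiased window.

**Blocking errors.** The production segment (by default the last 4 ns of
each 5 ns window — `discard_equilibration(keep_last = 4000)`) is split into
four contiguous equal-duration blocks; WHAM is solved once per block using
block *b* of every window; block profiles are aligned at the campaign's
starting value; the per-bin error is the sample standard deviation (n−1
normalization) across the four block profiles divided by √4. ΔG errors
combine the minimum and reference bins in quadrature.

A caveat the test suite encodes: with four blocks the error estimate has
three degrees of freedom, so the error-normalized deviation of a bin is
t₃-like — roughly 6% of independent bins exceed 3 error bars even for a
perfect estimator. Per-bin checks therefore assert ≥95% coverage and a
median deviation below 1.5 errors; the headline quantity (ΔG within 3× its
blocking error) holds as stated.

**ΔG and hysteresis.** Undocking ΔG = G(L_ref) − G(L_min) ≥ 0, with
L_ref = 34 Å the undocked reference; minima are bin centres, ties broken
toward smaller L, edge minima flagged. `hysteresis_report()` aligns the
forward and backward profiles at L_ref and reports both ΔGs, the maximum
aligned-profile gap, and ΔΔG bounds (min, max of the two estimates) — the
converged answer is expected to lie between them when sampling is not
converged.

## What the synthetic generator emulates — and what it does not

`sample_window()` draws *equilibrium* samples from
p(L) ∝ exp(−β(G(L)+U(L))) by grid inverse-CDF (resolution 0.01 Å, ≪ the
0.17 Å thermal width at k = 20), optionally as a Gaussian-copula AR(1)
chain: autocorrelation is added without changing the stationary marginal,
so blocking has something to absorb while the target density stays exact.
Defaults are the stated world of the emulated study: 44 windows, 5000
samples per 5 ns window (1/ps), the last 4 ns analyzed in four 1 ns blocks,
298 K. `ar1_phi` defaults to 0 (independent samples); correlation is
opt-in where a test exercises it.

Hysteresis is emulated by *planting* a PMF asymmetry: backward-direction
campaigns sample a PMF whose docked basin (below L* = 24 Å, a narrow
logistic step) is raised by `hysteresis_shift`, mimicking a backward
protocol in which the native WC pairs never re-form. This gives a known
ΔΔG ground truth; it does not emulate the *mechanism* (slow orthogonal
degrees of freedom), only its thermodynamic signature.

The default double-well PMF places the docked well at 15 Å (depth 9) and a
shallow well at the undocked reference 34 Å (depth 1), widths 1.2 Å, with a
2 kcal/mol barrier at 24 Å: a well-depth difference of 8.0 kcal/mol, far
enough apart that the Gaussian tails overlap negligibly (< 1e-4 kcal/mol),
so the analytic ΔG at the 34 Å reference is 8.0 to better than 1e-3. These
are round, desk-scale numbers chosen once for testability — real PMFs for
this system are an order of magnitude larger in the forward estimate, and
no synthetic test here says anything about force-field accuracy, solvent,
ions, or the real system's ΔG.

Geometry fixtures are idealized: hexagonal rings of radius 1.4 Å plus three
backbone markers — only the atoms the annotation and CoM machinery touch.
The synthetic kissing complex places the two planted WC pairs (G25–C49,
G26–C48) at the exact nominal WC geometry and splays the remaining
residues away so no accidental inter-loop contact arises; it is a labelled
stand-in for a crystal structure, not a model of one. A green annotation
test establishes that the classifier implements the stated criteria, not
that the criteria agree with any external annotation tool on real RNA.

## Degenerate inputs and tie-breaks

Collinear rings and missing ring atoms are errors naming the residue;
non-overlapping adjacent window histograms are errors naming the gap;
non-convergence reports the residual; series shorter than the requested
production span, empty CV files and shuffled time stamps are errors. A
window with zero stiffness is allowed (the unbiased limit), as is a window
centre of 0 in the abstract grid constructor. Jitter above 0.25 Å on pair
recipes is refused because the planted label is no longer guaranteed by
construction (labels sit ≥ 0.3 Å from every decision surface at jitter 0).

## Known limitations

* No MBAR, no Bayesian WHAM, no 2-D PMFs, no autocorrelation-time
  estimation beyond what blocking absorbs.
* No Leontis–Westhof edge classification, hydrogen-bond detection, or
  sugar-pucker annotation; purines are reduced to their pyrimidine ring.
* The absolute free energies of the emulated study are not reproducible
  from this package: they require the original explicit-solvent
  trajectories, which were never deposited. What is reproducible — and
  tested — is the machinery: design facts, estimator correctness on known
  ground truth, and the diagnostics' ability to recover planted effects.
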