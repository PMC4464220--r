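# kisspmf

Analysis machinery for umbrella-sampling studies of RNA **kissing-loop
complexes** — the tertiary contact in which the hairpin loops of two stems
base-pair with each other, as in purine-riboswitch aptamers. The package
covers everything downstream of the molecular-dynamics engine:

* **Structure I/O and the collective variable.** Multi-model PDB reading
  into a minimal structural model, loop selection by residue range, and the
  collective variable *L* = distance between the backbone centres of mass
  of the two loops (default backbone set `P, OP1, OP2, O5', C5', C4', C3',
  O3'`; mass-weighted).
* **Base-contact annotation.** A local orthonormal frame is built at the
  centroid of each base's six-membered ring (x toward C2, z normal to the
  least-squares ring plane). With r_jk the position of ring centre *k* in
  frame *j*, pairs are classified in strict precedence:
  1. **Watson-Crick** — sequence is AU or GC and
     N(r_jk; mu, sigma) x N(r_kj; mu, sigma) > 1e-8 (trivariate Gaussian
     model, calibratable from any annotated structure set);
  2. **non-canonical pair** — D_jk < 2.5 and D_kj < 2.5 and |z_jk|, |z_kj|
     < 2 A, where D = x^2/25 + y^2/25 + z^2/9 is the ellipsoidal distance;
  3. **stacking** — D within cutoff, |z| >= 2 A and in-plane offset
     x^2 + y^2 < 5 A^2 on both sides;
  4. otherwise **none**.
* **Umbrella design.** Uniform window grids (canonically 44 windows from
  12.5 to 34 A, k = 20 (kcal/mol)/A^2, U = 1/2 k (L - L0)^2),
  forward/backward initialization-order metadata, and a plain-text CV
  time-series dialect.
* **WHAM + blocking errors.** Self-consistent solution of the weighted
  histogram equations for G(L) = -kT ln p(L); per-bin errors from four
  contiguous 1-ns blocks (std across block profiles / sqrt(4)); profile
  alignment at a reference distance; Delta G extraction
  (undocking: G(L_ref) - G(L_min)) and forward/backward hysteresis
  diagnostics with Delta-Delta-G bounds.
* **Synthetic data with known ground truth.** Equilibrium biased samples
  drawn from exp(-beta (G + bias)) for analytic PMFs (grid inverse-CDF,
  optional AR(1) Gaussian-copula autocorrelation, optional planted
  forward/backward asymmetry), plus idealized labelled base geometries —
  including a synthetic kissing complex with two planted inter-loop WC
  pairs (G25-C49, G26-C48 in the aptamer numbering).

Intended users: people post-processing biased MD of RNA tertiary contacts,
and anyone needing a self-contained, testable WHAM/blocking/hysteresis
reference implementation.

## Worked example

Annotate the synthetic kissing complex:

```r
library(kisspmf)
kc  <- build_geometry(geometry_recipe("kissing_complex"), seed = 1)
res <- annotate_frame(kc, loop_definition("L2", 20, 26),
                      loop_definition("L3", 48, 54))
res$counts
#>   wc_inter noncanonical_inter stack_inter stack_intra wc_intra noncanonical_intra
#> 1        2                  0           0          12        0                  0
```

Two inter-loop Watson-Crick pairs (G25-C49, G26-C48) and six sequential
intra-loop stacks per loop — the planted ground truth.

Reconstruct a PMF and extract the undocking free energy. The default
double-well PMF has a docked well at 15 A and a shallow well at the
undocked reference 34 A, with a well-depth difference of 8 kcal/mol:

```r
pmf <- analytic_pmf("double_well")
ws  <- make_windows(12.5, 34, 44, 20)              # 44 windows, 0.5 A apart
ser <- sample_campaign(pmf, ws, sampler_settings(seed = 1, n_per_window = 5000))
ser <- lapply(ser, discard_equilibration, keep_last = 4000)  # last 4 ns
prof <- wham_profile(ser, wham_settings(), n_blocks = 4, align_at = 34)
extract_delta_g(prof, 34)[c("delta_g", "error", "L_min")]
#> $delta_g
#> [1] 8.014124
#> $error
#> [1] 0.1566004
#> $L_min
#> [1] 15.05
```

The planted 8 kcal/mol is recovered within one blocking standard error.
Planting a 5 kcal/mol hysteresis in the backward campaign
(`sample_campaign(..., hysteresis_shift = 5)` with a backward window set)
yields `delta_g_forward = 8.01`, `delta_g_backward = 2.96`,
`max_profile_gap = 5.27` and Delta-Delta-G bounds `(2.96, 8.01)` — the
forward/backward discrepancy a non-converged pulling protocol produces.

A command-line front end wraps the same operations
(`inst/cli/kisspmf windows|synth-cv|synth-structure|annotate|wham|deltag|compare`).

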