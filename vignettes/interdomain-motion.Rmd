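---
title: "Quantifying interdomain motion from paramagnetic NMR restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interdomain motion from paramagnetic NMR restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paramotion)
```

## The physical model

A lanthanide ion bound in one domain of a two-domain protein acts as a
paramagnetic reporter. Its anisotropic magnetic susceptibility
$\Delta\chi$ (a traceless symmetric $3\times3$ tensor, here in units of
$10^{-32}\,\mathrm{m}^3$) produces three observables that `paramotion`
predicts and fits:

* **Pseudocontact shifts (PCS).** For a nucleus at $\vec r$ from the metal,
  $$\delta_{\mathrm{pcs}} = \frac{1}{4\pi r^3}\,
  \hat r^{T}\,\Delta\chi\,\hat r,$$
  the point-dipole result; it decays as $r^{-3}$ and vanishes on the magic
  angle.
* **Residual dipolar couplings (RDC).** The susceptibility anisotropy
  partially aligns the molecule in the field, leaving the residual
  $$D = -\frac{B_0^2\,\gamma_1\gamma_2\,\hbar}
  {40\pi^2 k_B T\, r^3}\; \hat n^{T}\,\Delta\chi\,\hat n,$$
  the static dipolar splitting scaled by the orientational average
  $\langle P_2\rangle = \tfrac32\,\hat n^T A\,\hat n$ with the alignment
  tensor $A = B_0^2 \Delta\chi / (15\mu_0 k_B T)$. RDCs grow with $B_0^2$.
* **Residual chemical-shift anisotropy (RCSA).** The same alignment shifts
  every resonance by $\delta_{\mathrm{rcsa}} = \sum_{ij} A_{ij}\,
  \delta^{\mathrm{dev}}_{ij}$, the contraction of $A$ with the traceless
  part of the nuclear shift tensor. It is additive to the PCS, does not
  decay with distance from the metal, and is only included for carbonyl
  carbon and amide nitrogen, whose shift anisotropies are largest.

All three are **linear in the five independent tensor components**, which is
what makes the fitting a deterministic weighted least-squares problem and
the ensemble prediction a matrix product.

Each prefactor lives in exactly one internal function, and each is pinned by
an independent oracle in the test suite: the PCS against the classical
axial/rhombic angular closed form, the RDC and RCSA against a numerical
Boltzmann average over field orientations (Gauss–Legendre quadrature of
$\langle P_2 \rangle$ and $\langle \hat b^T\delta\hat b\rangle$ under the
anisotropic magnetizability energy). During development that oracle caught a
factor-$\tfrac32$ transcription error — this is precisely the class of
mistake it exists to catch, since alignment-tensor normalization conventions
differ between papers.

### CSA defaults

The shift-tensor principal values and in-plane orientations default to
approximate consensus solid-state values (carbonyl: 244/178/90 ppm with the
most-shielded axis normal to the peptide plane; amide nitrogen: 223/55/79
ppm with the least-shielded axis about 19° from the N–H bond). They are
plain configuration constants (`csa_tensor()`); users with better
system-specific tensors should supply them.

## Tensor component conventions

Published tensor tables parameterize $\Delta\chi$ as
$(\Delta\chi_{ax}, \Delta\chi_{rh}, \Delta\chi_{xy}, \Delta\chi_{xz},
\Delta\chi_{yz})$. Two conventions for the axial component are in
circulation, and `chi_tensor()` makes the choice explicit:

* `"axial"`: $\Delta\chi_{ax} = 2\Delta\chi_{zz} - \Delta\chi_{xx} -
  \Delta\chi_{yy}$, i.e. $\Delta\chi_{zz} = \Delta\chi_{ax}/3$;
* `"element"`: the first component *is* $\Delta\chi_{zz}$ (and the second
  $\Delta\chi_{xx}-\Delta\chi_{yy}$), i.e. the tabulated numbers are matrix
  elements.

This matters for every comparative statistic, because the two readings scale
the diagonal relative to the off-diagonal entries differently and therefore
change eigenvalues, eigenframes, and scalar products. The lanthanide table
bundled with the package (`lanthanide_tensors()`) defaults to `"element"`:
under that reading the package reproduces the published derived statistics
of the CaM/Munc13-1 reference system simultaneously — the Tm·Tb normalized
scalar product of $-0.92$, the ~9° Tm–Tb eigenframe angle, the pooled
eigenvalue-regression order parameter of $0.162$, and the
1-in-15 000 random-rotation frequency — whereas the `"axial"` reading
reproduces none of them. The test suite checks all four.

Two further measurement conventions are worth stating explicitly:

* **Normalized scalar product.** `normalized_scalar_product()` defaults to
  the Euclidean inner product of the five-component vectors (the metric in
  which component tables are conventionally compared); the Frobenius matrix
  inner product is available via `on = "matrix"`. The two differ slightly
  because the component basis is not orthonormal under the Frobenius metric.
* **Eigenframe angle.** An eigenframe is defined only up to the symmetry
  operations of its axis system. `eigenframe_angle()` therefore minimizes
  the relative rotation angle over all 24 proper signed axis permutations by
  default. This is essential for near-antiparallel tensors (such as Tm and
  Tb here), whose eigenvalue orders are reversed: restricting to sign flips
  at fixed ascending order (`match_axes = FALSE`) yields a meaningless ~89°.
  A per-axis mean-angle variant (`method = "axes"`) is also provided. For
  the bundled table the rotation-angle definition gives 9.0° for Tm–Tb and
  a 15-pair mean of 20.2°; the per-axis definition gives 7.2° and 15.8°. No
  single definition reproduces both published summary numbers (9° and
  ~16°) from the rounded table — the package reports the rotation-angle
  definition for both and documents the alternative.

## Fitting the metal-domain tensor

`fit_tensor()` solves the weighted linear system row-by-row assembled from
the restraints (`assemble_linear_system()`), with agreement measured by
$$Q = \sqrt{\sum w^2 (x_{exp}-x_{calc})^2 \Big/ \sum w^2 x_{exp}^2}.$$

* **Group weighting.** PCS (ppm) and RDC (Hz) are combined by scaling each
  group with its inverse standard deviation, estimated from the residual
  RMSD and iterated to a fixed point (`estimate_group_scales()`, relative
  tolerance $10^{-4}$). Inverse-σ rather than inverse-variance weighting is
  deliberately mild, for robustness against heavy-tailed errors; the
  synthetic generator's Student-t option exercises exactly that claim. RDC
  types are weighted separately only when every type has at least 15
  records, else pooled — with few records a per-type scatter estimate is
  noisier than the bias it removes.
* **Effective bond lengths.** N–H and Cα–Hα librations shrink observed
  RDCs; predictions use only the bond orientation with effective lengths
  1.041 Å and 1.117 Å.
* **Metal position.** The ion is initially placed at the crystallographic
  site; `optimize_metal_position()` refines it by Nelder–Mead minimization
  of $Q_{\mathrm{PCS}}$, refitting the tensor at each trial position
  (geometry is resolved once, so each refit is a cheap 5-parameter solve).
  Moves beyond 5 Å abort as unphysical. The attainable position precision
  is set by the proximal-PCS signal-to-noise: in synthetic tests a 0.6 Å
  displacement is recovered to ±0.05 Å for a strong tensor (Dy-like) with
  ~180 PCS, while weak tensors (Yb-like) leave a flat objective within
  ~0.2 Å.
* **Uncertainties.** `bootstrap_tensor()` resamples records with
  replacement, refits, and reports the per-component RMSD about the
  full-data estimate; degenerate resamples are redrawn (capped at 10× the
  resample count).

## Rigid-body arrangements and the prediction matrix

Interdomain arrangements are $4\times4$ homogeneous transforms
(`rigid_transform()`): positions carry weight 1, internuclear vectors weight
0, making RDCs translation-invariant by construction. Conformer pools are
imported from a flat text format (12 numbers per line) or derived from
coordinates by SVD superposition (`superposition_transform()`). Generating
conformers by molecular mechanics is out of scope.

`build_prediction_matrix()` predicts every mobile-domain restraint for every
pool member (tensors stay fixed in the metal-domain frame; the structure is
carried by the transform). Rows are verified in the test suite against
direct forward prediction on explicitly transformed coordinates. A guard
refuses matrices beyond $10^8$ entries unless overridden.

`optimal_pivot()` asks whether an ensemble's rotations share a single pivot:
it minimizes $\sum_i p_i\lVert t_i + (R_i - I)\,o\rVert^2$ over the origin
$o$ (minimum-norm least squares, since $R_i - I$ is singular along each
rotation axis) and reports the residual translation lengths.

## Ensemble selection

Populations for a candidate member set are assigned by non-negative least
squares with the sum-to-one constraint imposed through one extra row of
magnitude $\lambda$ in the coefficient matrix and data vector
(`constrained_nnls()`). The active-set solver returns exact zeros, which
defines the **effective ensemble size** $n_{\mathrm{eff}}$; populations
below $10^{-9}$ are treated as numerically zero (they arise only as
floating-point residue when the data are fitted exactly).
$\lambda = 10^4\times$ the largest weighted matrix entry keeps the sum error
below $10^{-6}$ (the sum deviation scales as $\lambda^{-2}$; a $10^3$
multiplier leaves ~$10^{-5}$) while preserving double-precision
conditioning.

Model selection is embedded in the fitness: with the data scaled to unit
scatter, the BIC of an ensemble with $k = 7\,n_{\mathrm{eff}}$ parameters
(6 rigid-body degrees of freedom + 1 population per effective member) and
scatter estimated by the RMSD is $n\ln(\mathrm{rmsd}^2) + k\ln n$, and
$$f = \mathrm{rmsd}\cdot n^{\,k/(2n)} = e^{\mathrm{BIC}/(2n)}$$
is its strictly monotone transform — same ordering, but on the intuitive
scale of an RMSD (at $k=0$, $f$ *is* the RMSD). The test suite verifies the
ordering equivalence on 1000 random model pairs and the consistency of the
transform with the reference system's reported best-model fitness.

`evolve_ensembles()` runs an elitist genetic algorithm over fixed-size
member-index sets: the best `elite_frac` are copied unchanged (the best
fitness is therefore non-increasing), parents are drawn with probability
$\propto e^{-\mathrm{rank}/\tau}$, children arise by uniform crossover and
per-slot mutation, and duplicates within a candidate are collapsed before
NNLS. Defaults (nominal size 20, elite 5%, $\tau = $ population/5, mutation
$1/\mathrm{size}$, crossover 1) were chosen to satisfy the planted-ensemble
recovery property below; all are exposed in `ga_config()`. Runs are fully
reproducible from `seed`.

Because the fitness landscape is multimodal, single runs can stall in local
optima; practice (and the reference analysis) is many independent seeded
runs, summarized by `run_statistics()`, with significance judged against the
bootstrap spread of fitness differences (`fitness_difference_sigma()`): two
ensembles closer than about twice that spread are indistinguishable given
the data scatter.

## The synthetic-data generator

`make_scenario()` builds a fully known ground truth: two rigid point-cloud
pseudo-domains whose residues carry backbone-like atoms (N, H, CA, HA, C, O
at realistic bond lengths but random orientations), a metal site, reference
tensors (the bundled lanthanide table, `"element"` reading), a pool of
rigid transforms with rotations uniform on SO(3) (optionally angle-capped)
and translations placing the mobile domain uniformly in an 18–35 Å shell
around the metal, and a planted ensemble with Dirichlet(2) populations.
`simulate_restraints()` generates metal-domain data from the unaveraged
tensors and mobile-domain data as the population-weighted ensemble average,
with Gaussian noise at the reference system's estimated scatter — 44 ppb
PCS / 4.6 Hz RDC in the metal domain; 9.8 ppb PCS and 1.63 / 3.42 / 2.20 /
0.78 Hz for the four RDC types in the mobile domain — or Student-t
($\nu=5$, matched variance) to probe weighting robustness. Everything is
deterministic given the seed.

What the generator does **not** emulate: real protein geometry and
dihedral correlations, steric exclusion between domains, linker
constraints, distance-dependent paramagnetic broadening (record counts do
not thin near the metal), and structural noise in the reference
coordinates. Passing tests therefore demonstrate the correctness and
calibration of the estimators under the stated noise model, not robustness
to structural-model error in real data.

Problem sizes in the test suite are chosen to exercise the full pipeline in
minutes: pools of 300–2000 transforms, 250–1300 restraints, GA populations
of 80–400 over 15–150 generations, 300–400 bootstrap resamples. The
planted-recovery check runs at pool size 2000 with a planted 4-member
ensemble: noiseless data are recovered to RMSD $<10^{-6}$ with the exact
planted members, and at experimental-scale noise the selected
$n_{\mathrm{eff}}$ stays within ±3 of the truth.

## Known limitations

* The GA provides approximate minimization; convergence is assessed across
  repeated runs, not guaranteed within one.
* RCSA support is limited to carbonyl C and amide N with a planar local
  frame; no PRE, contact shifts, or cross-correlated relaxation.
* Tensor fits are per metal; the metal position is refined against one
  metal's PCS at a time rather than jointly.
* Comparative tensor statistics depend on the component convention of the
  input table (see above); the package makes the choice explicit rather
  than guessing.
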