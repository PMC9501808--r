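# paramotion

Quantifying rigid-body interdomain motion in multidomain proteins from
paramagnetic NMR restraints.

Flexible two-domain proteins such as calmodulin in complex with a target
peptide do not adopt one interdomain arrangement but sample many. A
lanthanide ion substituted into a calcium site of one domain reports on this
motion: its anisotropic magnetic susceptibility Δχ (traceless symmetric
3×3, units 10⁻³² m³) generates pseudocontact shifts (PCS), field-induced
residual dipolar couplings (RDC) and residual chemical-shift anisotropy
(RCSA) throughout the protein. Restraints in the metal-carrying domain pin
down Δχ; restraints in the *other* domain are motional averages over the
interdomain ensemble and carry the information this package extracts.

`paramotion` implements the full analysis chain:

* **Forward model** — PCS `δ = (1/4πr³) r̂ᵀ Δχ r̂`, RDC
  `D = −(B₀²γ₁γ₂ħ / 40π²k_BTr³) n̂ᵀ Δχ n̂`, and RCSA
  `δ = Σ A_ij δ_ij` with the alignment tensor `A = B₀²Δχ/(15μ₀k_BT)`; all
  linear in the five tensor components.
* **Tensor fitting** — weighted linear least squares with iterative
  inverse-σ group weighting, effective N–H/Cα–Hα bond lengths, Q factors,
  Nelder–Mead refinement of the lanthanide position, and bootstrap
  component uncertainties.
* **Tensor statistics** — signed-ordered eigen-decomposition, normalized
  scalar products, eigenframe angles, rotational averaging, and the
  eigenvalue-regression order parameter `S = Σλ_ref λ_avg / Σλ_ref²`
  between a reference tensor and its motionally averaged counterpart.
* **Rigid-body machinery** — 4×4 homogeneous transforms (translation-
  invariant bond vectors), SVD superposition, conformer-pool prediction
  matrices, and pivot-of-rotation analysis.
* **Ensemble selection** — populations by sum-constrained non-negative
  least squares (Lawson–Hanson in C++), and a genetic algorithm whose
  fitness `f = rmsd · n^(7·n_eff/2n)` is a monotone embedding of the BIC,
  so the effective ensemble size is selected, not imposed.
* **Synthetic ground truth** — a seeded generator of pseudo-domains,
  transform pools, planted ensembles and noisy restraint sets for
  end-to-end validation.

## Worked example

```r
library(paramotion)

# bundled reference tensors (six lanthanides, CaM/Munc13-1 system)
N <- lanthanide_tensors("N")   # metal-domain fits
C <- lanthanide_tensors("C")   # effective mobile-domain fits
order_parameter(unname(N), unname(C))        # 0.165  — strong interdomain motion
normalized_scalar_product(N$Tm, N$Tb)        # -0.919 — nearly antiparallel tensors
eigenframe_angle(N$Tm, N$Tb)                 # 9.0 degrees — nearly shared eigenframe

# synthetic ground-truth scenario: 3 planted conformers in a 300-member pool
sc  <- make_scenario(n_fixed = 12, n_mobile = 12, pool_size = 300,
                     planted_size = 3, metals = c("Tb", "Tm", "Yb"), seed = 3)
sim <- simulate_restraints(sc)   # 44 ppb / 4.6 Hz metal-domain noise etc.

# fit the Tb tensor from metal-domain data
fit_tensor(sc$fixed, sc$metal_position,
           sim$fixed[sim$fixed$metal == "Tb", ], sc$conditions)
#> chi_fit: Q = 0.1188 (PCS 0.0383, RDC 0.1311)
#> chi_tensor (element convention), components [1e-32 m^3]:
#>      ax      rh      xy      xz      yz
#> 18.2290  1.2347  7.0263 12.9605 -7.6476     # truth: 17.58 2.02 6.83 12.79 -7.43

# select the ensemble from mobile-domain data
pm <- build_prediction_matrix(sc$pool, sc$tensors, sc$metal_position,
                              sc$mobile, sim$mobile, sc$conditions)
w   <- 1 / sc$noise$mobile[sim$mobile$type]
res <- evolve_ensembles(pm, sim$mobile$value, w,
                        ga_config(size = 10, generations = 120,
                                  population = 150, seed = 11))
res$best
#> ensemble: n_eff = 3 (of 8 members), rmsd = 0.9924, fitness = 1.25
#> members: 72 (0.214), 264 (0.340), 285 (0.446)
```

The fitted tensor matches the ground truth within its bootstrap
uncertainty, the dimensionless weighted RMSD of the selected ensemble is ~1
(i.e. the model fits to within the injected noise), and the genetic
algorithm recovers exactly the planted members 72/264/285 with populations
0.214/0.340/0.446 against the true 0.217/0.340/0.444 — the BIC-embedding
fitness prunes the five superfluous candidate members to zero population.

A command-line front end over the same functions ships in
`inst/cli/paramotion.R` with subcommands `simulate`, `fit-tensor`,
`predict`, `search` and `analyze`.

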