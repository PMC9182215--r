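# qssr — quantitative structure–selectivity modeling for secondary-sphere modified organocatalysts

`qssr` is an R package for asking a mechanistic question with regression:
when a proline organocatalyst is modified *in situ* by arylboronic acids
and run across several solvents, **which structural configuration of the
modifier best explains the observed stereoselectivity in each solvent?**
The candidate configurations are libraries of 3D structures — the free
boronic acid, its H-bond and π complexes with the aldehyde, and its
proline and enamine adducts — and the verdict is statistical: the
configuration whose descriptors support the most *predictive* linear model
of the selectivity wins.

It is written for catalysis and cheminformatics groups doing
descriptor-based structure–selectivity work who want the whole loop —
structure I/O, descriptor extraction, response transforms, model search,
configuration comparison — as tested, seeded, rerunnable code rather than
spreadsheets.

## The method in brief

* **Responses.** Diastereoselectivity is modeled as log₁₀(dr_anti/dr_syn);
  enantioselectivity as ΔΔG‡ = −RT ln(er_major/er_minor) in kcal/mol
  (T = 298.15 K default). Duplicate runs are averaged on the transformed
  scale.
* **Descriptors.** Sterimol L/B1/B5 (Bondi radii, B1 by support-function
  scan), distances, bond lengths, signed dihedrals, tabulated atomic
  charges and charge differences, point-charge dipole components in the
  aryl-ring frame (centroid → ipso axis; ortho/meta in-plane axis), and
  pass-through stretching frequencies.
* **Model search.** Descriptors are z-scored; every subset of up to 3
  descriptors whose pairwise |r| < 0.8 is fit by OLS and ranked by
  **leave-one-out Q² = 1 − PRESS/TSS** — the selection criterion, chosen
  over R² because it also measures predictive robustness and so suppresses
  overfit models. Q²(LOO) ≤ R² holds for every OLS fit and is enforced.
  Repeated 3-fold and 5-fold CV (500 iterations, seeded) is reported for
  top models; raw-parameter equations are recovered exactly from the
  normalized fits.
* **Comparison.** `run_campaign()` fills every (solvent, response,
  configuration) cell, ranks configurations per solvent by best Q²(LOO),
  skips flat responses with a flag (default floor sd = 0.1), and flags
  near-ties (ΔQ² < 0.05).
* **Synthetic data.** A first-class generator module produces
  equicorrelated descriptor matrices, planted sparse linear responses,
  idealized arylboronic-acid geometries, and outcome tables tiling a
  factorial design — so the entire pipeline runs and is tested without
  DFT or wet-lab input. The built-in design is 5 solvents × 15 modifiers
  × 2 replicates = 150 runs.

See `vignettes/qssr-methods.Rmd` for the full account of the model,
conventions, and numerical choices.

## Worked example

A two-solvent synthetic campaign in which acetonitrile selectivity is
generated by the π-complex library and neat-ketone selectivity by the
proline-adduct library:

```r
library(qssr)

design <- study_design(c("ACN", "neat"), sprintf("BA%02d", 1:15), replicates = 2)
labels <- configuration_labels()
mats <- list()
for (j in seq_along(labels)) {
  sp <- synth_spec(seed = 100 + j)
  m <- gen_matrix(sp, configuration = labels[j])
  rownames(m) <- design$modifiers
  mats[[labels[j]]] <- m
}
truth <- list(
  ACN  = list(configuration = "pi_complex", subset = c("x3", "x7", "x9"),
              coef = c(2, -1, 0.5), noise_sd = 0.05),
  neat = list(configuration = "proline_adduct", subset = c("x1", "x4"),
              coef = c(1.2, -0.8), noise_sd = 0.05))
outcomes <- gen_outcomes(design, truth, mats, replicate_sd = 0.02, seed = 7)

report <- run_campaign(mats, outcomes, design = design,
                       settings = campaign_settings(seed = 1))
report
#> <qssr_comparison_report> 5 libraries, 10 cells (2 skipped responses)
#>   ACN / log_dr: best = pi_complex (Q2_LOO = 0.999)
#>   neat / log_dr: best = proline_adduct (Q2_LOO = 0.998)
```

Both generating configurations are identified. The two skipped cells are
the ΔΔG‡ responses: the synthetic er columns are 50:50 in these solvents,
so enantioselectivity has no spread to model and is skipped with a flag
rather than fit. Drilling into the winning ACN model:

```r
best <- report$cells[["ACN"]][["log_dr"]][["pi_complex"]]$best
best
#> <qssr_model_fit> y ~ x3 + x7 + x9
#>   n = 15, R2 = 0.9997, Q2_LOO = 0.9995
#> (Intercept)          x3          x7          x9
#>     -0.0515      1.5985     -0.9131      0.4756
round(best$coef_raw, 4)
#> (Intercept)          x3          x7          x9
#>      0.0113      1.9826     -1.0129      0.4878
```

The search recovered the planted subset {x3, x7, x9}; the displayed
coefficients are on the normalized (z-score) scale, and the raw-parameter
equation — whose coefficients sit within noise of the planted
(2, −1, 0.5) — predicts identically. `write_report_bundle(report, dir)`
emits the JSON summary, per-cell ranked model tables (seed-stamped) and a
plain-text narrative.

Real campaigns swap the generated matrices for structure files plus
annotation tables: `read_structures()` (multi-record XYZ or SDF V2000),
`read_annotations()` (charges/frequencies CSV),
`assemble_descriptors()` with a spec list such as
`inst/extdata/descriptor_specs_free_acid.yaml`, and `read_outcomes()` for
the `solvent,modifier,replicate,yield_pct,dr_anti,dr_syn,er_major,er_minor`
table. A thin command-line wrapper over the same functions ships at
`inst/cli/qssr.R` (`descriptors` / `model` / `report` / `simulate`
subcommands driven by a YAML config).

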