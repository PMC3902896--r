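# hrebind

Thermodynamic modeling of steroid receptor–DNA binding energetics and what
they predict about transcriptional activation in cells.

Steroid receptors (GR, AR, ER, PR, MR) bind short, mostly palindromic DNA
elements — hormone response elements (HREs) — as dimers, and activate nearby
genes. A long-standing puzzle is that measured binding affinity seems to
correlate only weakly with measured transcriptional activity. `hrebind`
implements the quantitative framework that resolves this: the weak
correlation is an artifact of comparing a single-dose activity readout
against an intrinsically non-linear, sigmoidal dose–response family. When
binding is modeled thermodynamically and whole dose–response curves are fit
globally, in vitro binding energetics alone account for most
sequence-specific activation.

The package is aimed at quantitative biochemists and regulatory genomicists
who work with binding isotherms, reporter dose–response data, or
statistical-thermodynamic promoter models.

## The models

**Binding isotherms.** Fractional saturation of an HRE at free receptor
monomer concentration *x* is fit under two models (dissociation convention;
association constants are reciprocals):

- Langmuir (apparent affinity): Ȳ = x / (K_app + x)
- Dimer assembly (total affinity): Ȳ = x² / (K_tot + x²)

K_tot (units M²) is the macroscopic constant for assembling two monomers at
a palindrome; its square root is the midpoint concentration. Printed "fM²"
values mean 1e-15 M². Fits are global across replicates
(`fit_binding_model()`), with case-resampling bootstrap intervals
(`bootstrap_ci()`).

**Dose–response.** Cellular fold-activation at expression-vector dose *D*
(ng) is a rescaled binding curve with three factors shared by every HRE
(`fit_scaling_global()`):

FA(D) = e + d · Ȳ_dimer(f·D, K_tot)

where d is the amplitude, e the baseline, and f converts ng of vector to
molar receptor. Each HRE's K_tot is fixed at its measured value; only
(d, e, f) float, globally. Fitted factors predict curves for new HREs with
no refitting (`predict_new_hre()`).

**Diagnostics.** `cross_section()`, `regress()` and `perturbation_report()`
reproduce the correlation analyses: cross-sections of the dose–response
family at one dose, linear and log₁₀ regression of activity on affinity with
F-test P-values, and simulated mutagenesis/coactivator-knockdown
experiments.

**Competitive promoter occupancy.** `prob_fully_ligated()` and
`occupancy_sweep()` build the configurational partition function of a
promoter made of half-sites and palindromes, with species-specific
dimerization (k_dim), site affinities (k_half, k_pal) and nearest-neighbor
cooperativity (k_c), and compute each species' probability of fully
occupying the promoter under competition.

## Worked example

```r
library(hrebind)

tab <- hre_table()              # bundled 7-HRE reference panel
fold_range(tab$k_app)           # 62.5   -- apparent affinities span ~60-fold
fold_range(tab$k_tot)           # 697.5  -- true (total) range is ~700-fold

# the "weak correlation" and its resolution
regress(data.frame(affinity = tab$k_app, fa = tab$fold_activation), "linear")
#> Affinity-function regression [linear scale]
#>   R^2 = 0.441, P = 0.104 (F = 3.938, n = 7)
regress(data.frame(affinity = tab$k_app, fa = tab$fold_activation), "log10")
#> Affinity-function regression [log10 scale]
#>   R^2 = 0.734, P = 0.0137 (F = 13.83, n = 7)

# fit a noisy synthetic titration with both binding models
iso <- make_isotherm(0.800e-15, noise = noise_model(sd = 0.087, n_rep = 2, seed = 7))
fit_binding_model(iso, "dimer")
#> Global binding fit [dimer model]
#>   estimate: 9.681e-16 M^2 (k_tot)
#>   fit SD: 0.1067  (n = 24, converged = TRUE)
fit_binding_model(iso, "langmuir")$fit_sd   # 0.1496 -- visibly worse

# competitive occupancy: strong dimerizers win palindromes
gr <- receptor_species("GR", k_dim = 16e-9, k_half = 1e-6, k_pal = 10e-9)
prob_fully_ligated(promoter_architecture("palindrome"), list(gr), 100e-9)
#>       GR
#> 0.7904317
```

The linear fit (R² = 0.44, not significant) is what a traditional
single-dose analysis reports; the log-log fit (R² = 0.73, P = 0.01) reveals
the true affinity–function coupling. The synthetic isotherm fit shows the
dimer model describing dimer-generated data better than the Langmuir model
at realistic noise. The occupancy call says a receptor with 16 nM
dimerization and 10 nM dimer–palindrome affinity fully occupies an isolated
palindrome 79% of the time at 100 nM total receptor.

A command-line wrapper for the same stages is at
`inst/scripts/hrebind.R` (subcommands: `correlate`, `fit-isotherm`,
`fit-dose-response`, `predict`, `cross-section`, `correlate-doses`,
`perturb`, `simulate`, `occupancy`, `make-synthetic`).

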