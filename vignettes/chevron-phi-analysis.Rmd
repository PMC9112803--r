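---
title: "Three-state chevron fitting and Phi-value analysis with chevronfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-state chevron fitting and Phi-value analysis with chevronfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chevronfit)
```

## The model

Small single-domain proteins relax to equilibrium after a rapid change in
denaturant concentration with a single observed rate constant, `kobs`,
measured by stopped-flow fluorescence. For a two-state folder the logarithm
of `kobs` against urea concentration traces the classical V-shaped *chevron
plot*:

$$k_{obs} = k_f^0\,e^{-m_f [U]/RT} + k_u^0\,e^{+m_u [U]/RT}$$

where $k_f^0$ and $k_u^0$ are the folding and unfolding rate constants in
water and the kinetic m-values $m_f$, $m_u$ (kcal mol$^{-1}$ M$^{-1}$)
measure how much solvent-exposed surface is buried (or exposed) between the
ground state and the transition state.

Some domains — the C-terminal SH2 domain of the phosphatase SHP2 among them
— show a *kink* in the unfolding arm: the rate-limiting step switches from
an early transition state (TS1) to a late one (TS2) as denaturant rises,
diagnostic of an on-pathway high-energy intermediate that never accumulates.
`chevronfit` fits the corresponding three-state rate law

$$k_{obs} = \frac{k_f^0\,e^{-m_f [U]/RT} + k_u^0\,e^{+m_u [U]/RT}}
                 {1 + K_{part}\,e^{+m_{part} [U]/RT}}$$

in which $K_{part}$ is the partitioning constant between the two transition
states and $m_{part}$ its denaturant dependence. $K_{part}=0$ recovers the
two-state law exactly, so the two-state chevron is always nested inside the
three-state fit.

All free energies are in kcal mol$^{-1}$, urea in M, rates in s$^{-1}$, and
$RT = 0.5924$ kcal mol$^{-1}$ (25 °C) unless overridden.

```{r rate-law}
wt <- reference_wt_params()
wt
round(log10(three_state_rate(wt, c(0, 2, 4, 6, 8))), 3)
```

## From raw traces to chevrons

`fit_single_exponential()` extracts `kobs` from a fluorescence time course
by fitting $F(t) = F_\infty + A\,e^{-k_{obs} t}$, with the rate optimised on
a log scale so it stays positive and a small deterministic multistart ladder
guarding against bad initial guesses (offset from the last 5% of samples,
amplitude from the first sample, rate from the half-change time). Traces
whose signal change is below the noise floor raise a *no-amplitude* error
rather than returning a meaningless rate, and a fitted relaxation time
longer than half the sampled window triggers a warning. A runs test on the
residuals is reported as a lack-of-fit diagnostic but never escalates the
model: a single exponential is the model, by design. Replicate traces on an
identical time base are averaged with `average_traces()` and assembled into
a `chevron_dataset` with `build_chevron()`.

```{r traces}
tr <- simulate_trace(wt, urea = 5, direction = "unfolding",
                     n_points = 400, trace_noise_sd = 0.01, seed = 4)
fit_single_exponential(tr)
```

## Global fitting and constraint schemes

Fitting every variant's chevron independently leaves the m-values poorly
determined; sharing them across variants stabilises the problem. Fits
minimise squared residuals in $\log_{10} k_{obs}$ — the space in which the
data are displayed and in which multiplicative noise is additive —
unweighted by default (per-point sigmas can be enabled). Three constraint
schemes are offered, mirroring how such studies are analysed in practice:

* `shared_all_m` — one $m_f$, $m_u$, $m_{part}$ for all variants: the main
  scheme, assuming mutations change barrier heights, not positions.
* `free_mf_mu` — per-variant $m_f$, $m_u$ with shared $m_{part}$: relaxes
  the assumption enough to watch the transition states move.
* `free_mf` — per-variant $m_f$ only: a robustness check on TS1.

Per-variant $k_f^0$, $k_u^0$, $K_{part}$ are always free. The fully
unconstrained fit is nearly always rank-deficient and is deliberately not a
scheme; any rank deficiency encountered raises a degeneracy warning naming
the affected parameters instead of silently returning noise.

Numerically, rates and $K_{part}$ are optimised as logarithms (positivity
without constraints machinery), m-values are bounded at zero,
Levenberg–Marquardt iterations run to a relative SSR tolerance of
$10^{-10}$ with at most 5000 residual evaluations, and each fit uses one
grid-scan initialisation (limb regressions for the two-state skeleton, a
$K_{part} \times m_{part}$ grid for the partitioning term) plus randomised
restarts, deterministic given the `chevron_control()` seed. Datasets are
sorted internally by variant id so results cannot depend on input order.

## Phi-values and their categories

With a wild type and a mutant fitted, the mutational free-energy changes are

$$\Delta\Delta G_{D\text{-}TS1} = RT\ln(k_f^{wt}/k_f^{mut}), \quad
  \Delta\Delta G_{TS1\text{-}N} = RT\ln(k_u^{mut}/k_u^{wt}),$$
$$\Delta\Delta G_{TS2\text{-}N} =
  RT\ln\!\frac{(k_u/K_{part})^{mut}}{(k_u/K_{part})^{wt}}, \quad
  \Delta\Delta G_{eq} = \Delta\Delta G_{D\text{-}TS1} +
  \Delta\Delta G_{TS1\text{-}N}$$

and the Phi-values
$\Phi_{TS1} = \Delta\Delta G_{D\text{-}TS1}/\Delta\Delta G_{eq}$ and
$\Phi_{TS2} = 1 - \Delta\Delta G_{TS2\text{-}N}/\Delta\Delta G_{eq}$
measure how native-like the mutated residue's environment is in each
transition state (0 = denatured-like, 1 = native-like). Because the
normaliser is a small difference, variants with
$|\Delta\Delta G_{eq}| < 0.4$ kcal mol$^{-1}$ are excluded; the absolute
value is compared so that slightly *stabilising* substitutions are excluded
on the same footing, while strongly stabilising ones keep their (negative)
Phi-values. Categories follow the standard convention — low $[0, 0.3)$,
intermediate $[0.3, 0.7)$, high $[0.7, 1]$, non-canonical outside $[0, 1]$
— with half-open lower boundaries as the tie-break. Errors are propagated
to first order (delta method) from the fitted standard errors.

`phi_table()` produces the per-variant table; `residue_categories()` turns
it into a plot-ready per-residue file for structure colouring.

## Transition-state geometry: beta-Tanford, LFER, Hammond

The fractional position of each transition state along the
denaturant-accessible reaction coordinate is

$$\beta_{TS1} = \frac{m_f}{m_f + m_u}, \qquad
  \beta_{TS2} = 1 - \frac{m_u - m_{part}}{m_f + m_u}$$

with $m_{D\text{-}N} = m_f + m_u$ defined kinetically (the package analyses
kinetic data only, so no separate equilibrium m-value is introduced). Betas
are reported unclamped with an `out_of_range` flag: clamping would erase
precisely the trends a Hammond analysis needs.

`lfer_fit()` regresses transition-state destabilisation on
$\Delta\Delta G_{eq}$ across variants (ordinary least squares with a free
intercept); its slope, the $\alpha$ value, is a global measure of
native-likeness, and on the packaged reference table $\alpha_{TS2}$ exceeds
$\alpha_{TS1}$, the signature of a stepwise consolidating pathway.
`hammond_fit()` regresses per-variant betas (from a `free_mf_mu` fit)
against stability; a negative slope is the Hammond-consistent outcome —
reported, never enforced. `phi_vs_phi()` compares Phi-values of
structurally equivalent residues of two homologous domains given an
externally computed residue mapping (sequence alignment is out of scope),
summarising the retained pairs by mean offset, RMS deviation from the
identity line, and Pearson r.

## The synthetic-data generator

There is no public deposition of raw traces for this system, so the package
ships a generator that emulates the experimental design: chevrons on a 0–9
M urea grid in 0.25 M steps (wide enough to expose the unfolding-arm kink,
whose midpoint for the reference wild type sits near 5.4 M), multiplicative
lognormal noise on `kobs` with default sd 0.02 in $\log_{10}$ (about 5%
scatter, additive in the fitting space), and single-exponential traces of
1000 points spanning ten relaxation times. Mutants are constructed by
*inverting* the Phi formulas — `make_mutant()` chooses $k_f$, $k_u$,
$K_{part}$ so that a prescribed $(\Delta\Delta G_{eq}, \Phi_{TS1},
\Phi_{TS2})$ is recovered exactly — which gives every recovery test an
exact truth table. Ensemble defaults mirror the reference study: 29
variants with $\Delta\Delta G_{eq} \in [-1.3, 3.3]$ kcal mol$^{-1}$ and
Phi-values anywhere in $[0, 1]$.

The reference wild type is `kf0 = 300`, `ku0 = 0.06`, `Kpart = 0.017` (the
packaged table's wild-type row) with `mu = 0.52` and `mpart = 0.45` from
the published relaxed global fits and `mf = 0.81` back-derived from the
reported $\beta_{TS1} = 0.61$; the main-analysis shared m-values were never
published, so this back-derivation is the package's own choice.
`hammond_dbeta_ddG` tilts per-variant m-values linearly in stability
(holding $m_f + m_u$ and $m_{part}$ fixed) to manufacture ensembles with a
built-in Hammond effect.

What the generator does *not* emulate: instrument dead time, photobleaching
and burst phases, correlated residuals, and any real heterogeneity of
m-values beyond the linear Hammond tilt. Passing recovery tests therefore
demonstrate that the estimator is consistent and well-calibrated under the
model's own assumptions — not that those assumptions hold for any
particular instrument.

```{r ensemble}
spec <- ensemble_spec(n_variants = 6, noise_sd_log = 0.02, seed = 42)
ens <- simulate_ensemble(spec)
fit <- global_fit(ens$datasets, "shared_all_m",
                  control = chevron_control(n_starts = 2))
fit
head(phi_table(fit)[, c("variant", "ddG_eq", "phi_ts1", "phi_ts2",
                        "category_ts1", "category_ts2")])
```

## The packaged reference table

`load_table1()` returns the published per-variant parameters (wild type
plus 29 conservative-truncation variants) of the C-SH2 domain of SHP2,
transcribed verbatim with a checksum guard, and `validate_table1()`
recomputes every derived column from the printed rate constants.
Twenty-five of the 29 mutant rows reproduce within their printed
uncertainties; the remaining four (A122G, V148A, T153S, V209A) cannot be
regenerated from the printed rates because those are rounded to 1–2
significant figures while the derived columns were evidently computed from
unrounded fit parameters — for T153S, back-solving the printed
$\Delta\Delta G_{TS1\text{-}N} = -0.73$ implies an unrounded
$k_u \approx 0.0175$ s$^{-1}$ against a printed $0.01 \pm 0.01$. The
validator reports these rows as failures rather than hiding them.

```{r table1}
res <- validate_table1()
sum(res$pass)
res$variant[!res$pass]
```

## Problem sizes and limitations

The shipped tests fit ensembles of up to 30 variants on 25-point chevrons
(775 observations, 93 free parameters under `shared_all_m`), which runs in
a few seconds; the simulation studies use 20–300 replicates per property.
These sizes were chosen so that the full recovery suite exercises the same
parameter-per-observation ratio as the original study while remaining quick
to run routinely.

Known limitations: the three-state law is the steady-state partitioning
form (no explicit D–I–N eigenvalue kinetics), temperature is fixed,
denaturants other than urea are handled only in the sense that the axis is
generic, and the all-m-free global fit is intentionally unsupported. LFER
and Hammond slopes from published figures are validated qualitatively
(ordering and sign) because the exact variant subsets behind them are not
published.
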