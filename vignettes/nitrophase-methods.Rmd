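---
title: "Models and methods behind nitrophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nitrophase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrophase)
```

`nitrophase` analyses the transition of a turbidostat-grown diatom culture
from nitrogen repletion to nitrogen starvation: growth estimation from
overflow volumes, stored-energy accounting, spectrophotometric pigment
quantification, PCA-based phase segmentation of trait time courses, and an
exhaustive compound–gene slope screen over transcriptomic and metabolomic
log2 fold changes. Because the corresponding laboratory data are not
required, every stage is exercised against a synthetic experiment
generator whose design this vignette documents alongside the analysis
methods themselves.

## The turbidostat and the division-rate estimate

A turbidostat holds turbidity — and therefore cell density — constant: a
pump replaces a fraction of the culture with fresh medium whenever optical
density (measured at 735 nm, where pigments do not absorb) exceeds a
threshold. Writing $x$ for cell density, $\mu_s$ for the division rate and
$D$ for the dilution rate,

$$\frac{dx}{dt} = \mu_s x - D x,$$

and at the turbidostat set point $dx/dt = 0$, so $\mu_s = D$. The daily
dilution rate is simply the daily overflow volume divided by the culture
volume; `estimate_dilution_rate()` implements exactly that ratio and
`dilution_series()` applies it to a simulated run. No exponential fitting
of cell counts is needed — the pump does the measuring.

## The synthetic experiment generator

### Growth and nitrogen dynamics

`simulate_turbidostat()` integrates a Droop internal-quota model with an
explicit event-based control loop, using the Euler method on a 0.005-day
step:

* division: $\mu = \mu_{max}\,(1 - Q_{min}/Q)$ for internal nitrogen quota
  $Q$ (pg N/cell);
* uptake: $\rho = V_{max}\, \frac{S}{K_m + S}\,(1 - Q/Q_{max})$, i.e.
  Michaelis–Menten in external nitrate $S$ (mM), down-regulated as the
  quota fills;
* $dQ/dt = \rho - \mu Q$, $dx/dt = \mu x$, and the medium loses exactly
  the nitrogen the biomass gains (the debit is computed from the realized
  biomass increment, so the tank's nitrogen budget closes to machine
  precision between control events);
* whenever OD exceeds the threshold 0.151 the culture is instantaneously
  diluted back to the set point with feed medium, the replaced fraction is
  logged as overflow, and overflow is aggregated per calendar day because
  the division-rate estimate is a daily quantity.

The feed steps from 10 mM nitrate down to 0.15 mM at day 0 — a 67-fold
reduction in nitrogen availability. Default kinetic parameters
($\mu_{max} = 1.4\,d^{-1}$, $Q_{min} = 0.5$, $Q_{max} = 4$ pg N/cell,
$V_{max} = 7$ pg N/cell/day, $K_m = 0.6$ mM) were chosen once, by fitting
the simulated trajectory to the two landmarks the study design fixes:
external nitrate reaches its ≈0.03 mM floor at day 5 and stays low, and
the internal-quota transition (the crossing of $1.5\,Q_{min}$) falls
between sampling days 5 and 6. The replete-phase division rate implied by
these defaults is ≈1.1 d⁻¹, a realistic value for a fast-growing diatom
in continuous light-limited culture.

### Trait trajectories

The measured traits (DIC, neutral lipid, carbohydrate, soluble protein,
total pigment, internal N and C quotas, Fv/Fm, the PSII operating yield,
qP, qN, rETR) are modelled phenomenologically, not mechanistically: each
trait switches between a nitrogen-replete mean and a nitrogen-starved
mean (`trait_profiles()`), the phase means being pinned *exactly* — an
affine solve per trait makes the noiseless means over sampling days −2..4
and 7..15 equal the tabulated values.

The switch itself is a **two-stage logistic**: a first step into an
intermediate transitional state when external nitrate bottoms out, and a
second step completing the move about 2.4 days later. This was a genuine
design decision. A single symmetric logistic is steepest at its centre,
which leaves the two transition sampling days closer to the flanking
equilibria than to the midpoint; the observed time course instead passes
through a succession of transitory states across days 5–6, and the
two-stage form reproduces that geometry (the transition days sit between
the two clusters in PC space). Neutral lipid and DIC additionally keep
ramping linearly within the starved phase (lipid quotas climb from ~14
towards ~80 µg per 10⁶ cells), and qN carries a transient Gaussian
excursion around the transition — energy dissipation overshoots while the
cell re-balances.

Measurement noise is multiplicative Gaussian with CV `noise_cv` (default
0.05, a typical biochemical-assay precision), and quotas are clipped at
zero. What the generator does **not** emulate: day-to-day autocorrelated
drift, trait-specific noise levels, missing samples, or any mechanistic
coupling between traits beyond their common transition timing. Passing
tests therefore demonstrate correctness of the analysis code under the
stated two-equilibria model, not robustness to every pathology of real
assay data.

### Transcripts, metabolites, and planted ground truth

`generate_omics()` builds log2 fold-change matrices directly (the control
reference is the pre-step-down mean). Genes fall into five programs —
up-in-NS, down-in-NS, transient-transition, day-15-specific, and null —
with per-gene amplitudes; per-cell FDR values are generated consistently
with the programs (strongly shifted cells are confidently significant).
Day 15 gets its own program because late starvation diverges again at the
transcriptomic level, which is also why the five-phase averaging
convention (`NRep`, `D5`, `D6`, `NS`, `D15`) detaches it.

The metabolite matrix plants ground truth for the screen:

* **true pairs** — compounds equal to a partner gene's realized pattern
  times a slope drawn from [0.975, 1.025], plus noise. The draw sits just
  inside the screen's published [0.95, 1.05] acceptance window; slopes at
  the window edge would be lost to estimation noise at a rate unrelated
  to the property under test.
* **slope-2 decoys** — compounds tracking a gene at twice its amplitude,
  outside the window by construction.
* **uncorrelated decoys** — alternating-sign patterns, near-orthogonal to
  every monotone program.
* **weak compounds** — below the |log2FC| ≥ 2 retention threshold
  everywhere.

Partner genes receive individualized strong patterns, rejection-sampled so
that no partner is confusable with another partner, with a canonical
program, or with the alternating decoy shape inside the screen's
shared-timepoint domain (squared correlation ≤ 0.6, which keeps every
cross-pair regression p-value above 0.05 in the noiseless limit). Each
partner pattern is half program-driven and half individual, so the
differential-gene PCA keeps its low-rank phase structure while the screen
can only retain a planted compound with its own partner. The pooled
metabolomics sampling day "10/11" is represented as the single timepoint
10.5 and matched against the mean of transcript days 10 and 11; this is
configurable through the screen's `timepoint_map`.

## Stored energy

Macromolecule quotas are converted to combustion-energy equivalents:
39,500 mJ/mg for neutral lipids, 24,000 for proteins, 17,500 for
carbohydrates, i.e. 39.5/24.0/17.5 mJ per µg, with quotas expressed per
10⁶ cells:

$$E_a = 39.5\,L + 24.0\,P + 17.5\,C \quad
  [\mathrm{mJ}/10^6\,\mathrm{cells}].$$

The protein term uses the *soluble* protein quota, as measured by a
Bradford assay on the soluble fraction; the reported energy is therefore
an underestimate of total protein energy. Missing quota values propagate
as missing, never as zero.

## Pigment quantification

Chlorophyll a, chlorophyll c and total carotenoids come from trichromatic
equations on baseline-corrected absorbances (473, 630, 663 nm against the
750 nm turbidity baseline), scaled by $v/(l\,V)$ — extraction volume over
path length times sample volume. Two oddities in the published equations
are handled explicitly rather than silently:

* the chlorophyll-a equation repeats $(A_{663}-A_{750})$ in both terms,
  almost certainly a misprint for $(A_{630}-A_{750})$ in the second.
  `quantify_pigments()` always computes both readings — `"as_printed"`
  (the default) and `"corrected"` — and `variant` selects which is
  reported. Neither is asserted to be the authors' intent.
* the carotenoid equation contains a "Chl b" term although the organism
  has chlorophyll c, not b; the chlorophyll-c value is substituted there
  and the substitution is flagged in the output metadata.

Noisy baselines can produce small negative concentrations; these are
preserved raw (`*_raw` columns) and clipped to zero in the reported
quotas, with a warning. `generate_spectrum()` inverts the equations (for
either variant) so spectra with exactly known pigment content can be
synthesized; round-tripping through `quantify_pigments()` is required to
hold to 1e-9 relative error, which pins down the linear algebra in both
directions.

## Phase segmentation

Traits are z-scored (sample standard deviation, so every column has unit
variance; constant columns are dropped with a warning) and decomposed by
eigen-analysis of the correlation matrix. The correlation form is the
default because the traits span five orders of magnitude in scale; a
covariance-form PCA would be a PCA of the lipid quota. Component signs
are fixed deterministically (largest-magnitude loading positive).

Segmentation runs k-means with k = 2 on the first two component scores,
initialized at the earliest and latest timepoints — both choices remove
seed sensitivity. Clusters map to NRep/NS by mean time. A timepoint whose
distances to the two centroids differ by less than the ratio τ = 1.5 is
relabelled "transition": such points sit between the equilibria. τ is a
reproducible stand-in for what was originally a visual call; values just
above 1 flag almost nothing, large values flag everything, and 1.5 marks
points whose far-cluster distance is within half again their near-cluster
distance, which matches the intended reading of "between the groups".
Degenerate input (all timepoints identical) yields a single NRep cluster
and a warning rather than an error.

## The differential filters and the pair screen

Transcripts are retained when FDR ≤ 0.001 and |log2FC| ≥ 1 hold at the
same timepoint, at one or more timepoints; metabolites when |log2FC| ≥ 2
anywhere. The count-model differential test that would produce the FDR
values is out of scope; where only replicated abundances are available,
`stand_in_de_test()` provides a documented substitute: a pooled-variance
two-sample t-test per feature and timepoint (exact at the nominal level
under equal group variances, which replicate designs of the same assay
warrant — the Welch variant is noticeably conservative at n = 3) with
Benjamini–Hochberg adjustment across features within each timepoint.
Zero-variance degeneracies are decided exactly: equal means give p = 1,
different means p = 0.

`pair_screen()` regresses every retained compound's log2FC pattern on
every retained gene's pattern over their shared timepoints (ordinary
least squares, closed form) and retains combinations with |slope| in
[0.95, 1.05] and a two-sided slope t-test (df = n − 2) below 0.05. Three
conventions deserve note:

* the p-value tests slope ≠ 0, not slope ≠ 1 — "significant direct
  correlation" is read as "significantly non-flat and of unit slope";
* both slope signs are kept within the absolute window by default (the
  sign is recorded in the slope itself); `positive_only = TRUE` restricts
  to the strict direct-correlation reading;
* no multiple-testing correction is applied to the screen's p-values by
  default — the stringency lives in the slope window — but `adjust_p`
  turns on BH across all tested pairs.

Pairs with fewer than 3 shared timepoints or a zero-variance gene pattern
are skipped with a reason code, never silently dropped.

## Numerical choices and problem sizes

* Euler integration at 0.005 day keeps the per-step budget error far
  below the 0.1% acceptance on the closed nitrogen balance; the medium
  debit is defined from the realized biomass increment, making the
  no-dilution balance exact by construction.
* The trait-table noise is applied through one seeded generator; the
  trajectory itself is deterministic, so replicate tables reuse a single
  simulation.
* Seed-averaged checks use 20 replicate seeds; the synthetic experiment
  uses 200 genes × 11 timepoints, 100 compounds × 6 timepoints, and an
  18-day sampling grid (−2..15), sizes at which the full suite and the
  acceptance script complete in well under a minute while keeping the
  planted-pair and variance statistics stable to well inside their
  acceptance margins.
* k-means uses Lloyd iterations from fixed endpoint centers; ties cannot
  arise in practice because scores are continuous.

## Known limitations

* The Droop parameterization is phenomenological; uptake kinetics were
  calibrated to the experiment's landmarks, not measured, and the
  starved-state external-nitrate floor drifts somewhat below 0.03 mM late
  in the run rather than holding it exactly.
* Trait dynamics are pinned to two phase means; within-phase trends other
  than the lipid/DIC ramps are not modelled.
* The generator's FDR values are asserted, not derived from a count
  model; they are consistent with the planted programs by construction.
* The screen assumes patterns are comparable as log2 fold changes at the
  intersection of timepoints; no lag or nonlinearity between transcript
  and metabolite responses is considered.
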