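---
title: "Models and methods in acidstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in acidstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidstress)
```

# The problem

Octanoic acid (C8) is a representative medium-chain carboxylic acid, both a
target molecule for microbial production and a potent inhibitor of the
*E. coli* cells asked to produce it. Unlike a strong mineral acid, C8 in its
neutral protonated form partitions into the membrane, crosses it, and
deprotonates in the cytoplasm: at media pH 7.0 essentially all the bulk acid
is anionic (the pKa is 4.89), but the small protonated fraction acts as a
proton shuttle that acidifies the cell interior even when the medium is held
neutral. `acidstress` packages the quantitative machinery needed to study
this mode of toxicity: a chemiosmotic model of the proton motive force under
acid challenge, reporter-based intracellular pH inference, differential
expression and transcription-factor-activity analysis for the
transcriptomic response, and membrane/growth physiology metrics — together
with seeded generators that produce every input the pipeline consumes, so
all of it runs and is tested without external data.

# The proton motive force model

## State variables and conventions

The proton motive force (PMF, `Δp`, mV) combines the membrane potential and
the transmembrane pH gradient in the standard Mitchell form

$$\Delta p = \Delta\psi - Z\,\Delta\mathrm{pH}, \qquad
  Z = \frac{\ln 10 \cdot R T}{F},$$

with `Δψ = ψ_in − ψ_out` (mV), `ΔpH = pH_i − pH_e`, and `Z ≈ 61.5` mV per pH
unit at 310.15 K. Negative PMF drives protons inward. Ion gradients are
converted to potentials with the Nernst equation
`(RT/zF)·ln(ions_e/ions_i)`. Temperature defaults to 37 °C growth
conditions; a `thermo_context(303.15)` represents 30 °C plate-reader
measurements. Constants are `R = 8.314` J mol⁻¹ K⁻¹ and `F = 96485` C mol⁻¹.

The *normal* reference state is closed over the physiological anchor rather
than over-specified: given `pH_i = 7.6`, `pH_e = 7.0` and a target PMF of
−160 mV (the middle of the −140 to −180 mV physiological range), the
membrane potential is solved as `Δψ = target − ph_force ≈ −123.1` mV.

## Shock

An acid shock is the instantaneous state after an extreme environmental
change, before any cellular response:

* **Inorganic acids** (HCl): rapid addition delivers equal amounts of
  protons and anions, so `Δψ` is unchanged; only `pH_i` (measured, e.g. by
  the reporter) and — if the medium is not re-adjusted — `pH_e` move. The
  post-shock `pH_e` of unadjusted media is a required input, never guessed.
* **Carboxylic acids** (C8): the protonated acid loads the cytoplasm with
  protons irreversibly. We treat that proton load as uncompensated positive
  charge, shifting the membrane potential by
  `+Z·(pH_i,normal − pH_i,shock)` — the Nernst equivalent of the
  H⁺-pool fold increase. This is the minimal charge-balance rule consistent
  with an irreversible intracellular proton release, and with a collapsed
  pH gradient it produces the characteristic *inversion* of the PMF to
  positive values (protons driven outward). A multi-ion Goldman treatment
  is deliberately out of scope.

## Adaptation

The adapted state restores the PMF to the target mean by net ion transport:
cation accumulation (or anion release) under inorganic challenge, anion
accumulation under carboxylic challenge, whose inverted `ΔpH` demands a
strongly negative `Δψ` (≈ −252 mV for `pH_i` at the 5.5 reporter floor).
The required potential has the closed form `Δψ = target − ph_force`; a
bisection solver (tolerance 0.1 mV, 200-iteration cap) over the same PMF
function is kept as an independent numerical path and cross-checked in the
tests to ≤ 1e−6 mV.

The transport cost is summarised as
`ion_fold_change = exp(|ΔΔψ|·F/RT)` for a single monovalent carrier ion,
with `ΔΔψ` taken between the adapted and pre-adaptation (shock) states.
For inorganic shocks `Δψ` does not move during the shock itself, so this
equals the fold change relative to the normal state; for carboxylic shocks
the shock-phase `Δψ` shift is carried by the proton load, not by the
carrier ion, so the same convention applies. Note this single-carrier
Nernst conversion is an idealisation: it reports what a lone monovalent
ion pool would have to do, and for the C8 scenario the number is very
large (≈ 1.6 × 10⁴). Measured anion accumulation in organic-acid-challenged
cells is far smaller (literature values are on the order of a few fold),
because real adaptation distributes the burden over many ion species and
co-regulated transport. The model therefore reports the fold change
without asserting it as a prediction of any single measured pool.

# Intracellular pH from reporter fluorescence

Calibration standards are cells whose interior has been equilibrated to the
buffer pH (benzoate collapse), so buffer pH equals intracellular pH. The
calibration model is linear in pH — the reporter's response is smooth and
monotone over the useful range, and with 6–7 calibration levels a linear
fit is the most parsimonious monotone choice; the fitted span is taken
from the standards themselves. Estimation inverts the fitted line at the
mean of the replicate readings; with ≥ 3 replicates a t-based 95% interval
from the per-replicate inversions is attached.

Censoring follows the reporter's physics: fluorescence stops resolving pH
below the lowest calibrated level, so readings mapping below the span's
lower edge are reported *at* that floor with `censored = TRUE` — the value
is an upper bound. The default synthetic standards span 5.5–8.0, making
5.5 the floor, which is the reporter's stated detection limit. The
`hcl_20mM_unadjusted` preset instead emits standards down to pH 5.0:
severe HCl shock drives the interior to pH ≈ 5.3, and resolving it
requires calibrating below it (the benzoate-collapse protocol works at any
buffer pH). No upper censoring is applied — only a lower detection limit
exists. A monotone-spline calibration was considered and omitted: on
6–7 standard levels it cannot be distinguished from the linear fit it
would replace.

# Differential expression

Testing uses gene-wise equal-variance two-sample t statistics with a
permutation null built by relabelling samples — the permutation supplies
the null distribution, so no Gaussian assumption is needed and the
classical statistic suffices (a Welch variant adds nothing under
permutation and is omitted). When `choose(n, n_treated)` label assignments
fit within `n_perm` (default 10 000) the null is enumerated exhaustively;
otherwise random relabellings are drawn. Exhaustive p-values are `b/B`
with the identity assignment included; sampled p-values use the add-one
estimator `(b+1)/(B+1)`.

**Why the null is pooled across genes by default.** With `n` replicates per
condition there are only `choose(2n, n)` distinct relabellings — 20 at
n = 3, 70 at n = 4. A per-gene null therefore cannot produce p below
2/B, and after Benjamini–Hochberg adjustment the attainable q-value floor
is `2/B` even when the truly changed genes occupy the top ranks: at
n = 3 + 3 no gene can ever reach q < 0.05. Pooling the permuted |t|
values of all genes into one null reference (the classical SAM-style
device for small-replicate arrays) breaks the per-gene discreteness; at
n = 4 + 4 the pooled q-floor is 2/70 ≈ 0.029 and a 4-fold change with
σ = 0.25 log2 noise is comfortably detectable. The per-gene null remains
available (`null = "per_gene"`) and is the one used for the type-I
calibration checks, where its exact discreteness is the point.

q-values are Benjamini–Hochberg (`stats::p.adjust`); a Storey-type
estimator would differ mainly through its π₀ estimate and is not needed at
these scales. Significance requires `q < 0.05` (strict, matching the
stated criterion) and `|log2 FC| ≥ 1` (inclusive, so an exactly 2-fold
gene is kept). Signed linear ratios are reported as `+2^FC` / `−2^|FC|`.
Preprocessing for synthetic or pre-summarised inputs is per-sample median
centring in log2 space; probe-level microarray processing (background
correction, summarisation) is out of scope, and the packaged table of
C8-responsive genes ships as a plain-text fixture with its printed values
unmodified.

# Network component analysis

Transcription-factor activities are estimated from the constrained
factorisation `E ≈ A P`: `E` is the genes × conditions log-ratio matrix,
`A` a connectivity matrix whose sparsity pattern is fixed by a curated
regulatory network (RegulonDB-style TF→gene edge list), and `P` the TF ×
condition activity matrix. Identifiability requires (i) generic full
column rank of `A`'s support, (ii) full rank of every sub-pattern obtained
by deleting one TF and all its targets, and (iii) at least as many
conditions as TFs; `check_identifiability()` reports failures with the
offending TFs (zero-target TFs, duplicated regulons) named.

Estimation is alternating least squares: `P` is initialised from seeded
standard-normal draws, then each gene's row of `A` is solved restricted to
its permitted TFs, then `P` given `A`, repeating until the relative
Frobenius residual decreases by less than 1e−8 (or falls below 1e−12),
capped at 500 sweeps. Each step solves its subproblem exactly, so the
residual trace is non-increasing — asserted per sweep in the tests.
Singular subproblems fall back to a ridge-regularised solve with a
warning.

The factorisation has a diagonal gauge freedom (`A D`, `D⁻¹ P`). The
canonical gauge scales each TF column of `A` so its largest-magnitude
entry is +1; when the topology annotates edge signs, the column sign is
instead anchored to majority agreement with those signs. Under this gauge
the noiseless identifiable solution is unique: five different random
initialisations agree to ≤ 1e−6 in the tests. No printed activity
magnitudes exist to compare against, so parameter recovery on synthetic
identifiable systems — exact at zero noise, correlation ≥ 0.95 per TF at
σ = 0.05 — is the primary acceptance surface for this module.

Activity changes `ΔTFA = mean(treated) − mean(control)` are tested with a
null-centred bootstrap over replicate columns (default 1000 resamples,
seeded, add-one p), since the number of replicate conditions is far too
small for asymptotics; with fewer than two replicates per group only the
magnitude is reported.

# Physiology metrics

* **Specific growth rate** μ (h⁻¹) is the least-squares slope of ln(OD₅₅₀)
  versus time over the exponential window (user-specified bounds, ≥ 3
  points; automatic window selection was left out as the synthetic series
  are exponential end-to-end). Percent inhibition is
  `100·(1 − μ_treated/μ_control)`.
* **Membrane metrics** from mol% lipid profiles over {C12:0, C14:0, C16:0,
  C16:1, C17cyc, C18:0, C18:1, C19cyc}: the S:U ratio counts cyclopropane
  species in the unsaturated pool they derive from; the average lipid
  length defaults to actual carbon counts (C17cyc = 17, C19cyc = 19) with
  a selectable "precursor" convention (16, 18) because compositional
  groupings by carbon family are also common and the two conventions shift
  the average by up to ~0.1 carbons; total cyclopropane content is
  C17cyc + C19cyc.
* **GABA accounting**: glutamate decarboxylation consumes one proton per
  GABA, so total GABA (in + out) is a lower bound on protons sunk by the
  glutamate-dependent acid resistance system — a lower bound because the
  succinate shunt consumes GABA downstream.
* **Bonferroni threshold** `alpha/m`, e.g. 0.05 over a 20-amino-acid
  survey → 0.0025.

# Synthetic data: what it emulates, and what it does not

Every generator is seeded, returns its ground truth, and emits data that
passes the consuming module's validation. Noise models: Gaussian in log2
space for expression, multiplicative lognormal (2% CV) for OD and
fluorescence, Dirichlet perturbation (concentration 100 per mol%) for
lipid compositions, 5% lognormal for GABA pools. These values keep the
recovery tests meaningful but non-trivial — e.g. the growth-rate
round-trip recovers the embedded 23% inhibition with a standard error of
about 0.8 percentage points.

Preset constants live in one annotated registry (`preset_registry()`):
growth (μ = 0.60 h⁻¹ control, 23% inhibition at 10 mM C8), fluorescence
(true pH 5.32 for unadjusted HCl shock, below-floor 5.2 for long-term C8,
6.8 for the production strain, 7.6 resting), lipid base compositions
(wildtype ~9 mol% cyclopropanes, overexpression ~36 mol%, deletion 0) with
a deterministic dose response (wildtype S:U falls and average length rises
with C8 dose; the overexpression strain shifts oppositely), and
order-constrained GABA pools (balanced control, glutamate shifting GABA
outward at constant total, C8 depressing every pool). Where only an
inequality or ordering is reported for the modelled conditions, generator
means are placed with enough margin that the noise model cannot cross the
bound (> 4 sd).

What the generators do *not* emulate: probe-level microarray noise and
batch effects, plate-position and optical artefacts in fluorescence,
growth-phase dependence of lipid composition, correlated gene-gene noise,
and absolute GABA concentrations (figure-only in the source material;
only orderings are encoded). Passing tests on this synthetic data
therefore demonstrate correctness of the estimators under the assumed
statistical structure, not robustness to every artefact of real
measurements.

# Problem sizes and numerical choices

The test suite and acceptance script run at deliberately desk-scale sizes:
DE on 500–510 genes with 4 + 4 replicates (exhaustive 70-split null), NCA
on 5–30 genes and 2–5 TFs, growth series of 11 points, 6–7 calibration
levels × 3 replicates. These sizes are chosen so every stochastic recovery
statement is testable in seconds while remaining statistically honest
(discreteness floors, bootstrap resolution and Dirichlet noise are all at
realistic relative magnitudes). Key tolerances: 0.1 mV on the adaptation
solver, 1e−8 relative residual decrease for ALS, 1e−9 on analytic
round-trips (speciation inversion, calibration inversion on noiseless
data), add-one estimators wherever a sampled null could produce p = 0.

# Known limitations

* The carboxylic shock rule is a minimal charge-balance closure; it is not
  a kinetic model of proton flux and does not resolve the time course of
  the shock.
* Single-carrier ion accounting (see above) overstates the burden on any
  one real ion pool.
* The linear calibration is only as good as its standards; strongly
  nonlinear reporters would need the spline alternative this package does
  not implement.
* Pooled permutation nulls assume roughly exchangeable gene-wise noise
  scales after median centring; heavy per-gene variance heterogeneity
  would argue for the per-gene null despite its discreteness.
* NCA results are conditional on the curated topology: missing or spurious
  edges bias `A` and `P` in ways no identifiability check can detect.
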