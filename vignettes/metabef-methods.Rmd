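---
title: "Methods: biodiversity-ecosystem function analysis in algal metacommunities"
author: "metabef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biodiversity-ecosystem function analysis in algal metacommunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabef)
```

# The experimental system

`metabef` analyses a classic microcosm design for studying how species
richness, total resource supply and resource stoichiometry jointly shape
producer biomass, evenness and resource use efficiency (RUE) at two
spatial scales. The unit of replication is a *metacommunity* of three
50 mL flasks ("patches") that share the same total phosphorus supply
(P~sup~) but differ in their molar N:P supply ratio (2, 16 or 128; 16
approximates the Redfield ratio). Patches are linked by scheduled
dispersal: 2.5 mL (5% of patch volume) is removed from each patch,
pooled, mixed and redistributed, on days 13, 20 and 27 of a 31-day run.
Medium is partially exchanged on days 3 and 6 (5 mL) and days 10 and 17
(10 mL).

Species composition has six levels — five freshwater algal monocultures
(a needle-like chlorophyte `AN`, a flagellated chlorophyte `CL`, an
N-fixing cyanobacterium `CY`, a diatom `FR`, a dinoflagellate `GY`) and
the full five-species mixture `MIX` — in a substitutive design: every
flask is inoculated at 231,000 µm³ mL⁻¹ total biovolume, divided evenly
among species in the mixture. Three main P~sup~ levels (0.13, 0.81,
5.02 µmol L⁻¹, labelled I, III, V) are fully crossed with composition,
N:P and three replicates; two extra levels (0.32, 2.02; II, IV) are run
with the mixture only. `enumerate_design()` expands this to the 180
flasks in 60 metacommunities. Nitrogen is never an independent factor:
each patch starts at `p_sup * np_ratio` µmol N L⁻¹, and fresh exchange
medium carries the same stoichiometry.

# Response variables

Biovolume is measured by inverted-microscope counting: cells seen in an
effective examined volume times the species' mean cell volume
(`counts_to_biovolume()`). Mean cell volumes come from geometric solids
fitted to each taxon (`cell_biovolume()`), averaged over repeated
single-cell measurements; we average the per-cell *volumes*, not the
dimensions, because the mean volume is the unbiased scale factor for the
summed count. Chamber geometry, grids and magnification are abstracted
into the single effective `volume_examined_ml` per record.

From per-species biovolumes the package derives, at the local (flask)
scale: total biovolume, Pielou evenness \(J' = H'/\ln S\) (with \(S\)
the species *present*; monocultures have no defined evenness and carry
`NA`, which propagates by exclusion), and RUE = biovolume / P~sup~. At
the metacommunity scale, per-species biovolumes are summed across the
three patches for evenness, and RUE is the *mean* patch biovolume over
P~sup~ (the sum would differ only by the constant factor 3 and changes
no test statistic). Biovolume, resource and RUE responses are
ln-transformed before ANOVA; `ln_transform()` treats non-positive values
as an error rather than imputing an offset — the simulator's inocula
guarantee positivity, and real tables with zeros should be inspected,
not silently shifted.

# Diversity effects

Mixture performance is compared with the null expectation built from the
component monocultures. For yields the package uses the additive
partition of the net diversity effect: with monoculture yields \(M_i\),
observed mixture yields \(Y_{O,i}\) and initial shares
\(RY_{E,i} = 1/5\),

\[
\Delta Y \;=\; Y_O - Y_E \;=\;
N\,\overline{\Delta RY}\,\overline{M}
\;+\; N\,\mathrm{cov}(\Delta RY, M),
\]

the first term measuring complementarity (niche partitioning,
facilitation) and the second selection (dominance by species with high
monoculture yield). The covariance divides by \(N\) (population form) so
the identity is exact to machine precision — this is asserted on random
communities against the brute-force sum \(\sum_i \Delta RY_i M_i\).

RUE and evenness get observed-minus-expected deltas:
\(\Delta_{RUE}\) is observed mixture RUE minus the share-weighted mean
monoculture RUE (algebraically \(\Delta Y / P_{sup}\) at matching
scale — asserted numerically), and \(\Delta_{Even}\) compares observed
mixture evenness with the evenness of the proportions each species would
hold if it grew as in monoculture (\(p_{E,i} = M_i / \sum_j M_j\)).
\(\Delta_{RUE}\) is deliberately *not* partitioned further:
species-specific contributions to mixture RUE cannot be separated
without per-species nutrient uptake data.

Replicate pairing: mixture replicate *r* is always compared against
monoculture replicates *r* of the same treatment cell, giving three
replicate deltas per cell and one-sample t tests on df = 2. At the
metacommunity scale the cell is P~sup~ (per-species biovolumes first
averaged over the three patches, mirroring the RUE definition); at the
local scale it is P~sup~ × N:P. This df = 2 structure is exactly what
the t→p pairs of such three-replicate designs imply (e.g. t = −8.0 gives
p = 0.015, t = 19.8 gives p = 0.0025, two-sided).

# Inference

`balanced_anova()` fits fully crossed balanced factorial ANOVAs (1–3
factors, all interactions). Unbalanced input is rejected rather than
reweighted, which keeps the sum-of-squares decomposition unique and
exhaustive. Because the three patches of a metacommunity exchange volume
weekly they are not independent observations; local-scale tests are
therefore made conservative by evaluating the observed F against the
critical F whose *error* degrees of freedom are divided by 3 — one
independent unit per three dependent patches. The division is kept
continuous (F quantiles accept non-integer df); rounding down would add
unstated conservatism. The adjustment is strictly conservative:
significance under df/3 implies significance under the full df, by
monotonicity of F quantiles, and the suite checks this on every fitted
local table. Metacommunity-scale ANOVAs use the actual error df, since
metacommunities are independent (15 mixture metacommunities give error
df 10 for the five-level P~sup~ test; the 3 × 6 composition design gives
interaction df 10 and error df 36).

Correlations between evenness and ln RUE are computed twice: on the raw
observations and on *treatment residuals*, each observation minus its
full factorial cell mean (the residuals of the saturated model; the
method names no specific model, and cell-mean removal is the least
committal choice). If the raw correlation vanishes on residuals it
cannot be distinguished from a joint response to the treatments.

# The simulator

No raw data are deposited for this design, so the package ships a
mechanistic generator whose output has the statistical structure the
analysis assumes. Growth is discrete daily Monod kinetics under Liebig's
minimum: species *i* grows at
\(\mu_i = \mu_{max,i}\,b_i\,\min(f_N, f_P)\) with
\(f_R = R/(k_R + R)\), \(f_N \equiv 1\) for the N-fixer, and
\(b_i\) the `interaction_bonus` (active only in mixtures, default 1).
Biovolume multiplies by \(e^{\mu_i \Delta t}\) and draws down dissolved
N and P with fixed quotas; if a day's demand would overdraw a pool, all
growth increments are scaled by the common factor that exactly exhausts
it. One deliberate nuance: the N-shortage factor is applied to
*non-fixers only* — scaling the fixer by an N bottleneck would
contradict fixation — so when both pools bind, the scarcer one is
exhausted exactly and the other merely not overdrawn. Mass balance
(consumed + remaining = supplied) is asserted to 1e-9 relative
tolerance. The time step is 1 day with exponential within-step growth:
the horizon is 31 days and all event days are integers, so finer steps
would change nothing structurally. Exchange and dispersal are exact
volume-weighted mixtures; dispersal conserves per-species and nutrient
totals to machine precision and is a fixed point on equal patches.
Sampling happens at the end of day 31, after all events.

Counting noise emulates the enumeration protocol: an effective examined
volume is chosen so the expected total count equals the target (400
cells for monocultures, 1000 for mixtures), and per-species counts are
independent Poisson draws — unbiased for biovolume, with realistic
relative error for rare species. Noise-free mode returns exact
concentrations.

## Trait defaults and calibration

The default trait table encodes the qualitative trade-offs of the
species pool: the diatom is a slow-growing, high-affinity,
phosphorus-efficient competitor (lowest \(k_P\) and \(q_P\); its
silicate demand is folded into a low \(\mu_{max}\)); the N-fixing
cyanobacterium is a fast velocity specialist that needs plentiful P
(highest \(\mu_{max}\), high \(k_P\)); the chlorophytes are
N-demanding (high \(q_N\), \(k_N\)); the dinoflagellate is slow
throughout (carbon demand folded into \(\mu_{max}\)). Quotas are of
realistic magnitude for severely P-starved algae (around 1e-5 µmol P per
10⁶ µm³, a few-fold below Redfield-based biomass composition). Silicate
and carbon never appear as state variables — the analysis is
two-resource, and adding axes would change the analysis surface, not
improve it.

These defaults were calibrated once, against the coarse targets the
design itself fixes, and then frozen: the mixture's biovolume
fold-increase over the inoculum is ≈43 at P~sup~ I and ≈1730 at P~sup~ V
(targets ≈56 and ≈1500, both within the ±30% band the "around" wording
warrants); the diatom has the highest monoculture yield at the lowest
P~sup~, the N-fixer at the higher levels; the N-demanding chlorophyte
catches up with the fixer only at N:P = 128; and mixture evenness
declines with P~sup~. A consequence of this parameterisation worth
knowing: at low P the system is still rate-limited at day 31 (biomass is
approaching, not at, its P-determined ceiling), while at high P the
ceiling binds — which is precisely why a growth-rate
`interaction_bonus` measurably raises mixture yield at low and
intermediate P and why RUE declines with P~sup~.

## What the simulator does and does not emulate

Simulated tables reproduce the design structure, the event schedule, the
dominance and efficiency gradients, and enumeration noise. They do not
attempt light or temperature dynamics, allelopathy, luxury uptake,
size-distribution changes, or any fit to the original study's real
measurements beyond the calibration targets above. Passing tests
therefore demonstrate that the *analysis machinery* is correct and that
the pipeline recovers known effects injected into data with this
structure — not that the simulator's biology reproduces every published
statistic, most of which depend on unavailable raw data.

Two recovery properties are built into the acceptance suite under the
study's own conditions (n = 3 metacommunities, 200 simulated
experiments): with all five species made exchangeable (identical growth
parameters) and no interaction bonus, the mean net diversity effect is
centred on zero within 2 SE; with `interaction_bonus = 1.2` for all
species, the estimated complementarity effect is positive in at least
80% of experiments. Problem sizes throughout the suite (a full 180-flask
experiment per replicate, 200 replicates per recovery property, 1000
random communities for the partition identity) were chosen as the
smallest sizes at which the asserted properties are statistically sharp.

# Numerical and design choices

* **Identifiers** are deterministic (`P{level}-NP{ratio}-{comp}-r{rep}`)
  so outputs diff cleanly; the original design assigns none.
* **Evenness of one species** is `NA`, never 0; downstream means exclude
  missing values, and monocultures simply carry no evenness.
* **Monoculture yields of zero** make relative yields undefined; the
  partition refuses them rather than returning infinities. Simulated
  inocula keep all monoculture yields positive.
* **Validation never throws**: `validate_table()` returns a findings
  report (negative values, duplicated records, incomplete
  metacommunities, unknown species); the analysis entry point aborts
  only on error-severity findings.
* **Under-count flasks** (fewer cells than the counting target) are a
  quality flag in the real protocol; the simulator's targets are
  expectations, so individual draws below target are normal and not
  excluded.
* **Extra P levels** (II, IV) are assumed to form ordinary
  three-patch metacommunities with the same dispersal scheme — they
  carry all three N:P patches, which makes this the only structurally
  consistent reading.
* **RNG**: a single seed drives design-order simulation and observation;
  the seed is recorded in the run manifest, and identical seeds produce
  byte-identical output CSVs.

# Limitations

The conservative df/3 criterion is an ad hoc correction, not a mixed
model; it controls size at the cost of power and is applied only where
patches are the unit. The partition is the two-term version; tripartite
(dominance/trait-dependent) extensions are out of scope. The simulator's
interaction bonus is a single multiplicative knob — adequate for power
and recovery studies, not a mechanistic model of facilitation. And
because evenness is computed on realized (observed) communities,
heavy counting noise at very uneven communities biases evenness slightly
upward; at the default counting targets this bias is negligible relative
to replicate variance.
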