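---
title: "Resolving co-occurring C4BP assemblies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving co-occurring C4BP assemblies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4bpquant)
```

## The biological problem

Human C4b-binding protein (C4BP) is a ~600 kDa oligomeric complement
inhibitor assembled from 6-7 alpha chains and usually one beta chain,
which in turn binds vitamin K-dependent protein S (ProS)
non-covalently. Serum therefore carries an ensemble of co-occurring
higher-order species — alpha7 beta1 + ProS, alpha6 beta1 + ProS,
alpha7 beta1, alpha6 beta1, and (under acute-phase conditions) a
beta-free 7-alpha variant. Because one glycosylated alpha chain
(~73 kDa) and ProS (~80 kDa) weigh almost the same, single-particle
mass histograms cannot directly distinguish alpha7 beta1 from
alpha6 beta1 + ProS: both sit near 553 kDa. This package implements
the computational chain that resolves that ambiguity and quantifies
the ensemble, from raw single-ion observations through plasma-level
stoichiometry monitoring.

## Single-particle mass calibration

Charge detection mass spectrometry (CDMS) records, per ion, an m/z
value and a normalized single-ion intensity proportional to charge.
The conversion `charge = 14.713 * intensity` uses the calibration
factor determined on protein standards; mass follows as
`z * (m/z - m_proton)`. Charges are rounded half-up to integers by
default (physical charges are integral, and rounding sharpens the mass
histogram); rounding is configurable off because the original
processing does not document it.

Mass photometry (MP) contrast is linear in mass. `fit_mp_calibration()`
fits `contrast = slope * mass + intercept` to the *per-calibrant median*
contrast of a standard mixture (73, 149, 483, 800 kDa; a second common
instrument set, 335/670/1340 kDa, is equally accepted). Medians are
taken before the regression to resist outlier landing events.

## Gaussian-mixture deconvolution

`fit_mixture()` implements 1-D Gaussian-mixture
expectation-maximization with quantile-spaced initial means, equal
initial weights, convergence at a log-likelihood change below 1e-8 (or
500 iterations), and a variance floor to avoid collapse onto single
points. The fit is deterministic given the data. In auto mode the
component count is chosen by minimum BIC over k = 1..6; the source
analyses fixed component counts by visual inspection, and BIC
reproduces those choices on the simulated data (k = 3 native, k = 2
acidified complexes). The EM trace is stored so that the monotone
log-likelihood property can be asserted in tests.

Component weights can be quantified two ways, and both are reported:
raw EM mixing weights, and event counting — each event assigned to its
nearest component mean and counted if within 2 SD — which mirrors
quantification by single-ion events belonging to the respective
populations. The counting variant is the default for occupancy
inference.

## Stoichiometry assignment

`assign_stoichiometry()` enumerates the bounded copy-number lattice
(defaults: up to 8 alpha to keep the historical 8-arm hypothesis
testable, up to 1 beta, up to 1 ProS) and returns every species whose
theoretical mass is within `k_sigma * sd` (default 2 SD) of the
observed mass, ranked by absolute error with deterministic tie-breaks
(fewer subunits, then label). ProS without a beta chain is excluded by
default — ProS binds via the beta chain — except as the free monomer.
An assignment is ambiguous when two or more candidates survive; at
553 ± 20 kDa the window contains alpha7 beta1 (error 2.0 kDa),
alpha6 beta1 + ProS (4.9 kDa) and also the bare 8-alpha ring
(30.2 kDa), so the ambiguity at the heart of the analysis is
reproduced rather than hard-coded away. The default chain masses
(alpha 72.9, beta 40.7, ProS 79.8 kDa) are the least-squares-consistent
values for the four resolved peak masses (633, 551, 481/478 kDa plus
the ~80 kDa spacing).

## Occupancy inference from paired native/acidified data

Acidification dissociates ProS while preserving the disulfide-linked
alpha/beta core, collapsing the composition to alpha7 beta1 and
alpha6 beta1 plus free ProS. Writing the native complex-population
weights (heaviest to lightest) as a1, a2, a3 and the acid-dissociated
alpha7 beta1 fraction as f7, the unbound-alpha7 beta1 share of the
overlapping middle peak is `x = f7 - a1` and the ProS-bound fraction is
`2*a1 + a2 - f7`. `resolve_overlap()` implements this closed form (and
is tested against a grid-search oracle); `estimate_occupancy()` supplies
the weights by fitting the two event sets above a configurable 200 kDa
complex floor (low-mass quantification is more ambiguous on instruments
optimized for the 400-800 kDa assembly, so the monomer region is kept
out of the algebra).

Two design points deserve note. First, the component count for each fit
is selected by BIC (native k in 1..3, acidified k in 1..2) rather than
fixed: at occupancy extremes (q near 0 or 1) one of the native
populations is genuinely absent, and a forced three-component fit would
manufacture a spurious component. Second, fitted components are mapped
to theoretical mass bins computed from the chain masses (478 / ~554 /
631 kDa native; 478 / 551 acidified) by nearest mean, so weights land
in the right slot of the algebra regardless of how many components the
data support.

## Glycoproteoform profiling

Glycopeptide PSMs are filtered with strict inequalities, score > 150
and |log prob| > 1.5, as printed in the originating search protocol;
both thresholds are configurable. Sites are then profiled by PSM
counting: proportions per composition (unoccupied included), a dominant
occupied composition with ties broken toward higher sialylation, and a
flag for sites with more than 20% (strict) unoccupied PSMs. Composition
strings are accepted both in long form (`HexNAc4Hex5NeuAc2`, `Neu5Ac`
alias tolerated) and in the N/H/F/S shorthand. Site numbering is taken
verbatim from the input (precursor numbering); no renumbering is
attempted. `export_glycoforms()` feeds the dominant compositions into
the chain-mass arithmetic, where glycan masses use dehydrated residue
masses (glycosidic-bond convention, average or monoisotopic tables).

## Cross-link validation

`filter_links()` deduplicates by unordered endpoints and linker, then
applies the confidence rule: best score strictly above 40 and
identification in at least two of three replicates. `validate_links()`
enumerates all chain-copy pairings per link (for self-links the two
ends must sit on different physical copies; with a single copy the link
is unmappable, never distance 0), records the minimum CA-CA distance
and all alternate pairings within 2 Å of it, and flags links whose
minimum exceeds the linker cap. The caps — DSS 30 Å, DMTMM 25 Å
CA-CA — are community conventions, configurable and always reported
with the output, since the source analysis reports "overlength" links
without printing its threshold. `disulfide_check()` tests SG-SG
distances against a 2.05 Å plausibility threshold. Coordinates are read
from PDB or mmCIF via bio3d.

## Plasma stoichiometry monitoring

Per sample, `fit_concentration_regression()` regresses log10(MaxLFQ) on
log10(known concentration) over a 22-protein reference panel (log base
10 throughout; at least 3 quantified panel proteins required, missing
ones excluded and reported). Inverting the fit converts any protein's
LFQ to g/L, and chain molecular weights convert to molar units. The
C4BP alpha/beta ratio is computed on molar concentrations — mass-based
ratios would sit near 12-13 and be inconsistent with the expected 6-7
band for pure beta-containing ensembles — with `in_expected_range`
(6-7, inclusive) and `variation_flag` (ratio > 7) annotations. CRP is
carried alongside as the acute-phase correlate but is not used as a
gate. Unbound ProS is `max(0, [ProS] - [C4BPbeta])`, assuming
saturating high-affinity binding; negative intermediates are clamped
with a warning. `purity_profile()` normalizes non-contaminant iBAQ to
100%, merges the C4A/C4B isotypes into one C4b group, and shows groups
strictly above 1%. SEC profiles are summed over triplicates and
smoothed with a centered window-3 rolling mean whose edge windows
shrink to the available fractions; co-elution is the Pearson
correlation of smoothed profiles.

## The synthetic-data module

All generators are bit-reproducible given (parameters, seed) and
emulate the statistical structure the pipeline assumes:

* **CDMS events**: particles drawn from a preset population; mean
  charge follows a Rayleigh-limit-like `0.1 * sqrt(mass in Da)` with
  SD 2 charges (any positive mass-monotone charge model suffices — the
  published processing does not describe its ion population); intensity
  is `z / 14.713` plus Gaussian noise (SD 0.05). Noise-free settings
  make generation followed by mass inversion an exact round trip.
* **Presets**: `SERUM-CDMS-NATIVE` carries the published native peak
  parameters 633/553/481 kDa (SD 22/20/20) with weights
  0.374/0.482/0.144 — the weights implied by f7 = 0.55 and q = 0.68
  under the occupancy algebra. q = 0.68 reproduces the published 68%
  CDMS ProS-bound figure; f7 itself is not printed anywhere, so 0.55
  was chosen once as the value consistent with the roughly equal
  abundance of the two major native populations. `SERUM-CDMS-ACID`
  places complexes at 551/478 kDa (55:45 among complexes) and free
  ProS at 80 kDa (SD 6); event-level weights follow from every bound
  particle splitting into one complex and one ProS event, giving a
  ProS event fraction q/(1+q) = 0.405. `SERUM-MP-NATIVE` uses the MP
  masses 630/553/487/68 kDa; the free-ProS event weight (5%) is a
  package choice representing the "small portion" of dissociated ProS
  visible in native MP. The `MECHANISTIC` preset draws the four latent
  species from chain masses with per-species SD 20 kDa, matching the
  printed population SDs.
* **Acidified events** re-draw the same latent population and split
  every bound particle; a detection-efficiency parameter (default 1)
  can thin the low-mass free-ProS events.
* **Glyco PSMs** cover the eleven N-sites (three C4BPa, five C4BPb,
  three ProS) with biantennary mono-/di-sialylated dominants except
  ProS N509 (triantennary di-/tri-sialylated); unoccupied probability
  0.25 at C4BPa N221/N528 and C4BPb N71, 0.05 elsewhere; scores
  Uniform(100, 400) and |log prob| Uniform(0.5, 4) so that the
  confidence filters bite realistically.
* **Cross-link fixture**: a toy model with two copies of one protein
  and one of another on a known coordinate grid, links spanning
  kept/dropped/overlength/unmappable cases, and a manifest of
  ground-truth distances computed from the same coordinates.
* **Plasma cohorts**: healthy samples carry equimolar
  alpha6 beta1 + ProS and alpha7 beta1 + ProS at 175 nM each (total
  C4BP ~0.35 uM, a realistic serum level) plus 100 nM free ProS;
  acute timepoints convert half the complexes to the beta-free 7-alpha
  species and raise CRP from 0.002 to 0.15 g/L. LFQ responds
  log-linearly with slope 1, intercept 6 and log10 noise SD 0.05.
  The 22 reference-panel concentrations are literature-plausible
  synthetic values spanning ~4.5 orders of magnitude (real reported
  averages must be supplied for real data).

What the generators do *not* emulate: instrument transients or spectra,
charge-state artifacts and adducts, glycan microheterogeneity beyond
categorical compositions, chromatographic drift, or cohort-level
biological covariance. Passing tests therefore demonstrate that the
pipeline correctly inverts data with the assumed statistical structure
at realistic noise levels — not that it is robust to every artifact of
real instrument data.

## Numerical choices and degenerate inputs

* EM: log-likelihood asserted non-decreasing each step; SDs floored at
  1e-6 of the data range; fits with fewer than 10 events per component
  are refused; windows with fewer than two distinct masses are
  degenerate errors.
* Occupancy algebra: infeasible inputs (f7 < a1 or f7 > a1 + a2) are
  clamped and flagged `feasible = FALSE` rather than erroring, so
  sampling noise at the extremes degrades gracefully.
* Assignment ties: |error| ties broken by fewer subunits, then label —
  arbitrary but deterministic.
* Rounding: charge rounding is half-up (`floor(x + 0.5)`), floored at
  one charge.
* Non-positive MP masses are dropped with a logged count; missing LFQ
  stays missing rather than becoming zero; unbound ProS clamps at zero.

## Problem sizes

Simulation-based tests and the acceptance script use 5000 events per
single-particle data set (matching the scale at which the published
peak parameters are quoted), 200 PSMs per glycosite, and cohorts of
2 donors x 5 timepoints. At these sizes every stage runs in seconds on
one CPU while keeping Monte-Carlo error comfortably inside the
tolerances being tested (e.g. component-weight SE ~0.007 at n = 5000).

## Known limitations

* The ~80 kDa near-degeneracy between one alpha chain and ProS is
  intrinsic; the package reports the ambiguity and resolves it only
  through the paired native/acidified algebra, never from a single
  histogram.
* The occupancy algebra assumes acidification dissociates all ProS and
  nothing else, and that detection efficiency is mass-independent above
  the complex floor.
* Glycoform dominance is per-site and categorical; linkage isomers and
  site-site covariance are out of scope.
* Cross-link validation is geometric (CA-CA against fixed caps); it
  does not re-estimate identification FDR or refine structures.
* The LFQ regression assumes a common log-linear response across
  proteins within a sample; protein-specific ionization efficiency is
  absorbed into the residual.

## A worked end-to-end example

```{r example, eval = FALSE}
library(c4bpquant)

# 1. simulate native and acidified serum CDMS measurements
native <- gen_cdms_events("SERUM-CDMS-NATIVE", 5000, seed = 42)
masses <- cdms_event_to_mass(native)

# 2. deconvolve and assign
fit <- fit_mixture(masses$mass, k = 3)
quantify_isoforms(fit)

# 3. infer ProS occupancy from a mechanistic native/acid pair
mech <- named_preset("MECHANISTIC")
occ <- estimate_occupancy(
  cdms_event_to_mass(gen_cdms_events(mech, 5000, seed = 42)),
  cdms_event_to_mass(gen_acidified(mech, 5000, seed = 43)))
occ$pros_bound

# 4. plasma monitoring
cohort <- gen_plasma_cohort(scenario = "acute", sigma = 0.05, seed = 1)
fits <- fit_concentration_regression(cohort$lfq, cohort$panel)
conc <- to_concentration(cohort$lfq, fits, mw_map = cohort$mw_map)
subunit_ratio(conc$conc_molar)
```
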