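---
title: "Tract-Profile statistics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract-Profile statistics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractometry)
```

## The data model

Tractometry pipelines reduce a diffusion MRI acquisition to *Tract
Profiles*: a tissue metric — fractional anisotropy (FA, dimensionless in
[0, 1]), mean/radial/axial diffusivity (MD/RD/AD, in µm²/ms) — sampled at a
fixed number of equidistant nodes (conventionally 100) along the core of
each major white matter tract (conventionally around 24 of them). For a
cohort, the natural container is one matrix per (tract, metric) pair with
one row per subject and one column per node. A `tractometry_dataset` holds
exactly that, plus a per-subject metadata table joined on `subjectID` and a
free-form parameter list; the on-disk twin is the tidy bundle
(`nodes.csv`, `subjects.csv`, `subjects.json`, `params.json`) written by
`write_tidy()`.

Nodes are indexed **0-based** everywhere — in files, in `node_range()`, in
reported peak locations. This matches the exchange format consumed by
browser-based viewers and avoids off-by-one mistakes when a brushed plot
range is carried back to anatomy. Ranges are inclusive on both ends:
"between nodes 50 and 80" selects 31 nodes, which is what
`brush_mask(100, list(node_range(50, 80)))` returns.

## Descriptive statistics

All group summaries are per-node sample statistics over the non-missing
member values: count `n`, mean, standard deviation with the *n − 1*
denominator, and standard error `sd/sqrt(n)`. The sample denominator is
deliberate: reference norms are always estimated from a finite sample of
controls, never treated as a population. Where fewer than two values are
present the dispersion fields are missing rather than zero.

Individual-versus-group comparison is the normative z-profile

$$z(v) = \frac{x(v) - \bar{x}_{\mathrm{ref}}(v)}{s_{\mathrm{ref}}(v)},$$

missing wherever the subject value or reference SD is missing or the
reference SD is zero (degenerate-variance nodes additionally warn). Two
properties are guaranteed and property-tested: affine invariance (scaling a
metric by `a*x + b` with `a > 0` leaves every z-profile unchanged) and the
exact-zero identity (with self-exclusion disabled, the member-wise mean of
z-profiles is identically zero at every node).

**Self-exclusion.** When the scored subject appears in the reference list it
is removed before the norms are computed. Patient-versus-control comparisons
are unaffected (the patient is never a control), and in leave-one-out use
within a single group this prevents the subject from shrinking its own
score. It can be disabled (`exclude_self = FALSE`) when the reference is
meant as a fixed population.

**The scalar z for a tract.** A z-profile must often be reported as a single
number per tract ("the lesion is 5.6 SD from the norms"). The default rule
is the *signed peak*: the signed value at the node of maximum |z| within the
(optionally brushed) range, ties broken toward the lowest node index. A mean
would dilute a focal lesion over the ~95 unaffected nodes; the peak is the
natural statistic for focal pathology. The rule is a package choice — the
per-tract scalar convention is not standardized across tools — so
`summarize_z()` also exposes `how = "mean"` for diffuse effects, and reports
the argmax node so the choice is auditable.

**Deviance fractions.** `fraction_deviant()` scores each group member
against the reference and counts members whose z exceeds the threshold
*strictly* at one or more nodes of the range. The default direction is
`absolute` (deviation without sign), matching how "deviated by more than
1 SD" is usually meant; one-sided variants are available. The fraction is
monotonically non-increasing in the threshold, which is property-tested.
For corticospinal-tract degeneration the package defaults suggest FA over
nodes 30–50 (the cerebral-peduncle end of a 100-node CST profile) as the
scan window; the window is an argument, not a constant, because published
analyses rarely state it explicitly.

## Binning

`bin_subjects()` reproduces the "sort the metadata column, divide into N
groups" interaction. The default method is `quantile` (near-equal group
sizes, differing by at most one), with a stable tie-break on
(value, subjectID) so that repeated runs and permuted inputs give identical
assignments. `explicit_edges` exists to reproduce published age bins such as
8–15 / 15–30 / 30–50: intervals are half-open `[e_i, e_{i+1})` with the last
closed, so a 30-year-old falls in 30–50, and values outside the edges stay
unassigned. Missing metadata values are never imputed; they are excluded
from every group and reported, because silently imputing a grouping variable
would corrupt the norms downstream.

## File formats

* **Tidy bundle.** CSV dialect: comma separator, UTF-8, LF endings, header
  row, cells quoted only when they contain a comma, quote or newline;
  missing values are empty cells (CSV) and `null` (JSON). Numbers are
  written with the fewest significant digits that round-trip to the same
  IEEE double, so files stay human-readable without losing precision; the
  round trip is exact and tested on randomized datasets.
* **AFQ MAT.** Classic (v7) files are read and written through scipy.io —
  the de-facto reference implementation for that container — via a small
  bridge script; the HDF5 layout is read and written natively with rhdf5.
  Field lookup is case-insensitive; because HDF5 group listings are
  alphabetical, the writer records the metric order in an explicit
  `metric_order` dataset.
* **TRACULA stats folders.** The on-disk dialect of `stats` folders varies
  between installations, so this package fixes its own documented contract:
  `<tract>.<metric>.txt`, whitespace-delimited, first column the subject ID,
  remaining columns node values, no header. Tracts whose raw node counts
  differ are harmonized by linear interpolation onto the maximum count
  present, with the raw counts recorded in `params` so nothing is silently
  lost.
* **Viewer state.** The state-to-query-string grammar (lexicographic key
  order, comma-joined percent-encoded list elements, `tract:start-end`
  brushes) is likewise this package's own documented contract; the encoder
  is canonical (equal states encode identically, defaults are omitted) and
  both round-trip directions are property-tested, including multi-byte
  subject IDs.
* **Publish payload.** The dry-run publish step emits a registration payload
  validated against the JSON schema shipped in `inst/schema/`; the schema is
  the package's own, since no public payload schema exists for such
  registries. Hashes in the site manifest are SHA-256.

## The synthetic cohort generator

`generate_dataset()` realizes the model

$$x_s(v) = \mu(v) + \delta \cdot [s \in \mathrm{group}] \cdot [v \in \mathrm{window}] + b_s + \varepsilon_s(v)$$

with a smooth mean profile µ (per-metric baseline plus Gaussian bumps, with
a small tract-specific phase shift so tracts differ), between-subject
offsets `b_s ~ N(0, τ²)` drawn independently per subject and (tract, metric),
and stationary AR(1) node noise with marginal SD σ and lag-1 correlation ρ
(`ε_1 ~ N(0, σ²)`, `ε_v = ρ ε_{v−1} + σ√(1−ρ²) η_v`). All randomness flows
from one seed through Mersenne–Twister with a fixed draw order (metadata,
then per metric × tract: offsets, then noise), so a spec plus a seed is a
complete description of a dataset.

Default conditions: 30 subjects, six major tracts, 100 nodes, FA/MD/RD/AD
with baselines 0.5 / 0.8 / 0.6 / 1.2, τ and σ each 5 % of baseline, ρ = 0.7,
age uniform on 8–50 years. These are meant as a plausible healthy-adult
tractometry cohort: FA around 0.5 with ±10 % smooth anatomical structure,
coefficient of variation of a few percent, strongly autocorrelated node
noise (profiles are smooth because neighbouring nodes share anatomy).

Focal lesions are injected in **control-SD units**: a Gaussian bump of peak
amplitude `A·sd_ctrl(v)` (sign chosen per metric — diffusivities rise in
lesions, FA falls), so the injected amplitude maps directly onto the
normative z magnitude the analysis should recover, up to norm-estimation
noise. With 30 controls, the sample SD of the norm is itself noisy
(`SD(s)/σ ≈ 13 %`), so a 5-SD injection is recovered as a peak z
distributed around 5 with substantial spread — the calibration check in the
test suite therefore asserts the peak node within ±5 nodes of the injection
in at least 90 % of replicate cohorts and a median peak z in [4.0, 6.5],
not an exact value.

**What the generator does not emulate:** site and scanner effects,
metric-to-metric correlation within subject (FA and RD are generated
independently although they are algebraically coupled in real tensors),
heteroscedastic noise along the tract, non-Gaussian outliers, and any real
anatomical correspondence of node indices. Green tests on synthetic cohorts
therefore demonstrate the correctness and calibration of the *computations*,
not the clinical sensitivity of the measures on real data.

## Numerical and testing choices

Oracle-style tests re-implement every statistic as explicit per-node loops
and require agreement to 1e-10 on randomized small datasets (100 datasets,
up to 6 subjects × 5 nodes). Round-trip suites run on 50 randomized
datasets. The lesion-recovery check uses 20 replicate cohorts of 31
subjects at 100 nodes; the group-effect recovery check uses 400 subjects on
one tract. These sizes keep each property in the seconds range while leaving
the statistics well-resolved. Degenerate inputs are resolved explicitly:
zero reference SD gives missing z plus a warning, empty groups give `n = 0`
all-missing summaries, all-missing ranges are errors rather than NaN, and
`n_groups` larger than the assigned subject count is an error for quantile
binning.

## Known limitations

* Classic MAT v7 support requires a `python` with scipy on the `PATH`
  (declared in `SystemRequirements`); the HDF5 MAT layout needs no external
  interpreter. Deeply nested or reference-heavy MATLAB v7.3 files beyond
  the documented layout are not supported.
* The static server is a deliberately small single-threaded GET-only
  implementation intended for local viewing and testing, not for production
  hosting.
* Publishing is dry-run only by design: the artifacts (repository copy plus
  registration payload) are produced and verified locally, and actual
  uploads are left to external tooling.
* Statistical inference (hypothesis tests, multiple-comparison control,
  cluster statistics) is out of scope; the package computes descriptive and
  normative quantities only.
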