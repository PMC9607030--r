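---
title: "Auditing meal-delivery-app offerings: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing meal-delivery-app offerings: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdaudit)
```

`mdaudit` implements a reproducible audit of the food offerings of
meal-delivery apps (MDAs): stratified spatial sampling of addresses, a
core/discretionary healthiness score for menu items, a supervised text
classifier that imitates manual scoring, and equity analyses of
healthy/unhealthy proportions and outlet availability by deprivation,
outlet-density and ethnicity strata. This vignette explains the underlying
models and the choices made where the design was genuinely open.

## The sampling design

The unit of sampling is a small census area (an SA1-like unit). Within each
city, units are classified three ways:

* **Deprivation tertile** — thirds of a continuous deprivation index
  (higher = more deprived, mirroring a national deprivation index), computed
  within city.
* **Physical-access tertile** — thirds of the count of unhealthy-food
  outlets (dairy/convenience, fast food, takeaway) within an 800 m buffer of
  the unit centroid. Buffer membership is a closed Euclidean ball
  (distance ≤ 800 m): "within" is read inclusively, and the test oracles
  match that convention.
* **Higher-Māori flag** — whether the unit's Māori population proportion is
  in the top fifth within its city.

Three cities × 3 × 3 × 2 = 54 cells; 2 units are drawn per "other" cell and
1 per higher-Māori cell (81 total), then one address per sampled unit.

Three conventions deserve comment because the design brief leaves them
open:

* **Access tertiles are computed within city**, symmetric with the explicit
  within-city rule for deprivation. Pooling across cities would let one
  dense city absorb an entire tertile and empty out cells.
* **"Top quintile" vs "above the 80th percentile"** coincide under the rule
  used here: a unit is flagged when its proportion is ≥ the k-th largest
  within-city value, k = ⌊n/5⌋, with boundary ties resolved toward
  inclusion. A fully tied city flags every unit — degenerate but
  well-defined.
* **Ties everywhere are broken by a stable id sort** before any split or
  random draw. Consequently tertile assignment, quintile flags and sampling
  are invariant to the row order of their inputs, and a fixed seed
  reproduces the frame exactly.

When a city's count is not divisible by three, the lower tertiles take the
extra units (sizes as equal as possible, differing by at most one; ties can
shift a boundary by design, never by accident).

## The synthetic data generator

The generator replaces live census layers, address databases and web
scraping so the whole pipeline runs offline with known ground truth. It
emulates:

* **Geography** — each city is a grid of non-overlapping square units
  (default side 500 m), spaced far apart so buffers never straddle cities.
  Real SA1 polygons are irregular; squares keep point-in-area tests exact
  and dependency-free, which is what the downstream logic needs.
  Deprivation is uniform on [1, 10] (used only through ranks, so the shape
  is immaterial); the Māori population proportion is Beta(2, 8)
  (mean 0.2, matching the national share); addresses are uniform inside
  their unit.
* **Outlet clustering** — outlet counts per unit are Poisson with intensity
  ∝ exp(γ·z), z the within-city standardised deprivation and γ the
  clustering coefficient (default 1), normalised so the expected city-wide
  density stays at `outlet_intensity` (default 12 per km²). γ > 0 makes
  outlet density rise with deprivation, the association physical-access
  tertiles are meant to capture; γ = 0 gives a homogeneous landscape.
* **Coverage gaps** — each service has a per-city coverage probability and
  each address is covered by an independent Bernoulli draw. The default
  service set has two full-coverage services and one "domestic" service
  with 0.3 coverage in Auckland and 0.95 elsewhere, reproducing the
  observed pattern of a partially rolled-out platform missing most of one
  city. Uncovered addresses produce no snapshot and are logged as gap
  records, mirroring real audits where unavailable addresses must be
  accounted for.
* **Menus** — item categories are drawn from a mixture over the manual's 36
  categories. The default mixture allocates mass per overall score
  (−2: 0.30, −1: 0.31, 0: 0.16, 1: 0.20, 2: 0.03, split uniformly within a
  score group), reproducing the strong unhealthy skew that published MDA
  audits report (roughly three quarters of items scoring ≤ 0). Item text is
  drawn from per-category template sets; token noise applies, per token
  with probability `text_noise_rate`, a synonym substitution where a
  synonym is defined and dropout otherwise. A name that would be emptied by
  dropout retains its first token so the non-empty-name invariant always
  holds. Item lists are generated only for the first `item_depth` outlets
  (default 12, comfortably above the 10-outlet analysis window): only items
  near the top of the list are ever observed, while open-outlet counting
  uses the full list.

What the generator does **not** emulate: real joint distributions of
deprivation, ethnicity and outlet density (the defaults are plausible, not
estimates); personalised or account-holder views; duplicate outlet
listings; multilingual or free-form menu prose. Passing tests on synthetic
data therefore validate the *pipeline* — classification, sampling, scoring,
testing — not any substantive claim about real platforms.

Default sizes: 400 units per city. The higher-Māori flag selects a fifth of
each city, spread over 9 access × deprivation combinations, so each
higher-Māori cell expects about `sa1_per_city/45` members; 400 keeps the
probability of an empty cell around 10⁻³. The frame sampler refuses empty
cells by design and names them, and callers regenerate the geography with a
fresh seed — the bundled acceptance script does exactly that with a
deterministic seed offset.

## The scoring manual

The manual is data, not code: a CSV with one row per category carrying the
category-level core and discretionary integers (each 0–2), an alcohol flag,
and component columns (variety, fruit/veg, whole grains, dairy, protein;
saturated fat, salt, sugar, processed) kept as rationale metadata. The
category-level integers are authoritative — no aggregation formula from
components is applied, because none is defined for the scheme; the
components document *why* a category scores as it does.

The bundled default has 36 categories. Three of them, and the alcohol rule,
reproduce externally documented scores (`source = "printed"`): salad 2/0,
premium burger 2/2, pizza meal deal 0/2, and alcoholic drinks 0/2 (overall
−2). The remaining 32 are this package's own reconstructions
(`source = "reconstructed"`) chosen to populate all five overall-score
levels with plausible takeaway categories; any study using this package in
earnest should substitute its own manual via `load_manual(path)`.

Scoring invariants, enforced and exhaustively tested over the nine
(core, discretionary) pairs: overall = core − discretionary ∈ {−2, …, 2};
binary healthy ⇔ overall ≥ 1; alcohol ⇒ 0/2 ⇒ overall −2. Items with a
missing category label are routed to an `"unlabelled"` bucket, never
silently dropped.

## The text classifier

The classifier imitates manual scoring from item text (name +
description). Choices:

* **Two independent 3-class targets** (core, discretionary) rather than one
  9-class joint target, matching how agreement is reported per component.
* **Features**: lowercase word-token counts with a minimum corpus frequency
  (default 2). No embeddings, no pretrained models — the workflow is the
  contribution, and a bag of words is transparent and fast.
* **Model**: a single-hidden-layer feed-forward network with softmax output
  (`nnet`), hidden size 8, iteration cap 200, small weight decay. The
  architecture is exposed in `classifier_spec()` and deliberately small;
  anything that predicts two 3-class targets can be swapped in.
* **Accuracy** is exact score match per target, in percent.
* **Cross-validation**: records are pre-sorted by a stable key, folds are a
  random partition with sizes differing by ≤ 1, each record tests exactly
  once; the report is invariant to input row order for a fixed seed.

On synthetic text the classifier recovers the generator: at noise 0 the
category vocabularies are distinct and CV accuracy reaches 100% for both
targets; after label permutation accuracy falls to the chance level implied
by the label marginal (the test computes the bound by Monte Carlo over the
duplicated-text structure, since a signal-free model can still memorise the
plurality label of repeated texts). Accuracy declines only gently with
token noise: with templated text and distinctive vocabularies, a handful of
surviving tokens usually still identifies the category — a reminder that
synthetic difficulty is a lower bound on real-world difficulty, where
vocabulary overlap between categories is far greater. Published audit-scale
accuracies (high 80s on ~2000 hand-scored items) are plausible mid-noise
values here but are not reproducible without the original training data,
and the package makes no attempt to match them.

## Analysis stage

* **Chi-square**: the uncorrected Pearson statistic, Σ(O−E)²/E with
  E = row × column / N, upper-tail p on (r−1)(c−1) df. No Yates continuity
  correction, including for 2 × 2 tables — the uncorrected statistic is
  what reproduces published audit results exactly, and the choice is
  validated in tests against the closed form N(ad−bc)²/(r₁r₂c₁c₂) and an
  independent implementation. Tables with a zero margin are an error (the
  expected counts are undefined), not a silent 0. p-values are reported in
  full precision; the α = 0.05 decision is a labelled column, never a
  data-destroying threshold.
* **Quartiles**: Tukey hinges (`fivenum`) by default. Half-integer medians
  for even groups constrain the median to the midpoint rule; the published
  Q1/Q3 convention is not identifiable from half-integer medians alone, so
  the hinge rule was chosen (it is the same midpoint logic applied to each
  half) and a `rule = "linear"` override (`quantile` type 7) is exposed.
* **Calibration**: under simulated independence of class and stratum the
  chi-square stage rejects at the nominal 5% rate; the acceptance test runs
  1 000 independence replicates of 900 items each and checks the rejection
  count against the binomial 99% band.

## Reproducibility machinery

Every random stage takes an explicit seed and restores the caller's RNG
state (`withr::with_seed`). The pipeline derives stage seeds from one
master seed (geography +0, frame +1, snapshots +2, classifier +3), and
`run_audit()` records seeds, record counts and content hashes in a
manifest; identical configs give identical bundles, byte-identical through
JSONL serialisation. Problem sizes used by the test suite are deliberately
modest — 150 units per city for pipeline tests, 300 for the acceptance
script, a few hundred items for classifier tests — chosen as the smallest
sizes at which every stratification cell is reliably populated and the
statistical checks have power.

## Known limitations

* Square-grid geography and planar metres only; no projections, road
  networks or population weighting within units.
* The generator's stratum structure is independent of menu content by
  default, so equity differences exist only if configured (via
  stratum-varying `category_mixture` functions).
* The bundled manual's 32 reconstructed categories are illustrative; the
  binary healthy/unhealthy split discards the distinction between scores
  within each class.
* The classifier's noise axis under-states real-world text ambiguity, as
  discussed above.
* Duplicate outlet listings are rejected at validation rather than
  deduplicated; how a live platform's duplicates should be handled is a
  scraping-time policy this package does not take a position on.
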