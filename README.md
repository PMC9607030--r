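# mdaudit

Meal-delivery apps (MDAs) are an increasingly important — and largely
unregulated — part of the urban food environment. Public-health researchers
auditing them face a recurring design: sample residential addresses across
strata of socioeconomic deprivation, physical food-outlet density and
ethnicity; record what each platform displays to a naive user at each
address; score every menu item for healthiness; and test whether the
offerings differ by stratum. `mdaudit` packages that whole workflow for R,
with a synthetic-data generator in place of live scraping and census layers,
so every stage is reproducible and testable offline. It is aimed at food
environment and health-equity researchers who want to develop, validate or
power such an audit before (or instead of) touching live platforms.

## The design and the statistics

**Stratified address sampling.** Each city's small-area units (SA1-like
census areas) are classified into tertiles of deprivation, tertiles of
physical access to unhealthy food (count of outlets within an 800 m
Euclidean buffer of the unit centroid), and a binary higher-Māori flag (top
fifth of Māori population proportion within the city, boundary ties
included). With 3 cities this yields 3 × 3 × 3 × 2 = 54 cells; sampling 2
SA1s per "other" cell and 1 per higher-Māori cell gives 81 SA1s, and one
street address is drawn per sampled SA1.

**Healthiness scoring.** Each menu item is assigned to one of 36 categories
in a classification manual. A category carries a core score *c* ∈ {0, 1, 2}
(everyday-food components: variety, fruit/veg, whole grains, dairy, protein)
and a discretionary score *d* ∈ {0, 1, 2} (saturated fat, salt, sugar,
processing). The overall score is

&nbsp;&nbsp;&nbsp;&nbsp;*s* = *c* − *d* ∈ {−2, …, 2},

with *s* ≥ 1 classed **healthy** and *s* ≤ 0 **unhealthy**. Alcoholic drinks
score 0/2, hence *s* = −2.

**Observation window.** Only the first 10 outlets shown to an address and
the first 10 items per outlet are analysed (at most 8 100 items per service
for 81 addresses); open-outlet availability is counted over the full list.

**Classifier.** A bag-of-words featuriser feeding two independent 3-class
single-hidden-layer neural networks imitates the manual scoring from item
text, evaluated with k-fold cross-validation (exact-match accuracy per
target).

**Equity analysis.** Per service: the score distribution; 2 × k
healthy/unhealthy contingency tables by stratification factor tested with
the uncorrected Pearson chi-square, Χ² = Σ (O−E)²/E on
(rows−1)(cols−1) df; and open-outlet quartile summaries (Tukey hinges, so
even-sized groups get midpoint medians).

## Worked example

A single chi-square on a published 2 × 2 table (healthy/unhealthy counts for
higher-Māori vs other addresses):

```r
library(mdaudit)
tab <- contingency_table(rbind(c(448, 1070), c(2250, 4308)),
                         factor_name = "Maori population", service = "Menulog")
chi_square(tab)
#> <mda_chisq> X-squared = 12.7487, df = 1, p = 0.0003563
```

The statistic of 12.7 on 1 df (p ≈ 0.0004) says the healthy share differs
between the two address groups — here 16.6% healthy for higher-Māori
addresses vs 19.9% for the rest.

The full synthetic pipeline, end to end:

```r
res <- run_audit(audit_config(seed = 1))
res
#> <mda_audit> seed 1: 81 sampled SA1s, 219 snapshots (24 coverage gaps), 16745 scored items

res$unhealthy
#> # A tibble: 3 × 4
#>   service          n_unhealthy total unhealthy_pct
#> 1 delivereasy-like        3465  4451          77.8
#> 2 menulog-like            4682  6167          75.9
#> 3 ubereats-like           4754  6127          77.6

dplyr::filter(res$chi_tests, service == "menulog-like")
#> # A tibble: 3 × 6
#>   service      factor           statistic    df p_value significant
#> 1 menulog-like NZDep                0.459     2  0.795  FALSE
#> 2 menulog-like physical density     1.63      2  0.442  FALSE
#> 3 menulog-like Maori population     2.79      1  0.0950 FALSE
```

Three services are simulated over 81 stratified addresses; one service has a
deliberate coverage gap in one city (the 24 logged gaps), roughly three
quarters of simulated items are unhealthy under the default category
mixture, and — because the default generator draws item categories
independently of stratum — the chi-square tests are correctly
non-significant. `report_markdown(res)` renders the three result surfaces;
`autoplot()` methods cover contingency tables and CV reports.

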