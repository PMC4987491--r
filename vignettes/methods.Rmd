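---
title: "Measuring health-website quality: instrument, scoring rules and statistical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health-website quality: instrument, scoring rules and statistical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhws)
```

## The measurement problem

Healthy People 2020 tracks two objectives for the quality of health-related
websites. HC/HIT-8.1 asks what proportion of sites meet at least 3 of 6
evaluation criteria for disclosing information that lets a user judge
reliability (who runs the site, why, how content is produced and kept
current, how privacy is handled, how users can respond). HC/HIT-8.2 asks
what proportion follow established usability principles — 19 composites in
three categories (site design, information architecture, content design),
each scored as the mean of its task-based measures, rated 1 ("task
failure") to 4 ("minimal problems") by a trained reviewer, with a
principle counted as followed at a mean of 3.5 or better and the
site-level benchmark at 10 or more of the 19 principles.

`qhws` implements that measurement chain end to end: the instrument as
data, sample eligibility, rubric scoring, interrater-reliability gating,
binomial compliance estimation with Wald intervals, and target setting.
Because the per-website raw reviews behind the published baseline were
never deposited, the package also ships a seeded synthetic-assessment
generator so that every stage is testable against data whose true
parameters are known.

## The instrument as data

`load_instrument()` returns the canonical definition: 6 reliability
criteria holding 16 disclosure elements, and 19 usability principles
holding 59 measures. Scoring is entirely definition-driven; a modified
rubric loaded from YAML flows through the same code.

```{r}
instr <- load_instrument()
instr
```

Three element attributes carry scoring semantics:

* **Optional** elements ("how information from users is used", "copyright
  date") can never cause a criterion to fail.
* **Page-scoped** elements (authorship and the two content-dating items)
  are assessed on at least three sampled pages of health content. The
  instrument's source material describes the page sampling but not the
  pass rule, so the rule is a parameter: `page_policy = "all"` (default),
  `"any"`, or `"majority"`. "All" was chosen as the default because a
  disclosure that is absent from a sampled page is not reliably available
  to a user landing on that page.
* **Conditional** elements (differentiating advertising from content)
  only apply to sites with the relevant feature. Conditionality lives in
  the data as `NA` responses, not in the instrument: an `NA` drops the
  site from that element's estimation denominator and is excluded from
  the criterion determination.

The 59 individual measure texts are not part of the public record, so the
default instrument distributes 59 placeholder measures over the 19 named
principles through a configurable allocation table (4 for the first
principle of each of the two larger categories, 3 elsewhere). All scoring
logic is allocation-agnostic; only the totals are asserted.

## Scoring rules and their edge cases

**Criterion rule.** A criterion is met iff every required element that is
applicable (non-`NA`) scores yes. The aggregation rule is not stated
explicitly in the instrument's documentation; reading "required" versus
"optional requirements" as conjunctive necessity is the natural
interpretation and the one implemented. The test suite pins this
semantics by exhaustive enumeration over `{yes, no, NA}^k`.

**Threshold comparison.** A principle's mean of 3.5 counts as met
(inclusive comparison). Because means sit exactly on the boundary for
many rating patterns (e.g. `c(3,4)`), the determination is made in
integer arithmetic — `100 * sum(ratings) >= 350 * m` — so no boundary case
can be lost to floating-point representation.

**Unscorable principles.** When every measure of a principle is `NA` for
a site, the principle counts as *not met* in that site's 10-of-19
benchmark, but the site is *dropped from the denominator* of that
principle's compliance estimate. These two choices are deliberately
asymmetric: the benchmark is a site-level claim that should not be
inflatable by unassessable composites, whereas the per-principle estimate
is a claim about sites on which the principle could be assessed. The
published per-principle table contains one row whose printed percent
(39.4 from a count of 39) is only consistent with a denominator of 99
under exactly this rule, which is why it was adopted.

## Interrater reliability and the training gate

Before dividing the sample, two reviewers co-score training sites until
agreement clears a benchmark: Cohen's kappa at .80 for the nominal
disclosure items, and an intraclass correlation at .61 for the ordinal
usability ratings. `cohens_kappa()` pools item-level responses from all
co-rated sites into a single contingency table per instrument — the
published account reports one kappa across the co-rated sites without
stating a pooling rule, and item-level pooling is the variant that uses
every scored pair.

`icc()` implements the two-way random-effects, absolute-agreement,
single-rater form, ICC(A,1):

$$\mathrm{ICC} = \frac{MS_S - MS_E}{MS_S + (k-1)MS_E + \tfrac{k}{n}(MS_R - MS_E)}$$

Absolute agreement is the right form here because the reviewers go on to
score *different* sites alone, so a systematic severity shift between
raters is real disagreement; the consistency form, which forgives such
shifts, is available via `form = "consistency"` and the form used is
recorded in the result. Which ICC variant produced the published training
statistic is unstated, and without the unpublished ratings it cannot be
re-derived; the choice here is a design decision, not a reproduction.

Altman's qualitative scale bands the statistic (Poor < .20, Fair .21–.40,
Moderate .41–.60, Good .61–.80, Very good .81–1.00). The printed bins
leave a gap between .20 and .21; values are rounded to two decimals
before lookup so the bins are exhaustive (0.205 rounds to .21, Fair).

```{r}
shifted <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
icc(shifted)          # constant shift: < 1 under absolute agreement
altman_category(0.83) # the reliability instrument's training kappa band
```

## Estimation and target setting

Every compliance figure is a binomial proportion on the percentage scale
with Wald machinery: $SE = 100\sqrt{\hat p(1-\hat p)/n}$ and
$CI = 100\hat p \pm 1.96\,SE$. Wald (not Wilson or Clopper–Pearson)
intervals are used because the published tables are Wald exactly — every
printed row is reproduced to the printed precision from its count and
denominator, e.g.:

```{r}
presented(proportion_estimate(37, 100))
presented(proportion_estimate(28, 60))   # the conditional element, n = 60
```

Intermediates are carried unrounded; rounding happens only at
presentation (percent and CI bounds to 1 decimal, SE to 2, halves away
from zero — base R's round-half-to-even does not match published tables),
and CI bounds are clipped to [0, 100] after rounding.

Targets are set at *minimal statistical significance*: the smallest
improvement over the baseline detectable at the two-sided 95% level
between two independent samples of the baseline's size,

$$\mathrm{target} = \hat p + 1.96\sqrt{2}\,SE.$$

From the usability baseline of 42/100 this gives 55.7%, matching the
published 2020 target exactly. From the reliability baseline of 58/100
the same formula gives 71.7%, whereas the published target is 70.5%; the
published arithmetic for that number is not stated and is not claimed to
be reproducible here. `set_target()` therefore reports the formula value
and carries any externally mandated figure in a separate `override` slot,
never substituting it.

Wald coverage is checked by simulation in the test suite: at $n = 100$
and $p \in \{0.2, \ldots, 0.8\}$ with 10,000 replicates per point,
empirical coverage stays within 92–97%. Wald intervals degrade near the
boundaries ($p$ close to 0 or 1, where the interval collapses to zero
width at observed counts of 0 or $n$); none of the published rows except
the degenerate 100% row sit in that regime.

## The synthetic-assessment generator

The generator emulates the statistical structure the analysis assumes,
with defaults fixed at the study's conditions where those are on record:
100 sites per dataset, element compliance marginals at the published
element rates, the advertising item not applicable on 40% of sites
(matching its published denominator of 60), and a 48/36/16
for-profit/nonprofit/government sponsor mix.

* **Correlated binaries** come from a one-factor Gaussian threshold
  model: site factor $z_s$, element outcome yes iff
  $\sqrt{\lambda} z_s + \sqrt{1-\lambda}\,\varepsilon \le \Phi^{-1}(p_j)$.
  Marginals are preserved exactly for any $\lambda$; a single knob
  ($\lambda$, default 0.3) couples elements within a site so the
  criteria-met distribution is non-degenerate. The true inter-element
  correlation of the study is unknowable from printed marginals; 0.3 is a
  documented convention, not an estimate.
* **Ordinal ratings** come from a latent-normal cutpoint model: a
  site-by-principle quality score $N(\mu_p, \sigma_p)$ (defaults 3.4 and
  0.5 on the rating scale) plus measure-level noise (sd 0.5), discretised
  at cutpoints 1.5/2.5/3.5. No rating distribution was ever published;
  these defaults yield non-degenerate met-rates on both sides of the 3.5
  threshold.
* **Two raters.** Rater B reproduces each of A's item values with
  probability `rater_agreement`, otherwise resamples from the item's
  *marginal* distribution (not uniformly) — chosen so that chance
  agreement matches kappa's chance model, which makes the expected kappa
  equal the agreement parameter exactly:
  $p_o = a + (1-a)p_e \Rightarrow \kappa = a$. This gives the test suite
  a closed-form oracle: simulated kappa at agreement 0.6/0.8/0.95 must
  land within ±0.05 at 500+ item pairs.

What the generator does **not** emulate: real review behaviour
(rater-specific bias, item difficulty, within-criterion structure beyond
one factor), page-level observations, or the study's unpublished joint
distribution. Passing recovery tests therefore demonstrates that the
pipeline is statistically faithful to its own model, not that the model
reproduces the 2014 review.

```{r}
set <- generate_dataset(generator_params(n_sites = 100, seed = 2026))
res <- run_pipeline(set, output_dir = NULL)
res$benchmarks[, c("objective", "count", "n", "percent", "ci_low", "ci_high")]
```

## Problem sizes and numerical choices

Simulation-based checks in the tests use 300–2,000 synthetic sites and
10,000 binomial replicates per coverage point — sizes at which Monte-Carlo
error (3 SEs) is far smaller than the tolerances being checked, while a
full test run stays under a minute. Degenerate inputs are rejected or
signalled rather than silently absorbed: a 0% or 100% baseline has no
sampling error to scale a target (domain error); two constant identical
raters make kappa undefined ($p_e = 1$; `NA` with a classed warning
rather than 0/0); zero between-subject variance makes the ICC degenerate
(same treatment); a zero estimation denominator emits an `NA` row with a
warning rather than dropping the row.

## Known limitations

* The headline baselines (58.0% reliability, 42.0% usability) are not
  desk-reproducible from any published artifact; the package validates
  its scoring chain by oracle equivalence, monotonicity properties and
  constructed fixtures instead.
* The published reliability target (70.5%) does not follow from the
  formula that exactly reproduces the usability target; it is recorded,
  not reproduced.
* Kappa here is unweighted two-rater kappa; weighted kappa, more than two
  raters and Krippendorff's alpha are out of scope.
* The eligibility filter implements the published inclusion/exclusion
  rules as a closed vocabulary; it does not attempt traffic ranking or
  any crawling of live sites.
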