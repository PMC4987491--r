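# qhws

Quality assessment of health-related websites against the Healthy People
2020 website-quality objectives.

Healthy People 2020 tracks two measurable objectives for the quality of
Web-based health information. **HC/HIT-8.1** (information reliability): the
proportion of health-related websites meeting **3 or more of 6**
disclosure criteria — Identity, Purpose, Content Development, Privacy,
User Feedback, Content Updating — each a list of yes/no disclosure
elements. **HC/HIT-8.2** (usability): the proportion following **10 or
more of 19** established usability principles, where each principle is
scored as the mean of its task-based measures (rated 1 = task failure to
4 = minimal problems) and is "followed" at a mean ≥ 3.5.

`qhws` is for survey methodologists and health-communication researchers
who need that measurement chain as tested, reusable code:

- the survey **instrument as data** (criteria, required/optional/
  page-scoped/conditional disclosure elements, principles, measures,
  benchmark minima), loadable from YAML;
- **sample eligibility** filtering (≥ 3 items of health information, a
  closed vocabulary of exclusion reasons);
- **rubric scoring** to per-site scorecards: a criterion is met iff every
  required, applicable element is yes; principle means are compared to
  3.5 in exact integer arithmetic;
- **interrater reliability**: pooled Cohen's kappa for nominal items
  (training gate .80), two-way absolute-agreement ICC(A,1) for ordinal
  ratings (gate .61), Altman's qualitative bands;
- **estimation**: binomial compliance proportions with Wald standard
  errors and 95% CIs, per-item applicability denominators, met-count
  distributions;
- **target setting** at minimal statistical significance:
  `target = p̂ + 1.96·√2·SE`, the smallest improvement detectable between
  two independent samples of the baseline's size;
- a seeded **synthetic assessment generator** (one-factor threshold model
  for correlated disclosures, latent-normal cutpoint model for 1–4
  ratings, two-rater data with controllable agreement) standing in for
  the study's unpublished raw reviews.

## Worked example

```r
library(qhws)

instr <- load_instrument()
instr
#> <qhws_instrument hp2020-canonical-1.0>
#>   6 reliability criteria (16 disclosure elements), benchmark >= 3
#>   19 usability principles (59 measures, rated 1-4), benchmark >= 10

# simulate a 100-site assessment and run the full analysis
set <- generate_dataset(generator_params(n_sites = 100, seed = 2026))
res <- run_pipeline(set, output_dir = NULL)

res$scores
#> <qhws_scores: 100 sites, rater 'r1'>
#>   HC/HIT-8.1 reliability benchmark met: 68 (68.0%)
#>   HC/HIT-8.2 usability benchmark met:   21 (21.0%)

res$benchmarks[, c("objective", "count", "n", "percent", "se", "ci_low", "ci_high")]
#>    objective count   n percent   se ci_low ci_high
#> 1 HC/HIT-8.1    68 100      68 4.66   58.9    77.1
#> 2 HC/HIT-8.2    21 100      21 4.07   13.0    29.0
```

Of these 100 synthetic sites, 68 met at least 3 of the 6 reliability
criteria and 21 followed at least 10 of the 19 usability principles; each
share is reported with its Wald SE and 95% CI in percentage points.
(These are properties of the seeded simulation, not of any real
websites.) Passing `output_dir` writes the whole bundle — scorecards,
compliance table, met-count distributions, benchmark summary, targets,
and an IRR report when two raters are present — as CSV/text files.

Single estimates and targets work standalone, reproducing published
baseline rows from their counts:

```r
presented(proportion_estimate(37, 100))
#> percent      se  ci_low ci_high
#>   37.00    4.83   27.50   46.50

set_target(42, 100)
#> baseline 42.0% (n=100, SE 4.94) -> 2020 target 55.7% [minimal-statistical-significance]
```

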