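---
title: "Models and methods behind ltmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ltmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltmet)
```

## The problem

`ltmet` analyses balanced line × tester testcross trials of the kind used to
screen maize inbred lines for drought tolerance: *l* candidate lines
(females) each crossed to a common set of *t* testers (males), the resulting
hybrids grown in *r* replicates of a randomized incomplete block design at
*e* environments per research condition (managed drought versus rain-fed).
The pipeline covers genotype means, the multi-environment ANOVA with
variance components and hybrid-mean repeatability, the partition of hybrid
variation into general (GCA) and specific (SCA) combining ability, a
standardized multi-trait selection index, a rule-based heterotic-group
classifier, and GGE biplot geometry for which-won-where and stability
questions.

## Linear model and ANOVA

A plot value is described as

$$y = \mu + E_k + R_{r(k)} + B_{b(rk)} + G_g + (GE)_{gk} + \varepsilon$$

with environments, replicates and blocks random and genotypes fixed.
`trial_anova()` requires a balanced layout (every genotype once per
environment × replicate) and decomposes the total sum of squares
sequentially over the sources E, Rep(E), Block(E×Rep), G, G×E, Error. When
no incomplete blocks are present the closed-form balanced decomposition is
used; with blocks, sequential (Type I) projections with the nuisance terms
fitted *before* genotypes — the classical lattice treatment of blocks as
fixed nuisance effects. The exact recovery-of-interblock-information
adjustment of lattice-analysis software is deliberately not replicated;
unbalanced data are refused with a pointer to `ls_means()`, whose
least-squares genotype means (sum-to-zero nuisance contrasts) are the
stage-wise alternative.

F-test denominators follow the random-environment convention: genotypes are
tested against the G×E mean square; G×E, blocks and replicates against
Error; environments against Rep(E). The source study's ANOVA software
implies but never prints these choices; fixing them here makes the output
deterministic.

### Variance components and repeatability

`variance_components()` solves the expected mean squares by the method of
moments:

$$\hat\sigma^2 = MS_{Error},\qquad
  \hat\sigma^2_{GE} = \frac{MS_{G\times E} - MS_{Error}}{r},\qquad
  \hat\sigma^2_{G} = \frac{MS_{G} - MS_{G\times E}}{re}.$$

For the balanced complete case this is identical to REML (which the source
study used); it is exact, fast and fully deterministic, which is why it was
preferred over a general mixed-model optimizer. Negative solutions are
truncated to zero with a logged warning. Hybrid-mean repeatability is

$$R = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/e + \sigma^2/(re)},$$

monotone in each genetic argument and always in [0, 1]; the worked identity
$R(\sigma^2_G{=}2, \sigma^2_{GE}{=}3, \sigma^2{=}4, r{=}2, e{=}3) = 0.5455$
is asserted in the tests.

## Combining ability

With condition-level cell means $\bar y_{ij}$ for line *i* × tester *j*,

$$\widehat{GCA}_i = \bar y_{i\cdot} - \bar y_{\cdot\cdot},\qquad
  \widehat{GCA}_j = \bar y_{\cdot j} - \bar y_{\cdot\cdot},\qquad
  \widehat{SCA}_{ij} = \bar y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j}
  + \bar y_{\cdot\cdot}.$$

Each effect vector sums to zero and the SCA matrix is doubly centred; both
identities are enforced to 1e-9 in the tests, and the mean SCA per tester
(the zero "Mean" row of a published testcross table) is an acceptance
target. `ca_mean_squares()` partitions the hybrid sum of squares
orthogonally into GCA~line~, GCA~tester~ and SCA (the partition is exact by
projection algebra), plus their environment interactions; incomplete-block
variation, if present, is left in Error for this table.

Effect standard errors use the balanced line × tester forms with
$\hat\sigma^2 = MS_{Error}$:
$\mathrm{Var}(\hat g_{line}) = \hat\sigma^2 (l-1)/(lt re)$,
$\mathrm{Var}(\hat g_{tester}) = \hat\sigma^2 (t-1)/(lt re)$,
$\mathrm{Var}(\hat s) = \hat\sigma^2 (l-1)(t-1)/(lt re)$. The source cites a
standard textbook without printing formulas; these are the usual balanced
expressions and make the effect tables deterministic.

### Baker's proportion

The relative weight of additive variation is
$2\hat\sigma^2_{GCA} / (2\hat\sigma^2_{GCA} + \hat\sigma^2_{SCA})$ with the
components solved from expected mean squares after subtracting the matching
environment-interaction mean square (the interaction-corrected variant):

$$\hat\sigma^2_{gca,line} = \frac{MS_L - MS_{E\times L}}{rte},\quad
  \hat\sigma^2_{gca,tester} = \frac{MS_T - MS_{E\times T}}{rle},\quad
  \hat\sigma^2_{sca} = \frac{MS_{SCA} - MS_{E\times SCA}}{re},$$

negatives truncated, $2\hat\sigma^2_{GCA}$ taken as the line + tester sum,
the ratio clamped to [0, 1], and NA when everything is zero. The published
variant this follows pools GCA over the two parent classes; the unmodified
mean-square ratio remains available as `method = "baker_ms"`.

## Base drought-tolerance index

Each component trait is standardized over the indexed population with the
sample (n−1) standard deviation — the denominator is not specified in the
source, and n−1 is the conventional choice — then combined as

$$I = 2 z_{yield} + z_{EPP} - z_{ASI} - z_{PASP} - z_{EASP} - z_{SGC}$$

under drought. The stay-green score exists only on stressed plots, so the
rain-fed index omits that term; this is inferred rather than stated in the
source, which applies "the base index" in both conditions but defines the
score only under stress. The standardization population is all entries
evaluated in the condition (hybrids plus check), matching the published
selection of 26 best and 9 worst from the full 121-entry trial. Ties in the
index break by the yield z-score and then the genotype id, so selections
are deterministic. Published index values were standardized over all 121
entries, whose complete trait data are not printed; the package therefore
checks only ordering plausibility (rank correlation, identical extremes) on
the digitized 35-entry table, never the printed values themselves.

## Heterotic classification

A line joins the heterotic group of the tester with which it has a
*significant negative* SCA effect, provided it also has a significant
positive SCA with another tester and its testcross mean with some
significant-positive tester is at least one standard error above that
tester's grand mean. Reading "the other tester" as "at least one other"
(three testers exist) reproduces all six published assignments exactly,
including the non-classification of lines with one-sided patterns. When
several significant negatives occur (no published case), the most negative
wins and the trace records the ambiguity; when both non-group testers are
significant-positive, the yield gate passes if either clears its bar. In
digitized mode the per-tester SE printed with the grand-mean row is the
gate width; in computed mode it is $\sqrt{MS_{Error}/(lre)}$.

A caveat the tests pin down: the published significance flags cannot all be
reproduced from the printed pooled SCA standard error (174.5) — three
flagged effects (335, 336, 342) sit just inside the 5 % critical value and
one unflagged effect (−446) beyond it, presumably because the source used
cell-specific SEs. The classifier therefore consumes the digitized flags
verbatim, and the consistency test allows exactly that four-element
mismatch set.

## GGE biplots

The genotype × environment mean matrix is environment-centred (no
transformation, no scaling) and decomposed by SVD,

$$y_{ij} - \bar y_{\cdot j} = \lambda_1 \xi_{i1}\eta_{j1}
 + \lambda_2 \xi_{i2}\eta_{j2} + \epsilon_{ij}.$$

Axis signs are fixed by forcing each environment-score vector to a positive
sum (flipping $\xi$ and $\eta$ together), so coordinates are deterministic
across numeric backends. Singular-value partitioning gives genotype
coordinates $\xi\lambda^f$ and environment coordinates $\eta\lambda^{1-f}$
with $f \in \{1, 0, 0.5\}$; the coordinate product reproduces the same
rank-2 approximation in every mode. The source figures attach
"genotype-focused" to the program setting SVP = 2 and "environment-focused"
to SVP = 1 — opposite to the more common naming — so both are exposed by
name and the discrepancy is documented here without guessing intent.

Which-won-where builds the convex hull of the genotype markers; because
centring puts the genotype centroid at the origin, the origin is interior,
sector boundaries are the rays perpendicular to hull edges, and the winner
of a sector is its vertex — provably the genotype maximizing the inner
product with each environment marker, which is invariant to the SVP mode.
Environments exactly on a boundary (1e-12 radians) go to the
counter-clockwise sector. Missing cells are never imputed; the pipeline
restricts to complete subsets and logs exclusions. The
average-environment-coordinate view projects genotype-focused markers onto
the unit mean-environment vector: the projection estimates mean
performance, the perpendicular distance instability, and genotypes are
ranked by distance to the ideal point on the positive axis.

## The synthetic world

`generate_trial()` draws every random effect i.i.d. Gaussian on a latent
scale and then centres it, so true effects live on the same constraint
surface the estimators assume; SCA is doubly centred. Plot values are

$$y = \mu_{cond} + E + R + B + g_{line} + g_{tester} + s
  + (g_{line}{\times}E) + (s{\times}E) + \varepsilon,$$

ordinal scores (plant/ear aspect 1–5, stay-green 1–9) are rounded and
clamped, ears per plant clamped at zero, days to silking derived as
anthesis + interval, and the drought yield mean set to
`drought_yield_ratio` (default 0.523) times the rain-fed mean. Cross-trait
correlation is induced at every effect level through a one-factor loading
structure (guaranteed positive semi-definite); the Gaussian latent scale is
an assumption — the source makes no distributional statement.

Default parameters emulate the target trial: 40 lines × 3 testers, 2
replicates, 3 environments per condition, one open-pollinated check,
lattice-like incomplete blocks of size ≈ √n, and drought/rain-fed trait
means taken from the published condition means. Yield variance components
are loosely calibrated to the published drought mean squares, with one
deliberate exception: the environment variance is set to 2.5 × 10^5
(≈ 500 kg/ha spread between within-condition environment means) rather than
the ≈ 1.4 × 10^6 a naive reconstruction of the printed environment mean
square suggests, because that mean square mixes managed-drought and
terminal-drought regimes that the generator represents as separate
conditions — and environment main effects are removed by every downstream
estimator in any case.

What a green test does and does not establish: the generator reproduces the
covariance *structure* the estimators assume (so recovery tests are
informative about estimator correctness), but it does not emulate spatial
field trend, non-Gaussian trait distributions, genotype-specific drought
sensitivity of secondary traits, or the severe environment heterogeneity of
the real trial. Published quantities that require the undeposited plot data
(ANOVA tables, repeatabilities, CVs, GCA tables, printed index values,
biplot coordinates, the 52.3/58.5/54.9 % reduction statistics) are covered
by property suites and simulation bands, never asserted exactly;
`desk_scale_notes()` lists them.

### Numerical and design choices

- Reproducibility: one master seed; per-component substreams derived
  deterministically, so identical configs are bit-identical.
- Negative variance components truncate to zero, with a warning that the
  pipeline log records.
- The which-won-where noise tolerance: with noise at 5 % of the
  centred-signal variance on a rank-2 fixture, winner agreement with the
  per-environment argmax is ≈ 91 % at the canonical 5 × 4 fixture and
  degrades with more genotypes (≈ 88 % at 8 × 5, ≈ 82 % at 10 × 6) as
  near-ties multiply; the acceptance test runs at the canonical size.
- Percent superiority defaults to the candidate mean as denominator — the
  only convention that reproduces the published 43.7 % — and the rain-fed
  "30 %" claim matches neither convention (32.1 / 47.4 %), so nothing
  asserts it.
- The digitized hybrid-means fixture carries 35 entries, not 36: one of the
  published "worst nine" rows did not survive text extraction (the figure
  entry numbering confirms a single missing row), and inventing it was not
  an option.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(l = 10, t = 3, r = 2, e = 3, seed = 42)
sim <- generate_trial(cfg)
an <- trial_anova(sim$data, "yield", "drought")
vc <- variance_components(an)
repeatability(vc)
ca <- combining_ability(sim$data, "yield", "drought")
ca$baker_proportion
res <- run_pipeline(pipeline_config(generator = cfg, outdir = tempfile(),
                                    seed = 42))
basename(res$files)
```

## Known limitations

No unbalanced-data REML (unbalanced designs are analysed stage-wise through
least-squares means); no diallel or reciprocal analysis; no AMMI; no
spatial adjustment; no biplot confidence regions; figures are renderings of
the coordinate tables, which are the source of truth.
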