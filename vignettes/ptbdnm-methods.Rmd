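---
title: "Methods: de novo mutation burden and developmental consequences in preterm birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo mutation burden and developmental consequences in preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbdnm)
```

## The scientific question

Preterm birth (delivery before 37 completed gestational weeks) has a
substantial but poorly localized genetic component. One candidate mechanism is
the fetal genome itself: de novo mutations — variants present in the newborn
but in neither parent — are dominated by replication errors in the paternal
germline, scale strongly with paternal age, and occasionally disrupt genes
needed for early development. If fetal de novo mutations contribute to preterm
delivery, two things should hold: preterm newborns should carry a heavier de
novo mutation burden than term newborns after paternal age is accounted for,
and the genes those mutations damage should matter specifically for prenatal
(especially early fetal brain) development.

`ptbdnm` implements the full analysis chain for testing both predictions on
trio cohorts (child plus both parents) with called de novo mutations, and
ships a calibrated synthetic cohort generator so every stage can be exercised
and validated without access to any cohort data.

## The burden model and its confounders

The per-genome burden is the count of autosomal de novo mutations. Because
burden rises with paternal age (Pearson r near 0.62 in large trio studies,
i.e. paternal age explains roughly 38% of burden variance), a naive
case/control comparison is confounded whenever parental ages differ between
groups. The package offers the four complementary strategies used in this
literature:

1. **Raw comparison** — a two-sided Wilcoxon rank-sum test of burden between
   preterm and term genomes (`compare_groups()`).
2. **Joint logistic regression** — `preterm ~ z(paternal age) +
   z(maternal age) + z(burden)`, maximum likelihood via IRLS with tolerance
   1e-8 and at most 100 iterations; coefficients are per-SD log-odds and each
   term gets a Wald p-value (`fit_preterm_logistic()`). Suspected separation
   (fitted probabilities at the boundary, or runaway coefficients) is an
   error, not a silent result.
3. **Residualization** — ordinary least squares of burden on paternal (or
   maternal) age; the residuals are the age-corrected burden and are compared
   between groups exactly as the raw counts are (`residualize_burden()`).
4. **Extreme-load inspection** — the top 5% of genomes by burden
   (`extreme_load_subset()`; the `ceiling(0.05 n)`-th largest count is the
   threshold and ties at it are all included), within which the parental age
   distributions of preterm and term subjects are compared.

Replication timing is the other known driver of de novo mutation placement:
`timing_context()` averages a piecewise-constant timing track over a 1 kb
window centered on each mutation (base-weighted; mutations with no annotated
base are excluded), so the two groups' mutational context can be compared.
`stratified_burden()` repeats the group comparison within gestational-age
bins (default [32, 37) and [20, 32) weeks against the >= 37-week term group),
flagging bins with fewer than 5 subjects as underpowered.

### The rank-sum implementation

The Wilcoxon rank-sum test is the workhorse statistic of the whole pipeline,
so its conventions are pinned down rather than inherited: midranks for ties;
the reported statistic is the Mann-Whitney U of the first group; two-sided
tests by default (the sources never state sidedness; one-sided is available
via `alternative`). Exact inference is used when both groups have at most 12
observations — the exact Mann-Whitney distribution for untied data, and
direct enumeration of all label assignments when ties are present (up to 20
total observations, beyond which enumeration is infeasible and the
approximation takes over). Larger groups use the tie-corrected normal
approximation with **no continuity correction**. Two numerical consequences
of that choice are documented by the test suite: the approximate p sits
within about 0.04 of the exact p at group sizes 10-12 (within 0.02 only from
about 15 up), and the two-sided test is mildly anticonservative for a small
set against a large background (measured type-I error ~0.06 at nominal 0.05
for 51 genes against ~1950).

## Deleteriousness filtering and gene sets

Nonsynonymous means missense, nonsense or frameshift. A nonsynonymous
mutation is deleterious if it is a frameshift indel (automatically, since
CADD scores are typically unavailable for them), or if its CADD phred score
is **strictly greater than 20** (roughly the top 1% most deleterious variants
genome-wide). Nonsense mutations are not exempted from the CADD threshold:
only frameshifts are auto-deleterious, which is the literal reading of the
filtering rule this package follows. A missing CADD score on a non-frameshift
mutation conservatively fails the filter. `extract_gene_set()` collects the
unique gene symbols of the deleterious mutations (two hits in one gene yield
one member, mirroring the 112-mutations-to-111-genes arithmetic such filters
produce).

The extracted sets are characterized three ways:

- **Dosage sensitivity** (`compare_intolerance()`): rank-sum comparison of
  the set's copy-number intolerance scores (overall, deletion-specific or
  duplication-specific) against a background. With the default genome
  background, the set's own genes are excluded from the background to avoid
  self-comparison (the sources are silent on this; set-vs-rest is the
  cleaner contrast).
- **Mouse-knockout viability** (`viability_composition()`,
  `viability_enrichment()`): composition over lethal / subviable / viable
  classes (unknowns excluded from the denominator but counted), and a
  two-sided Fisher exact test on the 2x2 lethal-vs-viable table between two
  sets (subviable and unknown genes excluded; an all-zero margin is an
  error).
- **Phenotype-term enrichment** (`phenotype_enrichment()`): one-sided
  hypergeometric over-representation per term with Benjamini-Hochberg FDR
  across the tested terms. This is a deliberately generic,
  "EnrichR-analogous" reimplementation: the combined scores and library
  versions of external enrichment services are not reproducible, so their
  printed FDRs are not targets here.

Gene symbols are matched case-insensitively after whitespace stripping; no
alias resolution is attempted (it would require an external resource).

## Expression propensity

Developmental specificity is quantified on a gene-by-stage expression matrix
of the neocortical transcriptome, stages tagged with epochs: early fetal
(post-conceptional weeks 8-10, 12, 13), later fetal (PCW 16, 17-22, 25-26)
and postnatal (months 4, 10, 12). The stage list is configurable; the default
is the fuller enumeration that includes PCW 25-26 (the source figure legend
and text disagree on this stage; the text's enumeration is used).

Two views are computed:

- **Trajectories** (`normalize_stages()` + `trajectory()`): per-gene z-scores
  across stages (sample SD; zero-variance genes flagged and zeroed; min-max
  scaling available via the `normalization` config key), then stage-wise mean
  and SEM over a gene set. Per-gene z-scoring is chosen because the contrast
  of interest is each gene's temporal profile, not its absolute level.
- **Propensity fold change** (`beta_score()`, `beta_scores()`): for each gene,
  `beta` = mean raw expression over the early-fetal stages divided by mean
  raw expression over the postnatal stages. Raw values are used by
  definition; `beta` is per-gene scale-invariant, and undefined (excluded,
  counted) when the postnatal mean is zero. `compare_beta()` contrasts two
  sets' per-gene `beta` collections by rank-sum — a two-group comparison, per
  the figure this mirrors — and reports each group's median and fraction
  above 1 alongside, which covers the in-text "beta > 1" style of statement.

## CNV-region novelty

Copy-number-variable regions from a preterm cohort are classified against a
reference collection of structural variants seen in non-diseased individuals
(DGV-style). A deletion query is **shared** if at least 80% of its bases are
covered by the union of reference deletion records, otherwise **novel**;
duplications are treated the same way against reference duplications only.
Reading "can also be found in the reference" as coverage by the union (rather
than by any single record) is the only interpretation invariant to how the
reference happens to split its records, and is checked by exactly that
property test. Coordinates are BED-convention 0-based half-open throughout
the interval code (mutation positions are 1-based VCF-convention; conversion
happens only at I/O boundaries). Genes belong to a region when they overlap
it by at least 1 bp. The interval algebra itself is delegated to IRanges and
verified against a per-base bitmap oracle.

## The synthetic world

The generator's defaults are the study conditions, fixed once:

| quantity | default | provenance |
|---|---|---|
| trios / preterm | 816 / 292 | cohort composition |
| paternal age | 33.5 +/- 5.8 y, truncated at 18 | printed term-group moments |
| maternal age | 31.4 +/- 4.9 y, correlation 0.7 with paternal | printed moments; correlation is a realism choice |
| term burden mean `a` | 43.86 | printed mean |
| preterm shift `delta` | 2.22 | 46.08 - 43.86 |
| age slope `b` | solved from r = 0.62 | `b = sqrt(E[lambda] r^2/(1-r^2))/sigma` |
| coding fraction | 1/50 | ~1 exonic mutation per ~50 |
| coding split | 0.55/0.07/0.10/0.28 (mis/non/frame/syn) | synonymous share set so nonsynonymous yield matches 339/(524 x 43.86) ~ 1.5% |
| CADD > 20 fraction | 0.21 | with auto-deleterious frameshifts gives deleterious/nonsynonymous ~ 0.32, matching 51/169 and 112/339 |
| paternal origin | 0.80 | printed share |
| gestational age | mixture: term 39.1 +/- 1.2, preterm 33.1 +/- 2.9, clamped at 22.7 | printed modes and minimum; the mixture shape and SDs are our choice |

Burden noise is Poisson — counts of rare per-genome events, and the printed
mean/variance scale is consistent with it — with rate
`a + b (age - mean age) + delta * preterm`, floored at 1 (a nonpositive rate
is an error instructing recalibration). The preterm effect is additive, the
simplest form calibratable to the two printed means. One global seed drives
everything; each generator derives its stream by a fixed documented offset,
so the full bundle is byte-reproducible.

The planted structure downstream analyses should find: deleterious mutations
in preterm genomes hit a designated 51-gene causal set with probability 0.5
(an extension of the generator needed for the gene-set stage to have signal);
causal genes carry a +1 SD deletion-intolerance shift (propagating attenuated
into the overall CNV score and leaving duplication intolerance unshifted) and
3x lethal odds in the viability multinomial (background proportions
410/198/1143 with 30% of genes scored); causal and novel-CNV genes get
monotone-decreasing log-expression across stages (0.15 per stage step,
log-normal noise SD 0.3, so mean `beta` ~ 2.5 for biased genes and ~1.03 for
flat ones); and the interval bundle is constructed with exact shared/novel
ground truth (85-100% vs 10-70% coverage, references split in two to exercise
the union), 64 of 74 deletions and 56 of 57 duplications shared.

What the generator does **not** emulate: mutational signatures and sequence
context, family structure beyond independent trios, overdispersion of burden
beyond Poisson, locus-specific CNV recurrence, and expression replicate
structure (one pre-aggregated column per stage). A green test therefore
establishes that the statistical machinery is correct and calibrated on a
world with the stated moments — not that real cohorts satisfy the Poisson or
log-normal assumptions. One concrete consequence documented by the acceptance
suite: in the stated Poisson world the implied per-SD logistic burden
coefficient is `log(1 + delta/lambda) * sd(burden) ~ 0.41`, noticeably larger
than the 0.27 reported on the real cohort, which is what one expects if real
burden is overdispersed relative to Poisson.

## Numerical and design choices

- All tests two-sided unless asked otherwise; the conservative default where
  the sources do not state sidedness.
- The preterm boundary is strict (`< 37.0` weeks; 37.0 exactly is term), the
  CADD boundary is strict (`> 20`), the coverage boundary is inclusive
  (`>= 0.8`, "at least 80%"), and the extreme-load quantile is inclusive of
  threshold ties — each following the wording of the rule it implements.
- Gestational ages outside [20, 45] weeks are rejected at read time; a
  gestational-age column may be given in days (flagged by the column name
  `gestational_age_days`) and is converted by division by 7.
- Residualization uses plain OLS; residuals sum to zero within 1e-9 per
  subject, and the group comparison of residuals is invariant to adding any
  multiple of age to the counts.
- Unknown consequence labels degrade to `"other"` with a warning; unmapped
  structural-variant types are dropped and counted. Both keep partially
  annotated inputs usable without silently inventing categories.
- The logistic fit treats non-convergence and separation as errors naming the
  condition, never as results.
- Stages with missing inputs are recorded as `skipped` in the run summary
  rather than failing the run; every threshold actually used is echoed in the
  summary so a run is auditable.

## Known limitations

- The exact supplementary tables of the motivating study are not publicly
  retrievable, so the package validates against the calibrated synthetic
  world rather than against per-subject published counts; the readers accept
  such tables in plain TSV if a user has them.
- Enrichment is hypergeometric + BH only; combined-score rankings from
  external enrichment services will differ.
- No reciprocal-overlap mode for interval comparison (one-directional
  query-coverage only, as in the 80% rule), and no CNV calling: region lists
  are inputs.
- The rank-sum normal approximation is anticonservative by about one
  percentage point of type-I error for very unbalanced comparisons; exact
  inference is automatic only for small groups.
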