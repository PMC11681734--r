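---
title: "Comparing blood responses to endotoxin across sensitive and resilient species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing blood responses to endotoxin across sensitive and resilient species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlps)
```

## The scientific problem

Mammalian species differ by more than five orders of magnitude in their
sensitivity to bacterial lipopolysaccharide (LPS, endotoxin): rodents and
several non-human primates tolerate milligrams per kilogram, while humans
develop shock at nanogram doses. `xlps` implements a comparative pipeline
for asking where that difference is visible in blood. It compares
whole-blood leukocyte transcriptomes and plasma proteomes between a
*resilient* group of species (mouse, rat, rhesus macaque, baboon; in vivo
lethal dose above 1 mg/kg) and a *sensitive* group (rabbit, pig, cow,
sheep, chimpanzee, human), under an ex vivo design in which whole blood
from 4–5 individuals per species is incubated with 0, 10, 100 or
1000 ng/mL LPS for 2, 6 or 24 h.

The pipeline answers four questions:

1. Which genes differ between the groups **at baseline** (no LPS, earliest
   time point)?
2. Which genes **respond to LPS differently** in the two groups?
3. Which genes are **completely divergent** — no overlap at all between the
   individuals of the two groups?
4. Which plasma proteins **discriminate** the groups?

## Ortholog-space translation

Cross-species comparison requires a shared gene space. Every species'
gene abundances (TPM) are translated onto human orthologs using a
redistribution rule over the many-to-many orthology relation: within a
connected component of the bipartite species-gene/human-gene graph holding
*m* species genes and *n* human genes, each human gene receives the sum of
the *m* species-gene abundances divided by *n*. Components are used because
they are the only partition of a many-to-many relation under which "the m
genes" and "the n orthologs" are simultaneously well defined; a
per-human-gene reading would count a shared species gene more than once and
violate mass conservation. Human genes with no component in a species are
carried as explicitly missing for that species' samples, and the screens
below consume that missingness directly.

Translation operates on the TPM scale (the rule is stated on abundances);
the log2 transform `log2(TPM + 1)` is applied afterwards for all
distributional analyses. The pseudocount of 1 TPM is configurable; 1 is the
common choice that bounds the transform at zero.

```{r translate-example}
map <- ortholog_map(data.frame(
  species_gene_id = c("a", "a", "b", "b"),
  human_gene_id   = c("H1", "H2", "H1", "H2")), species = "mouse")
expr <- matrix(c(4, 6), 2, 1, dimnames = list(c("a", "b"), "s1"))
translate_expression(expr, map, c("H1", "H2", "H3"))$values
```

## The blocked moderated group test

Baseline differences between the groups are tested per gene with the
sensitive/resilient contrast as a fixed effect and species as a random
effect, since the contrast lives between species sets and individuals are
nested in species. The implementation follows the consensus-correlation
approach rather than a per-gene mixed-model fit:

1. **Consensus intra-block correlation.** For each gene observed in all
   samples, the intraclass correlation of the residuals (after removing
   group means) across species blocks is computed from the between/within
   mean squares. The per-gene values are averaged on the Fisher-z scale
   with 15% trimming. Because the per-gene ICC is a fixed function of an
   F(b−g, N−b) pivot under zero true correlation, the trimmed average has a
   known negative null expectation; this is computed by quadrature and
   subtracted, otherwise block-mean variances are understated and every t
   statistic is slightly inflated (we measured a null p<0.05 rate of 0.057
   instead of 0.05 before the correction).
2. **GLS per gene.** Each gene is fit by generalized least squares under a
   compound-symmetry covariance built from the consensus correlation,
   pattern-wise over missingness patterns so the whitening is computed once
   per pattern.
3. **Empirical-Bayes moderation.** Residual variances are shrunk toward a
   pooled prior whose degrees of freedom and scale are estimated by
   matching moments of the log-variance distribution under the scaled-F
   model (numerically identical to the standard moderated-t hyperparameter
   fit; our implementation is cross-checked against limma's in the test
   suite). The moderated t gains the prior degrees of freedom, capped at
   the pooled residual degrees of freedom.
4. **Multiple testing.** Benjamini–Hochberg step-up FDR across all genes
   with a fit; a gene is called significant when its fold difference is at
   least 2 (|log2 fc| ≥ 1) and FDR ≤ 0.05.

Genes whose missingness leaves fewer than two species in either group are
excluded with a recorded reason rather than silently dropped. Quantile
normalization (mean-of-sorted-columns reference, per-rank interpolation for
columns with missing entries, ties at their mean quantile) is applied to
the log2 matrix before the baseline test; fold changes are deliberately
*not* computed on normalized values (next section).

"Baseline" is the unstimulated (dose 0) samples at the earliest time point
— the closest available estimate of the resting leukocyte state. Both the
baseline time and the blocking unit (`species` vs `individual`) are
configurable in `de_config()`.

## LPS response and the between-group difference

The response of a gene in one individual is the paired log2 fold change
`log2((TPM_dose + 1)/(TPM_0 + 1))` between that individual's stimulated
and unstimulated samples at the same time point. Pairing on the individual
removes the individual-level intercept exactly, which is what makes the
paired design more powerful than an unpaired comparison. Fold changes are
computed on raw TPM (plus pseudocount), not on quantile-normalized values:
the response is defined as a within-individual TPM ratio, while
normalization is reserved for cross-sample group comparisons.

Two tests consume these records:

* **Per species**, a moderated one-sample t across individuals (≥3 paired
  individuals required), significant at fold change ≥ 2 and FDR ≤ 0.05.
* **Between groups**, the blocked moderated machinery above applied to the
  per-individual fold changes with species as blocks, significant at a
  difference in fold changes ≥ 1.5 (interpreted multiplicatively:
  |Δ mean log2 fc| ≥ log2 1.5) and FDR ≤ 0.05.

The 10 ng/mL dose is the default analysis dose; 100 and 1000 ng/mL are
supported but secondary, since dose escalation has a consistent but minimal
effect on the planted (and observed) responses.

## Complete-separation screens

A gene is *completely divergent* when every non-missing value in one group
strictly exceeds every non-missing value in the other. The class expected
to be higher is decided by the group mean of non-missing values — the
simplest consistent statistic, recorded in the output for audit. One
missing individual is tolerated in the *higher* class only, accommodating
incomplete genome annotations; a missing value in the lower class is never
tolerated because it cannot certify non-overlap. Ties across classes break
separation (a conservative reading of "no overlap"). The same screen runs
on baseline log2 expression and on per-individual response fold changes.

Ranked gene lists order separated genes by the absolute difference of
group means (with a deterministic lexicographic tie-break); for response
screens the list is additionally restricted to genes significant in the
between-group test, matching how the headline response lists are filtered,
while the baseline divergence list applies no FDR filter. Both orders are
supported through `require_significant`.

## The proteomics cascade

Plasma (or HDL) proteomes arrive as protein × species log2 LFQ tables with
missing values meaning "not detected". Discriminating proteins are captured
by three mutually exclusive tiers applied in strict order:

1. **ANOVA tier** — proteins with ≥2 detected values per group get a
   two-group ANOVA p-value; p < 0.05 captures them. The threshold is the
   raw p-value by design (an initial capture, not an inference), so no
   multiple-testing correction is applied here. A protein that received a
   p-value exits the cascade whether captured or not. Zero within-group
   variance with unequal means is treated as maximally significant; with
   equal means it is uninformative.
2. **Fold-change tier** — proteins without a p-value but detected in both
   groups and in ≥4 species total are captured when the difference of group
   means of detected log2 values is ≥3. "Occurrences" is read as the number
   of species with a detected value, the only replicate unit available in
   species-pooled plasma data.
3. **Presence tier** — proteins detected in exactly one group are captured
   when detected in ≥3 species of that group.

Every protein ends in exactly one of {anova, foldchange, presence, none};
the cascade output records the tier statistic and, for presence-tier
proteins, the detected group.

## What the synthetic generator emulates

`simulate_transcriptome()` and `simulate_proteome()` generate full studies
with known ground truth at the study design: 10 species (4 resilient, 6
sensitive), 5 individuals each, the full dose × time grid.

* Gene-level means are Uniform(2, 10) in log2 TPM; per-sample noise is
  Normal(0, 0.5); each individual carries a Normal(0, 0.3) intercept shared
  across all of its samples, so pairing is informative.
* The m:n orthology family structure is sampled **once** and shared across
  species (gene families are conserved across mammals), with weights
  1:1 = 0.80, 2:1 = 0.06, 1:2 = 0.06, 2:3 = 0.03 chosen to mirror mammal
  orthology, where the large majority of mapped genes are one-to-one.
  Annotation dropout ("missing", 0.05) is applied per species per family,
  which feeds the one-missing tolerance rule. Sampling the m:n structure
  independently per species was rejected: it induces per-species aggregation
  offsets that act as heavy-tailed species random effects and destroy the
  calibration of any test that assumes exchangeable species — an artefact of
  the inversion, not a feature of real orthology.
* Planted baseline effects (default 10% of genes at ±1.5 log2, favouring
  the sensitive group with probability 0.95) are added to one group's
  samples. Planted responses (10% at 2 log2) scale with a saturating dose
  factor (0.8/0.9/1.0 at 10/100/1000 ng/mL — escalation is consistent but
  minimal) and peak at 6 h (time factors 0.7/1.0/0.5). Planted group
  response differences (5% at 1.5 log2) are responses present in one group
  only, favouring the resilient group with probability 0.9. The three
  planted sets are disjoint.
* Because the translation rule spreads a component's abundance over all its
  human genes, a planted effect propagates to family partners. The ground
  truth therefore also records these *linked* genes; recovery is measured
  as recall over planted genes and false discoveries over genes carrying no
  planted signal at all. Counting a genuinely-affected family partner as a
  false positive would mis-state the error rate.
* The proteome generator plants ANOVA-tier proteins as fully detected group
  shifts of 3 log2, fold-change-tier proteins as ±6 log2 group differences
  detected in one species of one group and all of the other (ineligible for
  the ANOVA tier, ≥4 occurrences), and presence-tier proteins as detected
  in every species of exactly one group.

What the generator does **not** emulate: sequencing depth and count noise
(TPM is modelled directly as log-normal), leukocyte composition differences
between species, correlated gene programs (genes are independent given the
individual intercept), time-course autocorrelation, and real orthology
topologies more complex than 2:3. Passing recovery tests therefore
demonstrate the statistical machinery under the design's assumptions, not
performance on any real dataset.

## Numerical choices and degenerate inputs

* Quantile normalization requires ≥2 non-missing values per column, refuses
  otherwise, and handles ties by assigning the reference value at the mean
  quantile of the tied block.
* The consensus correlation is clamped to keep the compound-symmetry
  covariance positive definite; with too few complete genes it falls back
  to 0 with a warning.
* Zero residual variances are excluded from the hyperparameter fit and
  receive the prior variance; constant genes get t = 0 rather than NaN.
* When the log-variance spread is no larger than its sampling noise, the
  prior degrees of freedom are infinite and the prior scale is the mean
  sample variance; total df is capped at the pooled residual df.
* All rankings break ties lexicographically by gene id; all output files
  are byte-deterministic functions of the configuration seed.

## Problem sizes used in the checks

The test suite exercises translation against a brute-force oracle on 1000+
random maps, the separation screen against an all-pairs oracle on 1200+
gene instances, null calibration on 20 simulated studies of 2000 genes
(pooled binomial check at α = 0.05 and 0.01), baseline recovery at 2000
genes with 10% planted effects, response recovery over 20 seeds at 400
genes, and the proteomics cascade at the default 300-protein table. These
sizes were chosen so the whole suite runs in a few minutes on one CPU while
keeping every binomial tolerance meaningful.

## Known limitations

* The consensus-correlation GLS is not a full REML mixed model; it is the
  standard (and deliberate) approximation that shares one correlation
  across genes.
* With only 4 + 6 species, the species-level random effect is estimated
  from few blocks; the test refuses designs with fewer than two species per
  group rather than pretending to estimate it.
* Complete-separation counts are extremely sensitive to effect size: at the
  default planted effects, full separation of 30 vs 20 individuals is rare,
  so end-to-end runs report honest near-zero divergent-gene counts while
  the screen's correctness is established against oracles.
* Ortholog translation distorts genes without 1:1 conservation (the sum/n
  rule averages family members); the linked-gene bookkeeping quantifies
  this in simulation but nothing can recover per-gene resolution inside a
  family.
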