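---
title: "Methods: burden testing and polygenic scoring in FH exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden testing and polygenic scoring in FH exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhburden)
```

## The problem

Familial hypercholesterolaemia (FH) is an autosomal-dominant disorder of
LDL-cholesterol clearance. Most molecularly explained cases carry a
mutation in *LDLR*, *APOB* or *PCSK9* (with a recessive form in
*LDLRAP1*), but a substantial fraction of clinically definite patients
have no detectable mutation in these genes. Two competing explanations
must be separated before searching for new genes:

1. **Missed known mutations** — detectable by re-screening exomes
   against a curated catalogue of pathogenic variants (the *Tier-1*
   screen).
2. **Polygenic hypercholesterolaemia** — the cumulative effect of
   common LDL-C-raising alleles, detectable with a weighted SNP score:
   a patient in the top decile of a healthy population's score
   distribution plausibly needs no monogenic explanation.

Only after removing both groups is a gene-discovery comparison
meaningful: the remaining cases are tested gene by gene for an excess
of rare, protein-altering variants against a large control cohort.
`fhburden` implements this cascade end to end.

## Variant filtering

Variants are flagged from an external annotation table (consequence
prediction is out of scope; any VEP/ANNOVAR-style annotation exported
to TSV works):

* **rare** — maximum allele frequency over all reference panels
  strictly below 0.5% (configurable);
* **novel** — frequency 0 in every panel; the novel set is by
  construction a subset of the rare set;
* **functional** — consequence in {missense, stop gain, stop loss,
  frameshift insertion/deletion, splice site}; synonymous, intronic
  and unclassified calls are dropped.

Three conventions deserve justification. First, panel frequencies are
aggregated by the **maximum**: a variant common in any one panel is not
rare, which is the conservative choice when panels differ in ancestry
composition. Second, novelty is judged against reference panels only —
presence in the study's own controls does *not* revoke novelty, because
control carriers enter the analysis through the burden counts
themselves; revoking novelty would double-count that evidence. Third,
thresholds are strict inequalities (a frequency of exactly 0.5% is not
rare), matching the "below/above" phrasing conventions throughout.

The counting unit everywhere is the **carrier event**: one sample
carrying one qualifying variant in one gene. A variant seen in two
cases contributes two events; a sample with two qualifying variants in
a gene contributes two events. Zygosity is collapsed to het/hom and
does not multiply counts.

## Tier-1 screening

Case calls are matched against the catalogue primarily by normalized
coordinate key (`chrom:pos:ref:alt` after trimming shared suffix then
prefix), with HGVS string equality as a fallback for entries whose
coordinates drift between annotation sources. Reference-free
normalization handles padded representations of one event; fully
left-aligning an indel inside a repeat run would require the reference
sequence and is deliberately not attempted — catalogue and calls are
expected to come from the same reference build.

Dominant genes (*LDLR*, *APOB*, *PCSK9*) are explained by a single
`known_fh` match. *LDLRAP1* follows a recessive model: a homozygous
match or two distinct heterozygous matches explain a sample; a single
heterozygous hit is reported but the sample stays in the cohort.
Catalogue entries marked `unknown_effect` (e.g. novel *APOB* variants
whose pathogenicity is untested) are reported and never exclusionary.

## The LDL-C gene score

The score is a weighted sum of effect-allele dosages over 12 LDL-C
GWAS SNPs plus a fixed APOE diplotype term:

$$S = \sum_{i=1}^{12} w_i \, d_i + a(\varepsilon), \qquad d_i \in \{0,1,2\}$$

with the APOE table
ε2ε2 = −0.9, ε2ε3 = −0.4, ε2ε4 = −0.2, ε3ε3 = 0, ε3ε4 = 0.1,
ε4ε4 = 0.2. The diplotype can be supplied directly or derived from
rs429358/rs7412 genotypes; the ambiguous double heterozygote resolves
to ε2/ε4, the only phase assignment that does not imply an ε1 allele.
Dosage weighting (rather than carrier counting) follows the standard
construction of weighted allele scores.

A sample missing any of the 12 SNPs or APOE is **unscored** — never
imputed — and an unscored sample is never excluded as polygenic.
Classification is strict: `polygenic` requires a score strictly above
the cutoff. The default cutoff 1.16 is the healthy-population
top-decile boundary; 1.08 (the 9th decile) is a documented, less
stringent alternative, settable via `classify_polygenic(cutoff =)`.

The published GWAS-consortium weights are not redistributed with the
package: the shipped 12-SNP table is marked `provenance = "synthetic"`
and real analyses must supply their own weights TSV.

Group comparisons (healthy controls vs mutation-positive vs
mutation-negative) use pairwise Welch two-sample *t* tests — the
unequal-variance form, appropriate with group sizes as lopsided as
3020 vs 21 — plus a one-way ANOVA across groups, both delegated to
base R (`t.test`, `lm`/`anova`).

## The burden test

For one gene, pool the qualifying carrier events of both groups:
$n = k_{case} + k_{control}$ events, of which $k_{case}$ landed in
cases. Under the null that qualifying events are exchangeable across
the cohort, each event falls in a case with probability
$\pi = N_{case}/(N_{case}+N_{control})$, and the evidence for case
excess is the one-sided upper binomial tail

$$p = P(X \ge k_{case}), \qquad X \sim \mathrm{Bin}(n, \pi).$$

With 71 cases and 1926 controls, $\pi = 71/1997 \approx 0.0356$; the
count pairs (3,2), (2,0), (3,4) and (2,1) give p-values 4.3×10⁻⁴,
1.3×10⁻³, 1.4×10⁻³ and 3.7×10⁻³ — the (2,0) case is simply $\pi^2$.
The tail is computed by `stats::pbinom` and verified in the test suite
against an independent term-by-term summation oracle to 10⁻¹²
relative error for all event totals up to 50.

The discovery scan applies three gene-level filters before testing:

* genes with **more than four** qualifying control events are
  excluded (with FH prevalence 1/500, a 1926-control cohort is
  expected to contain ~4 affected individuals, so a handful of control
  carriers cannot rule a gene out, but many can);
* genes on the X chromosome are excluded (case/control sex
  composition unknown; Y and mitochondrial labels are excluded by
  default too, configurable);
* genes with no case events are reported as untested.

Flagging uses a strict `p < 4×10⁻³` threshold, deliberately
**uncorrected** for multiple testing: the flag marks genes for
follow-up, not exome-wide significance claims. A Bonferroni column
over the tested genes is emitted for information. Candidate-list mode
(`run_gene_list_burden`) pools counts across a configured gene set
into one test and additionally tests each listed gene, with no
control-count or chromosome filters — a candidate list is tested as
given.

Because the test conditions on pooled event totals and the counts are
small and discrete, its realised type-I error is below the nominal
level; the calibration test demonstrates this on null simulations
rather than assuming it.

## The synthetic cohort generator

No patient-level data ships with the package; the generator produces
cohorts with the statistical structure the analysis assumes, and a
truth table for every planted signal.

* **Cohort sizes** default to 125 cases / 1926 controls, the study
  design this pipeline targets.
* **Qualifying variation**: per (sample, gene), at most one novel
  functional carrier event (Bernoulli), with per-gene background rates
  log-spaced over 5×10⁻⁵–2×10⁻³ — i.e. roughly 0.1–4 expected control
  events per gene, the regime the control-count filter operates in.
  Case enrichment is a per-gene rate multiplier. Low-rate common
  missense and novel synonymous background calls are added so the
  frequency and consequence filters have real work.
* **Tier-1 spikes**: 25 cases receive a dominant catalogue mutation.
* **Scores**: 12 independent SNPs (binomial dosages) plus APOE
  haplotypes drawn at frequencies (ε2, ε3, ε4) = (0.08, 0.77, 0.15).
  The weight scale is set in closed form so the analytic population
  mean is 0.90; the frequency spread was chosen once so the simulated
  90th percentile sits at ≈1.16, reproducing the published mean and
  top-decile cutoff of the healthy comparison population. By default
  29% of mutation-negative cases (29 of 100) are planted strictly
  above the cutoff and 2 spiked cases are additionally planted high,
  reproducing the 25 + 29 exclusion arithmetic (31 high scores, 2 of
  them mutation carriers); 16 of 125 cases are rendered unscorable by
  dropping one SNP genotype, mirroring the realistic rate of
  DNA-quality failures. Planting uses rejection sampling conditional
  on the cutoff, so planted fractions are exact by construction.
* **Not emulated**: linkage disequilibrium between score SNPs,
  realistic site-frequency spectra, sequencing error, relatedness.
  Passing tests therefore validate the *arithmetic and logic* of the
  pipeline under its own model assumptions, not robustness to
  artefacts of real sequencing data.

```{r example}
sim <- simulate_cohort(sim_config(seed = 7))
report <- run_pipeline(sim$cohort, sim$config$catalogue,
                       sim$genotypes, sim$config$score_model$snps,
                       sim$apoe)
report
```

## Numerical and design choices

* All positions are 1-based (VCF convention); multi-allelic records
  are decomposed into one variant per ALT allele, and decomposition
  conserves the number of ALT-carrying genotypes.
* Duplicate call records for one (sample, variant) collapse with hom
  taking precedence over het.
* Burden output is sorted by ascending p then gene symbol; excluded
  genes follow, so reports are byte-identical across reruns.
* p-values are displayed at 2 significant figures alongside full
  precision.
* The empirical control 90th percentile uses the default quantile
  definition (type 7); the decile property is asserted within two
  binomial standard errors, not exactly, because the score
  distribution is discrete at the boundary.
* Test problem sizes — 200 replicate null scans of a 500-gene panel
  at 71 vs 1926 samples for calibration, 10⁶ draws for distribution
  checks during development — were chosen as the smallest sizes at
  which the binomial standard errors are decisively smaller than the
  effects asserted.

## Limitations

The burden test treats carrier events as exchangeable and ignores
per-gene mutability differences; a highly polymorphic gene dilutes its
own signal (the reason the filters exist). The Tier-1 screen is only
as good as the supplied catalogue, and copy-number variation is out of
scope entirely. The score model's independence assumption makes the
generator unsuitable for studying LD-aware scoring. None of the
shipped example tables (weights, catalogue) are clinical resources.
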