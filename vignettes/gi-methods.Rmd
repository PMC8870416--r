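---
title: "Genomic instability scoring and its validation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic instability scoring and its validation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdgi)
```

## The problem

Tumors deficient in homologous recombination repair (HRR) accumulate a
characteristic burden of copy-number change and loss of heterozygosity
(LOH), and that burden - rather than any single mutation - is what
predicts response to DNA-damaging therapy in many gynecological
cancers.  `hrdgi` implements an in-house style genomic instability (GI)
pipeline for targeted-panel sequencing: it starts from segmented
copy-number profiles (the output of an external segmentation tool such
as a cnvkit-style caller, which this package deliberately does not
re-implement), a backbone of common SNPs genotyped in a small panel of
normals, tumor purity estimates and a curated variant table, and ends
in a per-sample vector of named instability parameters, a mutational
HRD flag, and cohort-level association statistics against trial
response groupings and survival.

## The event-calling model

A segment with log2 depth ratio $r$ from a sample of purity $p$ is
modelled as a two-component mixture of tumor and diploid normal cells:
the observed linear ratio is $p\,n_t/2 + (1-p)$ for tumor copy number
$n_t$.  `purity_adjust()` inverts this,

$$ n_t = \max\!\left(0, \frac{2 \cdot 2^{r} - 2(1-p)}{p}\right), $$

so a neutral signal maps to $n_t = 2$ at every purity and the
adjustment is the identity scaling $2\cdot 2^r$ in a pure sample.  The
purity is an input: how it is estimated (pathology review, variant
allele fractions, dedicated tools) is outside the package's scope.

`call_events()` then applies a fixed cascade, each step configurable
but shipped with the defaults used throughout:

1. segments carrying a segmentation p-value above **0.001** are
   dropped (segments without a p-value pass - absence of an annotation
   should not silently delete data);
2. surviving segments are classified as gains at adjusted copy number
   $\ge 2.5$ and losses at $\le 1.5$, the half-integer midpoints
   between the diploid state and a single-copy change;
3. adjacent same-state events with zero gap merge, because the
   minimum-length filter is aimed at segmentation artifacts and a
   fragmented biological event should count once;
4. events shorter than **1 Mb** are removed as probable technical
   artifacts.

Merging before length-filtering is deliberate: two 0.6 Mb fragments of
one loss survive as a single 1.2 Mb event, whereas filtering first
would delete both.

`baf_borderline_filter()` removes events whose mean B-allele frequency
(BAF) lies strictly inside the open interval **(0.3, 0.7)**: such
events show no allelic imbalance and are treated as borderline calls.
The bounds are exclusive, so a BAF of exactly 0.3 still counts as
imbalanced, and events with no BAF annotation are kept.  Both the
filtered and unfiltered event tiers feed the GI vector, so the filter
can only re-rank, never fabricate, signal.

## LOH detection

Constitutive heterozygosity is approximated from the panel of normals:
a SNP enters the mask when at least **3 of the 5** controls are
heterozygous and no control genotype is missing at the site - a
majority rule that tolerates single-control genotyping noise without
admitting sites whose population heterozygosity is doubtful.

Within each evaluation interval (the sample's own copy-number
segments, plus 10 Mb tiles over any genomic span not covered by a
segment, so copy-neutral LOH in unsegmented regions stays detectable)
the tumor BAFs at masked SNPs are first *folded* about one half,
$b^\ast = \max(b, 1-b)$, and the interval is called LOH when it
contains at least **10** informative SNPs and the median folded BAF
falls outside the (0.3, 0.7) band.  Folding matters: the parental
allele lost at any one SNP is arbitrary, so the raw BAFs of a genuine
LOH tract scatter symmetrically toward 0 *and* 1 and their unfolded
median sits near 0.5, indistinguishable from balance.  On the folded
scale the same band separates the two cases cleanly, and the median
(rather than the mean) keeps single mis-genotyped SNPs from moving the
call.

The band has a known purity sensitivity: a clonal one-copy loss at
purity $p$ has expected major-allele BAF $(p + (1-p))/(p + 2(1-p))$,
which falls back inside the band below roughly $p = 0.46$.  This is a
property of the method being modelled, not a defect of the
implementation, and the simulator reproduces it exactly (a fully
clonal LOH tract at purity 0.4 has BAF about 0.625 and is correctly
not called).  Called intervals merge when adjacent and pass the same
1 Mb artifact filter as copy-number events.  Long-LOH span statistics
use strict thresholds at **10 Mb** and **15 Mb**.

## The GI parameter vector

`compute_gi_vector()` emits 26 named, non-negative parameters per
sample (see `gi_parameter_dictionary()`): event count, mean event
length, altered length and percent of genome altered; the same four on
the BAF-filtered tier; the gain breakdown on both tiers; the loss
breakdown; and LOH count/length/percent overall and above each long-LOH
threshold.  Percentages divide by the total length of the configured
autosomal genome model, not by a covered/callable length - the
denominator is therefore stable across samples and stated per run.
Mean event length on a sample with no events is defined as 0 so cohort
tables remain complete and sortable.  Sex chromosomes are excluded
from the default genome model (and hence all denominators) because
BAF-based LOH logic is not meaningful on a hemizygous X in mixed-sex
panels of normals; the chromosome table is configuration
(`read_genome_sizes()`), not code.

For cohort analyses, `categorize()` splits each parameter at the
cohort median (ties at the cut go low) or into quartiles with linearly
interpolated cuts (`stats::quantile()` type 7, right-closed).  The
quantile definition is exposed because group membership near a cut
depends on it.

## Mutational HRD status

A variant qualifies when it clears the technical gates - coverage
$\ge$ **100x** (inclusive) and VAF $>$ **5%** (strict) - and is either
classified P/LP, or is a VUS with an upstream pathogenic prediction,
or is a VUS called pathogenic by *both* SIFT and PolyPhen.  A sample
is HRD-positive when at least one qualifying variant lands in the
configured HRR gene set; the shipped default is the 27 HRR-pathway
members of the 35-gene panel, excluding the mismatch-repair genes,
TP53, CCNE1, EMSY and PTEN (PTEN's pathway membership is debatable and
its alterations concentrate in endometrial disease; users studying it
can simply add it to the set).  Simple gene-level calls
(`gene_cn_call()`) use the length-weighted mean adjusted copy number
over each gene interval with amplification at $\ge 5$ and deletion at
$\le 1$ copies.

## The clinical layer

Response groupings follow the trial conventions: ORR groups CR/PR
against SD/PD; CBR additionally credits SD lasting *more than* 6
months (exactly 6.0 is negative); long-term responders (LTR) have PFS
at least twice the cohort's Kaplan-Meier median PFS, computed from the
cohort itself unless pinned to a published value.  Not-evaluable
patients keep their own category: they stay in intention-to-treat
denominators for rates but are excluded from two-group comparisons.

Rates carry exact Clopper-Pearson intervals (`stats::binom.test`).
Group comparisons use the two-sided Wilcoxon rank-sum test - exact by
enumeration when the pooled sample is at most 12 and tie-free, else
the tie- and continuity-corrected normal approximation - with Cohen's
d (pooled SD) as the effect size.  Survival uses the product-limit
estimator with log-log confidence intervals and the standard log-rank
test (`survival::survfit`/`survdiff`).  `association_scan()` crosses
every GI parameter with every grouping and, for survival, with its own
median split, reporting raw p values alongside Benjamini-Hochberg
adjusted ones in a separate column; nothing is filtered on
significance, and degenerate pairs are skipped with a logged message.

## The synthetic validation cohort

No patient-level data ship with the package, so validation rests on a
generative model (`simulation_config()`, `simulate_cohort()`) whose
defaults define the conditions every recovery and calibration result
refers to:

* genome: the autosomal model at 1/10 scale with one SNP per 20 kb -
  the same SNP density as roughly 147,000 backbone SNPs on a full
  genome, at a size that keeps a 200-patient cohort under half a
  minute on a desktop;
* per-patient instability $\theta \sim U(0,1)$ driving
  $K \sim \text{Poisson}(2 + 18\theta)$ events with log-normal lengths
  (median 8 Mb, $\sigma_{\log} = 0.8$), typed gain/loss/cnLOH with
  probability 0.4/0.4/0.2;
* purity $\sim U(0.3, 0.9)$, diluting log2 ratios and BAFs through
  exactly the mixture model the caller inverts; Gaussian noise with SD
  0.03 on BAF and 0.1 on log2;
* response Bernoulli with logit $-2.2 + 1.0\,z$ on the standardized
  event count (about a 10% base rate, matching early-phase reality),
  PFS exponential with log hazard $\log(1/4.5) - 0.5\,z$ months,
  uniform censoring on (0, 24) months, 7% not-evaluable;
* a qualifying HRR variant with probability logistic in $\theta$
  ($-2.2 + 1.5\,\theta$, about 19% prevalence), plus TP53 and
  sub-threshold noise variants that must *not* change HRD status.

Tumor BAF is emitted only at SNPs heterozygous in the simulated tumor
germline; control genotypes are drawn independently per control with
40% heterozygosity.  This mimics an upstream step that restricts BAF
reporting to informative sites, and it is the main idealisation:
real data would also show BAF at homozygous sites, plus GC-dependent
coverage waves, subclonal events and segmentation errors, none of
which the generator produces.  Passing recovery tests therefore shows
the pipeline's internal consistency under its own model assumptions -
not robustness to artifacts the model does not contain.

Event placement draws lengths first and places them longest-first into
free gaps chosen with probability proportional to the number of
admissible start positions; an event that fits nowhere is redrawn from
the length distribution a bounded number of times before a clear
"genome too small" error.  At high $\theta$ the demanded total length
can approach the reduced genome's size, so occasional redraws are
expected and effectively truncate only the extreme tail of the length
distribution.

## Validation results the test suite computes

The suite (and nothing else) establishes: equality of the GI vector
with a per-basepair brute-force tally on toy genomes; equality of the
exact rank-sum branch with full enumeration for every tie-free
configuration up to a pooled size of 8; equality of Clopper-Pearson
bounds with a direct beta-quantile oracle; exact recovery of
engineered event spans at purity 1 and zero noise; rank recovery of
$\theta$ by the called event count (Spearman threshold 0.6 at
$n = 200$); approximate uniformity of the scan's raw p values when the
clinical links are severed (Kolmogorov-Smirnov at $\alpha = 0.01$ over
200 null cohorts of 50, one designated parameter-grouping pair per
cohort so the KS test sees independent draws); and monotonicity of the
long-LOH tiers and the BAF filter on randomized inputs.  Problem
sizes - 200 patients for recovery, 200 x 50 for calibration, toy
genomes of 1 Mb for the brute-force oracle - are the package's chosen
validation conditions.

One numerical caveat is recorded here rather than hidden: the
continuity-corrected normal approximation to the rank-sum test can
deviate from the exact two-sided p value by up to 0.0155 at the worst
outcome when both groups have six observations; the suite checks this
exhaustively rather than asserting a uniform 0.01 agreement that the
approximation cannot deliver.

## Known limitations

* LOH is evaluated on the copy-number segmentation (plus tiles), not
  on an independent BAF segmentation; an LOH boundary inside one long
  neutral segment resolves only to tile resolution.
* The purity adjustment assumes a single clone and a diploid normal;
  subclonal events shrink toward neutrality and may be missed.
* Allele-specific copy number (major/minor counts) is out of scope;
  the package reports allelic imbalance, not its copy-number cause.
* The association layer reports many tests on small cohorts.  The BH
  column is provided, but the package deliberately does not gate any
  output on it.
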