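---
title: "Monitoring tumor burden from plasma cfDNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring tumor burden from plasma cfDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmonitor)
library(dplyr)
```

This vignette explains the models behind `cfmonitor`, the assumptions they
make, the tunable parameters and their defaults, what the synthetic data
generator does and does not emulate, and the numerical and design choices
made where several reasonable options existed.

## The monitoring problem

A solid tumor sheds DNA into the bloodstream; the fraction of plasma
cell-free DNA (cfDNA) that is tumor-derived — the *tumor fraction* — rises
and falls with tumor burden. Two measurement strategies are implemented:

* **Tumor-informed (WGMAF).** If the patient's tumor has been sequenced,
  its somatic mutations define a personal marker panel. Low-coverage
  whole-genome sequencing of plasma is then interrogated only at those
  positions, and the genome-wide mutant allele fraction estimates the
  tumor fraction directly.
* **Tumor-independent (ARTEMIS-DELFI).** Without tumor tissue, the
  *fragmentome* carries the signal: cfDNA fragment-length composition,
  chromosome-arm representation, repeat-element content and coverage of
  epigenetically marked regions all shift when tumor-derived DNA is
  present. A locked ensemble classifier converts these features into a
  probability-scale score.

Either score, measured at a *landmark* draw about eight weeks into
therapy, stratifies patients into molecular responders and nonresponders
whose survival is then compared.

## Tumor-informed arm

### Somatic filter chain

Candidate variants from a tumor/normal caller are retained only if all of
the following hold: the caller's own FILTER is PASS; at least 3 mutant
tier-1 reads in the tumor; tumor tier-1 MAF at least 10%; at least 30×
tier-1 coverage in the matched normal; zero mutant tier-1 reads in the
normal; normal tier-2 MAF at most 5%; and the variant is absent from the
population database above 1 in 10,000 (a missing database entry passes;
the database's own QC must also pass). All thresholds are inclusive at
the boundary, exactly as stated. The chain is a pure conjunction, so rule
order cannot matter; `apply_somatic_filters()` evaluates every rule for
every candidate and records all violated rules, not just the first. A
ratio with a zero denominator cannot satisfy its rule and fails with an
explicit "undefined ratio" annotation. Only single-base substitutions are
in scope; indels are rejected on ingest with a count. Tier-1 and tier-2
read classes are defined by the upstream caller and consumed here as
opaque annotated counts.

### Evaluability

With $N$ passing mutations, tumor fraction $f$, and mean depth $d$
fragments per variant position, the chance of at least one mutant
observation under independent sampling is
$P = 1 - (1-f)^{Nd}$. The evaluability threshold of 50 mutations comes
from this model: at $f = 0.01$ and $d = 3$, $P \approx 0.78 \ge 0.75$.
The depth model is a deterministic $N\!\cdot\!d$ Bernoulli count; a
Poisson-distributed depth with the same mean gives the same marginal
detection probability, and the closed form makes the model directly
testable against Monte Carlo. The per-position depth behind the original
evaluability analysis is not fixed by the statement itself, so $d$ is an
explicit parameter with default 3.

### Consensus pileup and WGMAF

A fragment contributes exactly one base at a variant position iff it is a
proper pair at the aligner's maximum mapping quality (42, configurable,
tested as equality exactly as worded), is not a PCR/optical duplicate,
neither mate has ≥ 5 uncalled bases, both mates cover the position with
base quality ≥ 30, both called bases are the reference or the mutant
allele, and the mates agree. Rejections are data (each carries a reason),
not errors. WGMAF is the ratio of mutant to total accepted bases summed
over all positions; a fragment spanning two variant positions contributes
independently at each, since counting is per position. Sequencing error
is deliberately *not* subtracted — the score is the raw ratio, and
limit-of-blank handling lives in the monitoring layer. Confidence
intervals are Wald intervals on the logit scale, back-transformed;
degenerate counts ($M = 0$ or $M = T$, routine in complete responders)
use a 0.5-count continuity adjustment so the interval stays defined, with
the hard boundary pinned to 0 (or 1).

## Tumor-independent arm

### Fragmentation profiles

The genome is tiled into large non-overlapping bins from an annotation
table carrying per-bin GC and mappability; bins with GC < 0.3 or
mappability < 0.9 are excluded (strictly below — a bin at exactly 0.3 is
kept). Fragments with MAPQ ≥ 30 and length in 100–220 bp are assigned to
the bin containing their midpoint — midpoint assignment is unambiguous
for bin-spanning fragments, which is why it was chosen — and split into
short (100–150 bp) and long (151–220 bp) classes. The per-bin short/long
ratio is the profile. Fragment intervals are 0-based half-open (BED);
variant positions 1-based (VCF); `bed_to_pos()`/`pos_to_bed()` convert.

One wording subtlety is worth recording: the ratio windows split short
from long between 150 and 151 bp, while GC correction is described as
splitting below/at 150. The package uses the ratio windows for binning
and splits GC correction at 150 *inclusive to the short class*, so the
two are consistent; the split point is a documented argument.

GC correction weights each fragment by `target_freq / observed_freq` of
its 1%-wide GC stratum, separately per size class, against a target
distribution estimated from a healthy reference panel (20 individuals by
default). Weights for strata absent from the target are zero; weights are
capped (default 10) with a counted warning. Arm z-scores use the *raw*
(uncorrected) arm fractions by default — the arm representation is
computed from total aligned fragments — centered and scaled by the
reference panel's per-arm means and SDs over the 39 autosomal arms
(acrocentric short arms 13p, 14p, 15p, 21p, 22p carry no usable sequence
and are excluded).

### Repeat landscapes and the ensemble

Repeat-element content is quantified without alignment: each repeat
family (LINE, SINE, LTR, satellite, other transposable elements) owns a
set of diagnostic kmers (k = 24 by default; both k and the multiplicity
rule are configuration, since different repeat references make different
choices), and a read increments a feature when it contains at least one
of its kmers. A read matching two features increments both — features
stay independent and no arbitrary priority is imposed. Feature selection
happens once, on a reference cohort: features with more than 1000 kmers
per million aligned reads (strictly more) enter the panel, which is then
locked. Within each sample, panel features are centered and scaled within
family; the sample-SD convention (denominator $n-1$, R's `sd()`) is used,
so a two-feature family with rates (100, 300) scales to ±0.707.

The ensemble mirrors the penalized-logistic-regression (PLR) stack: one
ridge PLR per repeat family and one on the epigenetic coverage block,
their out-of-fold scores stacked into the ARTEMIS score; one PLR on the
principal components capturing 95% of fragmentation-ratio variance
(missing ratios mean-imputed from training); one PLR on arm z-scores; and
a final stack of the three. Choices made where the mechanism was open:

* **Penalty:** L2 (ridge) with CV-selected strength — "penalized" without
  further qualification, and ridge keeps all correlated genomic features
  in play.
* **Stacker:** logistic, for a calibrated [0, 1] output, fit on
  out-of-fold component scores to avoid leakage. The stacker itself
  carries a small fixed L2 penalty (λ = 0.01): component scores routinely
  separate the training cohort perfectly, where unpenalized logistic
  regression diverges and saturates the output at exactly 0/1.
* **Locking:** the trained model serializes to versioned JSON
  (coefficients, PCA rotation, imputation means, feature panel, seed) and
  carries a checksum over panel and coefficients; application verifies
  the checksum and the presence of every panel feature, refits nothing,
  and is deterministic.

The reference feature counts of a genome-scale reference (hundreds of
repeat features, hundreds of epigenetic bins) are properties of that
reference, not constants of the method: synthetic references here use
small panels and the code is generic over panel size.

## Monitoring layer

Draw roles: baseline is the latest draw at or before treatment start;
fast-fail the first draw after start; landmark the second. The survival
clock starts at treatment initiation. The landmark cut is the cohort
median of landmark scores; responders are *strictly below* the cut, so
ties at the cut are nonresponders. The fast-fail threshold is the 75th
percentile (linear-interpolation quantile by default; the nearest-rank
convention is also supported and gives the same 9/27 split at n = 36 —
the convention is fixed and documented rather than silently environment
dependent). Cut points are cohort-specific and never transferred between
cohorts by default, because score scales shift between treatment settings.

The limit of blank is the maximum score among designated ctDNA-negative
samples — the original description reports the negatives' median and
range without fixing a formula, and the maximum is the conservative
choice that guarantees zero false positives on the negatives by
construction. Change-direction grouping is strict (landmark > baseline =
increasing); exact ties fall to the decreasing group and are flagged.

Kaplan–Meier medians, the log-rank test and univariate Cox hazard ratios
come from the `survival` package. The multivariate Cox model takes
molecular scores as continuous terms (genome-wide MAF standardized,
probability-scale ensemble scores raw) plus clinical covariates and
treatment arm; covariates constant in the cohort are dropped with a
warning (e.g., when no analyzed patient has elevated bilirubin), and
duplicated covariate columns are a collinearity error rather than a
silent aliasing.

## Compartment deconvolution

Reference A/B-compartment tracks assign each 100-kb bin a signed
eigenvalue (A = open = positive). Informative bins are those where two
reference tracks disagree in domain or where the z-standardized
eigenvalue difference exceeds ±1.96. The extraction model is the minimal
one consistent with weighting by the sample's tumor fraction $w$: plasma
is a two-source mixture, $\text{plasma} = (1-w)\,\text{healthy} +
w\,\text{component}$, inverted per sample and summarized as the per-bin
median across samples. Per-sample inversion (rather than a joint
regression across samples) was chosen as the default because it is exact
on noiseless mixtures for any $w \in (0,1]$ and makes no assumption that
samples share one component. Fragmentation profiles are z-scored per bin
before comparison with eigen-scale tracks. Samples with $w = 0$ carry no
tumor information under this model and are excluded with a warning.

## The synthetic cohort generator

The generator produces every input the pipeline consumes, with truth
labels sufficient to score any downstream stage without re-simulation.
Its defaults define the study conditions:

| Parameter | Default | Why |
|---|---|---|
| baseline tumor fraction | log-normal, median 4.9% | typical advanced-disease baseline burden |
| mutation count | log-uniform 9–20000 | observed range plus a hypermutator tail |
| plasma depth $d$ | 3 per position | low-coverage WGS at 2–3× |
| fragment modes | 167 bp healthy / 145 bp tumor | nucleosomal cfDNA vs shorter tumor-derived fragments |
| arm effects | gains 1q, 5p, 7p, 8q; losses 1p, 3p, 6p, 6q, 9p, 17p, 18q | recurrent pancreatic-cancer aneuploidies |
| true hazard ratio | 0.29 | responder/nonresponder separation of the monitored endpoint |
| nonresponder median OS | 126 days | anchors the baseline hazard |
| cohort | 40 patients × 5 draws, 2×10⁵ fragments/sample | desk-scale stand-in for tens of millions of fragments |
| sequencing error | 10⁻³ per base | typical post-filter substitution error |

A single master seed fans out to fixed substreams (panel, per-patient
tumor, per-sample pileup and fragment set, survival), so any patient is
reproducible in isolation and a cohort is byte-identical under the same
seed. Pileup depth is Poisson per position, matching shotgun sampling. A
plasma fragment carries the mutant allele with probability $f$ (not
$f/2$): this mirrors the convention of equating plasma tumor fraction
with expected MAF; ploidy and copy-number refinements are out of scope.
Survival times are exponential under proportional hazards with
independent exponential censoring calibrated to the configured censoring
fraction.

Artifact classes — caller failures, low-support calls, noisy-normal
evidence, population-database variants, PCR duplicates, discordant
mates, low MAPQ/quality bases, N-rich mates — are each constructed to
violate exactly one documented rule, which is what makes
sensitivity/specificity of the filter chains exactly 1 by construction
and any deviation a real defect.

Two tiers of realism exist: fragment-level simulation (lengths, bins,
GC, arm effects, kmer counts) feeds the fragmentomics and counting code;
*summary-level* feature simulation (`simulate_sample_features()`) draws
ensemble feature vectors directly, with fixed per-config effect loadings
scaled by tumor fraction, and is what the ensemble trains on. What the
generator does **not** emulate: real fragment-size multimodality and
tissue-of-origin nucleosome structure, GC–coverage interactions beyond a
per-bin mean, clonal hematopoiesis, indels and structural variants,
batch effects, and between-feature correlation structure of real repeat
landscapes. Passing tests therefore demonstrate that the *computations*
are correct and the statistical machinery recovers known truth under the
stated model — not that the classifier's synthetic AUC (or any other
figure of merit here) transfers to real cohorts.

## Numerical choices and degenerate inputs

* Undefined ratios in filters fail their rule with an explicit reason.
* A sample with no informative coverage yields a flagged missing WGMAF,
  not an error; `logit_interval()` errors only when the total count is 0.
* GC strata observed in a sample but absent from the target get weight 0;
  weights are capped at 10 with a counted warning.
* A repeat family whose features are identical in a sample scales to all
  zeros (zero variance), not NaN.
* Quantile conventions, tie handling at cuts, and the MAPQ equality rule
  are all fixed arguments, not environment-dependent behavior.
* Survival analyses refuse single-group and zero-event inputs with typed
  errors; `censoring_rate = 1` produces an all-censored cohort that
  triggers exactly that error downstream.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes while estimates remain well inside their
sampling tolerances: reference panels of 8–20 healthy samples at 2×10⁴
fragments each, training cohorts of 30–60 samples per class, 100
replicate pileups of ≤ 10⁴ fragments for oracle equivalence, 100
simulated cohorts of 400 patients for hazard-ratio recovery, and 10⁵
Monte-Carlo replicates for the detection-probability cross-check.

## Known limitations

* BAM ingestion is not implemented; fragment tables and pileup evidence
  enter as the documented TSV schemas (the synthetic generator writes
  them, and upstream extraction from BAM is standard tooling).
* The ensemble's synthetic performance says nothing about real-data
  performance (see above); the locked-model machinery, not the synthetic
  weights, is the deliverable.
* Tumor-fraction deconvolution from MAF, duplex/UMI error suppression,
  interval-censored survival methods and multiplicity correction across
  secondary endpoints are out of scope.
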