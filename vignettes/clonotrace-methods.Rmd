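---
title: "Methods: repertoire statistics, clone dynamics, and outcome association in clonotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire statistics, clone dynamics, and outcome association in clonotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

## Scope and data model

clonotrace analyses bulk T cell receptor (TCR) beta-chain repertoires
delivered as clone tables: one row per clonotype with its CDR3 nucleotide
and amino-acid sequence, V/J calls, read count, and frequency. A *clone* is
keyed by the CDR3 nucleotide sequence alone; records differing only in V/J
calls are merged with read counts summed and the majority call retained.
This keying is deliberate: the nucleotide junction is the most specific
observable identifier of a T cell clone in bulk data, whereas gene calls
are ambiguous at the primer and alignment level.

Two input dialects are supported behind one canonical container, the
`tcr_repertoire` (a tibble with sample metadata attributes): the AIRR
Rearrangement TSV schema (`junction`, `junction_aa`, `v_call`, `j_call`,
`duplicate_count`, `productive`) and a MiXCR-style clone-table export
(`cloneCount`, `cloneFraction`, `nSeqCDR3`, `aaSeqCDR3`, V/J hit columns).
When a dialect lacks an explicit productivity flag, productivity is
inferred: a clone is non-productive when its nucleotide length is not a
multiple of three, the translation contains a stop, or a declared
amino-acid sequence carries a stop (`*`) or frameshift (`_`) symbol or is
inconsistent with the nucleotide length.

### Filters

`filter_clones()` applies the two standard clone-table filters:

* **Read support.** Clones with fewer than 50 reads are removed; a clone at
  exactly 50 reads is kept (the cutoff is a strict "less than"). Clones at
  extremely low read counts are dominated by sequencing artifacts of
  abnormal length and frequent frameshifts, so this filter is a data-quality
  gate, not a biological threshold. The cutoff is a parameter (`min_reads`).
* **Productivity.** Non-productive clones are removed so one protein
  sequence represents each clone.

After filtering, frequencies are recomputed from the surviving read counts
so they sum to 1. Whether the original clone fractions should instead be
retained after filtering is genuinely open (both conventions appear in
practice); renormalization is the default because every downstream formula
assumes a proper frequency distribution, and `renormalize = FALSE` is
provided for sensitivity analysis.

## Diversity and clonal expansion

The central summary is the normalized Shannon diversity (Pielou evenness)

$$ H_\mathrm{norm} \;=\; -\frac{1}{\log N}\sum_{i=1}^{N} p_i \log p_i, $$

where $N$ is the number of clones and $p_i$ the clone frequencies. The
value lies in $[0, 1]$; the base of the logarithm cancels (natural logs are
used internally). Two conventions are fixed and documented: a single-clone
repertoire returns 0 (the limit of a maximally uneven repertoire; the
normalizer $\log 1$ vanishes), and unnormalized frequency vectors are an
error rather than silently rescaled.

Clones are classified as **hyper-expanded** when their frequency strictly
exceeds 0.002 (0.2% of the repertoire) and **non-expanded** otherwise. The
defining phrases ("exceeding" / "below" 0.2%) leave exact equality
unassigned; equality is assigned to the non-expanded class (strict `>`),
which is the conservative direction for a hyper-expansion call. The
hyper-expanded *fraction* is the summed frequency of hyper-expanded clones
— the share of cells, not of clonotypes — and `diversity_summary()` reports
both ratios (share of unique clones, share of cells).

Because a heavy hyper-expanded tail is exactly what depresses evenness,
$H_\mathrm{norm}$ and the hyper-expanded fraction are strongly negatively
correlated across a cohort; the acceptance suite checks Spearman
$\rho < -0.8$ on a 100-patient synthetic cohort spanning hyper-expanded
fractions from 0 to about 0.65.

Presentation helpers follow the same conventions used in repertoire
figures: `weighted_size_distribution()` bins $\log_{10}$ clone frequency
weighting each clone by its frequency (so the histogram shows the
distribution of *cells* across clone sizes), and `top_clones_by_mass()`
returns the smallest prefix of clones, by decreasing frequency, covering a
cumulative 75% of the repertoire (ties broken by clone key).

## Longitudinal clone dynamics

Within a patient's ordered series of blood samples, a clone is
**persistent** if detected in every sample, **transient** if detected in
exactly one, and **recurrent** otherwise. Detection is presence of the
clone key after filtering; no additional abundance threshold is imposed.
The three labels partition the observed clones. For a single-sample patient
the persistent and transient definitions collide, so such series are
rejected with an explicit error rather than labelled arbitrarily.

`persistent_recurrent_baseline_mass()` reports the baseline frequency mass
of redetected (persistent or recurrent) clones, and
`persistence_by_size_curve()` shows the proportion of each category across
uniform $\log_{10}$ baseline-size bins. Redetection probability rises
mechanically with clone size under finite sampling (a clone at frequency
$p$ is seen in a sample of $R$ reads with probability $1-(1-p)^R$), so the
persistent fraction should be non-decreasing in size even without any
biological stability — a point worth remembering when interpreting the
curve.

### The random-sharing null and the exact binomial test

`binomial_sharing_test()` asks, clone by clone, whether a paired sample is
compatible with random sharing from the baseline repertoire:

* null probability $p$ = the clone's baseline frequency;
* trials $n$ = the number of unique clones in the paired sample, a
  deliberate lower bound for the number of T cells surveyed (using a lower
  bound makes the test conservative);
* observed $x$ = the clone's paired frequency times $n$, rounded to the
  nearest integer. "Nearest integer" is ambiguous at `.5`; rounding half
  away from zero is fixed and documented.

The two-sided p-value is the exact minimum-likelihood ("minlike") binomial
probability — the sum of probabilities of all outcomes no more likely than
the observed one — computed by direct enumeration of the pmf over $0..n$,
with the conventional $1+10^{-7}$ relative guard when comparing densities
(the same convention as `stats::binom.test`, which serves as an independent
oracle in the test suite; agreement is at the $10^{-10}$ relative level,
apart from p-values below about $10^{-300}$ where double precision is
subnormal). Bonferroni correction multiplies by the number of baseline
clones tested; the correction is per comparison (per sample pair) by
default, since each paired sample is reported as its own analysis —
pooling across a patient's timepoints is available by correcting the
returned p-values externally. Only clones present at baseline are testable
(the null probability is defined from the baseline frequency); clones
private to the paired sample are counted in an attribute rather than
silently dropped.

Calibration is checked by construction: when the paired sample is an
actual multinomial draw from the baseline frequencies, the non-neutral
call rate at $\alpha = 0.05$ stays at or below the nominal level (the test
is conservative both through the Bonferroni correction and through the
lower-bound trials).

## Compartment overlap

Blood-tumor (or blood-blood) comparisons intersect repertoires on the
nucleotide key. `sharing_by_size_bin()` bins the reference repertoire's
clones uniformly in $\log_{10}$ frequency (bins right-closed, the maximum
assigned to the last bin; empty bins reported as missing, never as 0%) and
reports the percentage shared per bin, with the bin's upper edge as its
coordinate. `shared_size_correlation()` compares the sizes of shared
clones: Spearman correlation and an ordinary least-squares fit on
$\log_{10}$ frequencies (the figure axes in this field are log-scaled, and
a multiplicative size relationship is linear on that scale), with the
identity line as the random-sharing reference and per-clone
enrichment/depletion calls taken from the binomial test with the first
sample as baseline. Fewer than three shared clones yields a warning and a
missing correlation rather than a spurious number. Pooling across patients
is the default for the size-binned curves, with per-patient curves
available by mapping over patients.

## Specificity grouping and antigen annotation

The package does **not** reimplement GLIPH2. Its role — grouping CDR3
sequences likely to share specificity — is filled by an explicitly
simplified engine, and this is the largest deliberate design deviation in
the package:

* **Local similarity**: interior k-mers (k = 3 and 4 by default) obtained
  by trimming three residues from each end of the CDR3 (the flanks are
  largely germline-encoded). A motif founds a cluster when its frequency
  among the analysed sequences is at least 10-fold its background
  frequency and it occurs in at least 3 distinct sequences.
* **Global similarity**: groups of equal-length sequences identical up to
  one position (Hamming distance ≤ 1), including identical sequences
  carried by different clones.
* **Background**: a synthetic naive-repertoire motif table generated by the
  package's own CDR3 generator under a fixed internal seed (20,000
  sequences, cached per session, labelled synthetic in the documentation);
  motifs absent from the background receive a pseudo-frequency of
  $0.5/n_\text{seqs}$.

Clone frequency plays no role anywhere in clustering or annotation, and a
permutation test in the suite verifies exact frequency-invariance.
Sequences of 25 or more residues are excluded as abnormal-length artifacts.

High-confidence clusters require at least 3 unique sequences from at least
3 patients and a significant V-gene usage bias (one-sided exact binomial
test that the modal V gene exceeds its cohort background proportion, at
$\alpha = 0.05$).

Annotation is two-step so the reference cannot bias cluster formation:
step 1 clusters the patient clones alone; step 2 reclusters them together
with a reference table of CDR3-antigen pairs (VDJdb-style export, retaining
only pairs with confidence score above zero, duplicates collapsed).
Clusters found in both runs — matched by cluster key; matching by member
overlap is a reasonable alternative but the key is deterministic and
auditable — inherit the antigen of any co-grouped reference sequence.
Multiple antigens resolve to the most common named antigen, ties broken
lexicographically and flagged. A clone in several annotated clusters takes
the antigen of the largest cluster. HLA restriction is out of scope here;
annotations ignore HLA entirely, which inflates false positives relative
to an HLA-aware analysis and is stated as a limitation. Enrichment
statistics count *clones*, not cells, consistent with
frequency-independent clustering.

Association with expansion uses Fisher's exact test: a two-sided test on
the 2x2 table {has inferred target x hyper-expanded} (the reported odds
ratio is the sample cross-product ratio, not the conditional MLE), and
per-antigen one-sided tests for enrichment among hyper-expanded clones
with Benjamini-Hochberg correction. Degenerate margins report an undefined
or unbounded odds ratio with a note instead of failing.

Recovery is validated with planted truth: 10 specificity groups of 8
clones each, sharing an interior 4-mer and a V gene, hidden among 5,000
background clones with decoy reference pairs. At default parameters the
two-step annotation recovers at least 90% of the planted groups with at
least 90% of annotated clusters majority-planted.

## Survival association

Per-patient repertoire statistics enter survival analysis through a
median split: *low* is strictly below the sample median ("below-median"),
values equal to the median go to *high*. Kaplan-Meier curves, the log-rank
test, and Cox proportional-hazards regression delegate to the `survival`
package (product-limit estimator; `survdiff`; `coxph` with Breslow tie
handling — adequate at continuously simulated times). The curve-comparison
p-value reported by default is the Cox partial-likelihood ratio test, with
the log-rank statistic reported alongside; for a binary covariate without
ties the Cox score test and the log-rank statistic coincide, which the
suite checks to $10^{-6}$ relative error. Monotone likelihood (complete
separation) is reported as an unbounded hazard ratio with a diagnostic
rather than an error. Reference levels for categorical covariates in
multivariable models are left to the caller's factor coding rather than
fixed internally.

## The synthetic-data generators

Every stage is testable without patient data because the generators
produce the statistical structure the analysis assumes, with truth tables
for exact scoring:

* **Repertoires**: background clone weights from a log-normal law
  ($\sigma = 1.5$, giving the smooth low-frequency bulk of a right-skewed
  clone-size distribution; a Pareto alternative is available for
  tail-sensitivity checks), plus `n_hyperexpanded` clones planted at
  target frequencies Uniform(0.002, 0.15). As `n_hyperexpanded` varies
  0-12 the cohort-level hyper-expanded fraction spans roughly 0-65%; the
  cohort generator redraws a patient whose planted mass would exceed 0.65,
  keeping cohorts inside that emulated range. Read counts are multinomial
  draws (default $10^6$ reads); the 50-read filter is applied downstream
  exactly as for real data. About 2% of generated clones carry a stop
  codon so the productivity filter is exercised. CDR3 nucleotide sequences
  are random in-frame codons framed as C...F junctions — cosmetic realism
  only; no V(D)J recombination model is implied.
* **Longitudinal series**: latent frequencies drift by log-normal steps
  (sd 0.3 per step); at the first post-baseline timepoint non-expanded
  clones are depleted by a factor 0.5 and the distribution renormalized,
  emulating treatment-induced loss of small clones and the associated
  diversity decrease. Multinomial sampling per timepoint makes redetection
  size-dependent without further assumptions.
* **Paired tumors**: each blood clone enters the tumor with probability
  $\mathrm{logit}^{-1}(2.9 + 1.5\,\log_{10} p)$ — rising with blood clone
  size — with log-normal size perturbation; the tumor adds a majority of
  private clones and has fewer clones than blood, emulating a compartment
  with limited recirculation.
* **Specificity truth**: planted motif groups and reference pairs as
  above, with planted clones hyper-expanded at elevated probability so
  target-expansion association is positive by construction.
* **Outcomes**: exponential event times with hazard
  $h_0 \cdot \mathrm{HR}^{\,[\text{low diversity}]}$ ($h_0 = 0.05$ per
  month, HR = 2 by default) and uniform censoring on (0, 80) months, which
  yields roughly 20% censoring.

What the generators do *not* emulate — and therefore what passing tests do
not establish about real data — includes sequencing error and PCR bias,
UMI structure, batch effects, V(D)J generation probabilities, HLA-driven
specificity structure, and any dependence of outcome on covariates other
than the planted group effect. Tests on these generators validate the
*estimators and their contracts*, not biological claims.

All generators are deterministic given their configuration seed;
byte-identical reruns of the full pipeline are part of the acceptance
suite.

## Problem sizes and numerical conventions

The test and acceptance runs use desk-scale sizes chosen as reasonable
defaults for a laptop-class machine: cohorts of 100 patients at 2,000
background clones and $2\times10^5$ reads; 200 null-calibration pairs at
1,200-1,400 clones; 100 longitudinal series at 800 clones and 3 timepoints;
motif recovery at the full 5,000-background scale; survival recovery at
$n = 2000$ patients and 100 replicates; pipeline demos at 6-12 patients.

Numerical conventions collected in one place: frequencies must sum to 1
within $10^{-6}$ (inputs are renormalized from counts, so this only
triggers on malformed external input); minlike density comparisons use the
$1+10^{-7}$ relative guard; extreme tail p-values may underflow to 0 in
double precision, as in base R's exact tests; observed counts round half
away from zero; log-size bins are right-closed with the maximum in the
last bin and degenerate (single-valued) ranges widened by ±0.5; Cox
convergence uses a $10^{-9}$ score tolerance with at most 50 iterations,
and |beta| > 15 or SE > 100 is reported as an unbounded estimate.

## Known limitations

Beta-chain-only specificity inference is intrinsically noisy (both false
and missing targets are expected), and the simplified motif engine trades
the statistical machinery of dedicated tools for auditability; its
annotations should be treated as screening hypotheses. The sharing test's
trials are a lower bound on cells surveyed, so its calls are conservative;
depletion calls for small clones have limited power. Persistence is
confounded with clone size through detection probability, as noted above.
The pipeline's orchestration is single-threaded by design so results are
independent of scheduling.
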