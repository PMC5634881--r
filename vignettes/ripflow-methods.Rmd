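---
title: "ripflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ripflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ripflow` packages the quantitative procedures used in multi-omics
studies of protein–RNA and protein–chromatin cooperation — the kind of
study that combines RIP-Seq of a tagged bait, nascent-RNA sequencing
with and without a knock-down, ChIP-Seq interval statistics, and
tandem-affinity-purification proteomics. This vignette explains the
statistical models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and
the numerical choices made where conventions differ.

## 1. Count normalization and enrichment testing

Read counts $k_{ij}$ (feature $i$, sample $j$) are normalized with
median-of-ratios size factors,

$$s_j = \mathrm{median}_{i \in R}\; \frac{k_{ij}}{(\prod_j k_{ij})^{1/m}},$$

where the reference set $R$ holds the features with strictly positive
counts in all $m$ samples. Size factors are reported as returned by the
median (they are defined up to a common scale): rescaling one sample's
counts rescales its factor *relative to the others* by the same
constant.

The **enrichment factor (EF)** of a feature is the log2 ratio of mean
normalized counts between two groups, typically IP over input. The
associated test is a deliberately transparent negative-binomial Wald
surrogate, not a re-implementation of a shrinkage-based engine:

* per-feature method-of-moments dispersion
  $\hat\alpha = (\widehat{\mathrm{Var}} - \bar\mu)/\bar\mu^2$, pooled
  across the two groups and floored at $10^{-8}$;
* delta-method variance of the log mean,
  $\mathrm{Var}(\log \bar y_g) \approx 1/(n_g \bar\mu_g) + \hat\alpha/n_g$;
* the Wald statistic is referred to a *t* distribution with
  Satterthwaite degrees of freedom rather than a normal — with
  triplicates a normal reference is visibly anti-conservative, while
  the *t* reference keeps the null rejection rate at the nominal level
  (the test suite checks this on 200 null simulations).

Consequences are documented rather than hidden: no dispersion
shrinkage, no outlier filtering, and therefore no expectation that
data-derived constants from any particular dataset (such as a
75th-percentile cutoff value) are reproduced numerically. The cascade
semantics, not the engine, are the point.

EF display policy: the pseudocount (default 0.5) is applied only when
one group mean is zero, so testing is unbiased and EFs of partially
detected features remain finite. All-zero features are flagged, with
$p = 1$ and EF marked `NA`. Multiple testing uses Benjamini–Hochberg
throughout (`bh_adjust()` wraps the standard step-up; an independent
brute-force implementation of the definition lives in the test suite).

Expression detection uses a total-count threshold of 10 reads,
boundary inclusive; whether the sum or the per-sample maximum is used
is configurable because the convention is genuinely ambiguous in the
field (`per_sample` argument, default sum).

## 2. The RIP-Seq selection cascade

Selection of bait-associated RNAs proceeds in stages:

1. **candidates** — EF strictly greater than 1 and adjusted
   $p \le 0.05$;
2. **percentile gate** — EF strictly above the 75th percentile
   (linear-interpolation, type 7) of the candidate EF distribution.
   Type 7 is R's default and the most widely reproduced convention;
3. **specificity** — gated RNAs absent from the control-detected set
   are *specific*. "Detected in control" defaults to: passes the
   expression filter *and* has control EF > 0. The rule is
   configurable (`control_detect = "expressed"`) because the source
   convention is underspecified;
4. **rescue** — shared RNAs are rescued when the case/control EF ratio
   is at least 4 (evaluated only when both EFs are strictly positive;
   a control EF of exactly 0 skips the branch) *or* the control EF
   shows negative enrichment below −1.

The rescue rule is stated in the literature in two conflicting forms:
one reading requires the ratio *and* the negative control enrichment
simultaneously, which is arithmetically impossible (a control EF below
−1 cannot appear in the denominator of a positive ratio above 4).
`ripflow` implements the disjunctive reading — ratio branch *or*
negative-enrichment branch — and exposes the ratio boundary
(`ratio_strict`) as configuration. Note the interplay with the default
detection rule: an RNA with control EF below −1 is already "not
detected" under `ef_pos` and exits as specific; the negative-EF rescue
branch is exercised when detection is by expression alone.

The structural law `selected = specific + rescued` (disjoint) holds on
every input by construction and is asserted property-style in the test
suite, alongside a replay of the published stage arithmetic
(1139 gated → 614 specific + 525 shared → 264 rescued → 878 selected).

The miRNA variant uses the same cascade shape without a percentile
gate: candidate EF > 1 with raw $p \le 0.05$ (the adjusted-$p < 0.1$
variant is a configuration preset, since both appear in the
literature), an EF > 1.5 stage, ratio ≥ 2, and a negative-EF branch
that fires for any control EF below 0.

Biotype composition of a selected set is scored per class with an
upper-tail hypergeometric $P(X \ge k)$ against the full annotation
table as population.

## 3. Intron retention and knock-down reversal

For nascent-RNA counts, the per-intron **retention coefficient** in a
sample is the density ratio

$$\mathrm{IR} = \frac{\text{reads}_\text{intron}/\ell_\text{intron}}
                    {\sum \text{reads}_\text{exon} / \sum \ell_\text{exon}},$$

with all exons of the gene pooled, so exon-length imbalance cancels.
IR is 0 for a read-free intron and undefined (NA) when the gene has no
exon signal in that sample. Introns are the gaps between merged exon
records within the gene span; single-exon genes have none.

Differential retention between conditions uses a Welch *t*-test per
intron across replicates (the unequal-variance form is chosen because
nothing guarantees variance homogeneity between conditions), BH
adjustment, and a **modulation coefficient** defined as the log2 ratio
of mean IR, condition A over condition B. The log2 scale is chosen
because the conventional effect-size bins (±1.5, ±2) read naturally as
log2 fold changes; positive modulation means more retention in A,
i.e. reduced splicing efficiency. When a mean IR is zero the smallest
positive IR in the table is added to both means before the log — a
single documented floor rather than per-intron tuning. Zero-variance
introns are flagged and not tested.

The **reversal analysis** stratifies significant events of a primary
contrast into modulation bins
$\{<\!-2,\ [-2,-1.5],\ (-1.5,1.5),\ [1.5,2],\ >\!2\}$ and reports, per
bin, the fraction of introns whose knock-down contrast is significant
with opposite sign. The stated bin edges leave −1.5 unassigned; it is
closed into the left flank bin so the bins tile the real line (a
measure-zero choice on continuous data). Requiring knock-down
significance is the default and can be disabled; empty bins report NA,
never 0.

## 4. Genomic-interval statistics

Coordinates are 0-based half-open (BED) internally; GTF converts at
the boundary. All overlap machinery is `GenomicRanges`/`IRanges`;
quadratic brute-force oracles in the test suite pin the semantics.

* **TSS annotation**: signed midpoint-to-TSS distance, sign flipped on
  the − strand so upstream is negative; *promoter* means distance in
  [−1000, +100], both ends inclusive. Non-promoter peaks are labelled
  by midpoint overlap with workspace segments, priority
  exon > intron > intergenic.
* **Proximity pairing**: midpoints within 1000 bp, inclusive — the
  "within 1000 bases" convention is anchored at midpoints and
  documented because edge-to-edge alternatives exist.
* **Exact co-localization**: at least 1 bp of intersection under
  half-open semantics.
* **Permutation overlap test**: intervals are re-placed uniformly
  within their chromosomes, preserving lengths and per-chromosome
  counts, both sets shuffled by default;
  $p = (1 + \#\{\mathrm{sim} \ge \mathrm{obs}\})/(1 + N)$ is never
  zero. The statistic is the number of distinct query intervals
  overlapping the reference.
* **Segment enrichment**: observed vs expected base-pair overlap per
  segment class under the same randomization, fold = obs/exp (NA when
  the class is unreachable, never infinite), two-sided empirical $p$
  with the plus-one correction, BH $q$ across classes, and an
  `enriched` flag at fold > 2 and $q \le 0.05$. Randomization places
  intervals without inter-interval exclusion, which is simpler than
  isochore-matched workspaces; folds are therefore comparable, not
  identical, to tools that condition on local composition.

Default simulation counts in tests are scaled to 199–1000 placements
with the estimator unchanged; production analyses should raise
`n_sims` (the conventional scale is 10^4–10^5).

## 5. Bait-normalized interactome analysis

LFQ intensities are divided, per replicate, by the bait protein's
intensity — pull-down efficiency then cancels, the bait row becomes 1,
and the operation is idempotent. A missing bait intensity is a hard
error naming the replicate. Testing happens on log2 normalized values
(the scale is stated nowhere in the source conventions; log2 is the
field's default for intensity ratios): per-protein Welch *t*, with a
SAM-style permutation FDR — all distinct group-label splits enumerated
when $\binom{n}{n_A}$ is small (20 for 3 vs 3, making the result
deterministic), sampled otherwise, and
$\mathrm{FDR}(t^*) = \mathrm{median}_\pi \#\{|t_\pi| \ge t^*\} /
\#\{|t_\mathrm{obs}| \ge t^*\}$. Proteins need two non-missing values
per group; there is no imputation. The dependence summary reports the
fraction of quantified interactors significantly reduced under the
perturbation, with percentages rounded half away from zero (31/41
reports as 76).

## 6. The synthetic-data generators

All generators draw from one integer seed through a splitting scheme
(the seed is hashed with a per-stage stream name via 32-bit FNV-1a),
so outputs are byte-reproducible and stages are mutually independent.
Defaults emulate the targeted study designs:

* **RIP counts**: two cell lines × IP/input × 3 replicates; log-normal
  baseline expression around 100 reads; NB counts with dispersion 0.05
  (variance $\mu + 0.05\mu^2$, i.e. `size` = 20); per-sample depth
  factors log-uniform in [1/2, 2] so size-factor estimation is
  non-trivial. A planted 5% of features gets a specific IP enrichment
  of $2^3$ in the case line only. A further 40% carries *nonspecific
  carryover* — background IP binding of equal strength in both lines,
  log2 uniform in [1.0, 2.4]. The carryover mass reproduces the broad
  EF spectrum of real IP libraries, in which the percentile gate trims
  a large candidate pool down to a strongly enriched quartile; the
  chosen proportions mirror the published cascade (selected ≈ 19% of
  candidates, gated ≈ 25%). A *null configuration* for calibration
  work sets both `enriched_fraction` and `carryover_fraction` to 0.
  Joint IP/input normalization of libraries with substantial enriched
  mass exhibits the usual median-of-ratios composition bias; the
  parameter-recovery checks therefore run carryover-free, where the
  planted EF of 3 is recovered within ±0.2.
* **Gene models**: non-overlapping genes, 2–6 exons of 150–400 bp,
  introns of 200–1500 bp, random strand, biotypes drawn from a
  configurable distribution defaulting to a transcriptome dominated by
  protein-coding (38%) and antisense (26%) classes.
* **Nascent counts**: three conditions (baseline, case, case +
  knock-down) × 3 replicates. Replicate noise is modelled as a
  per-gene gamma multiplier shared by all features of the gene in a
  sample, with Poisson counting noise on top — marginally negative
  binomial, but correlated within a gene, which is what makes the
  intron/exon density *ratio* far more precise than either count. This
  mirrors real nascent libraries, where transcription-rate variation
  dominates replicate scatter and cancels in IR. Planted introns
  (default 30%) carry a signed retention shift of ±`ir_shift_log2`;
  a `reversal_fraction` of them returns to baseline retention under
  the knock-down, the rest keep the shifted level.
* **Interval sets**: reference intervals uniform on the workspace; a
  planted fraction of query intervals lands with its midpoint within
  `coloc_distance` (default 500 bp) of a reference midpoint.
* **LFQ matrix**: log-normal intensities with a per-replicate
  pull-down efficiency factor (absorbed by bait normalization), a
  high-abundance bait present everywhere, and a planted 70% of
  proteins reduced 4-fold in the knock-down arm, matching the reported
  scale of perturbation-dependent interactomes.

What the generators do **not** emulate: read-level artifacts
(alignment, duplicates, GC and positional bias), isoform structure,
peak-width and summit-shape variation, batch effects, and
intensity-dependent missingness in proteomics. Passing the
planted-truth suites therefore demonstrates correctness of the
procedures under their stated statistical assumptions, not robustness
to every failure mode of real libraries.

## 7. Problem sizes and reproducibility

The bundled demonstration (`run_demo()`) chains every track at sizes
chosen to finish in seconds on a single core while keeping all planted
signals recoverable: 1200 genes for the RIP track, 250 gene models for
the nascent track, 300 × 300 intervals with 500 placements, 200
proteins. The test suite and the acceptance script use 150–1000
features per run and 199–1000 permutations; null calibrations average
200 independent seeds. Reports echo their parameters and a config
fingerprint and contain no timestamps, so a fixed seed reproduces
every output byte for byte.

## 8. Known limitations

* The enrichment engine's p-values rely on a large-ish mean
  approximation; features with very low counts lean on the *t*
  reference and the dispersion floor. Borderline features near the
  detection threshold should be interpreted with care.
* The permutation randomizations do not condition on chromatin
  composition or mappability; enrichment folds are relative to a
  uniform-genome null.
* The cascade inherits the composition-bias caveat of joint IP/input
  normalization when the enriched mass is large; EF values are then
  uniformly compressed even though the selection logic (which is
  rank- and ratio-based) is unaffected.
* Percentages are rounded half away from zero; sources that round
  differently may print values one unit apart (75.6% as 75 vs 76).
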