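---
title: "Methods: binding landscapes, transcript design and qPCR arithmetic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding landscapes, transcript design and qPCR arithmetic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindscape)
```

# The scientific problem

Bacterial cold shock proteins (CspA family; CspE and CspC are the
constitutively expressed members in *E. coli*) are small single-stranded
RNA-binding proteins with a documented preference for uracil-rich RNA.
Transcripts encoding multi-pass membrane proteins carry periodic ~60-nt
U-rich stretches — the codon-level signature of ~20-residue transmembrane
helices. `bindscape` implements the quantitative workflow for asking whether
such proteins preferentially bind membrane-protein-encoding mRNAs (MPRs)
relative to cytoplasmic ones (CPRs): designing untranslatable model
transcripts to decouple binding from translation, scoring genome-wide
pull-down enrichment, building the percentile binding landscape with
category enrichment statistics, and the qPCR arithmetic used for targeted
validation.

# The binding-score model

For a pull-down experiment with paired total-extract and eluate libraries,
expression is normalised as reads per kilobase per million mapped reads,

$$\mathrm{RPKM}(g, s) = \frac{c_{gs}}{L_g / 10^3 \cdot T_s / 10^6},$$

with $c_{gs}$ the read count, $L_g$ the gene length in nt and $T_s$ the
per-sample mapped total. Because rRNA/tRNA and other non-coding reads are
conventionally removed before mRNA quantification, $T_s$ is by default the
column sum over protein-coding genes only (`totals = "coding"`); the raw
total is available as an option. The per-gene binding score is

$$B_g = \frac{\mathrm{RPKM}_{\text{pulldown}}(g)}{\mathrm{RPKM}_{\text{extract}}(g)},$$

computed after pooling replicates. Replicates are pooled by summing counts
and recomputing RPKM on the pooled library (`pooled_counts`), which weights
replicates by depth; averaging per-replicate RPKMs (`mean_rpkm`) is offered
and coincides exactly when replicate library sizes are equal. A gene whose
pooled extract RPKM is zero gets an explicit `defined = FALSE` flag rather
than being dropped — silent drops would bias the landscape tails, where
low-expression genes concentrate.

Detection filtering keeps a protein-coding gene only if it reaches
`min_rpkm` (default 1) in at least `min_samples` (default 1) samples of
*each* fraction, i.e. it must be detected in both the extract and the
pull-down. The threshold is a free parameter of the method: published
pull-down analyses rarely state theirs, so the default is deliberately
permissive and every removal is reported with a reason.

# The percentile landscape and enrichment statistics

Defined-score genes are ranked ascending by $B_g$ (ties broken
lexicographically by gene id, so results are identical across platforms)
and cut into `n_bins` contiguous blocks of near-equal size — deciles by
default, with remainder genes assigned to the lowest bins. The quota of a
category in a bin is the fraction of the bin's genes in that category; a
centred moving average (default window 3 bins, shrinking symmetrically at
the edges) gives the smoothed quota curve that visualises how, say, the MPR
share rises along the landscape.

The top and bottom sets hold $\lceil f N \rceil$ genes each (default
$f = 0.30$); with 2731 detected genes this is 820. Over-representation of a
category of size $K$ in a selected set of size $n$ drawn from a background
of $N$ is tested with the exact upper hypergeometric tail

$$p = \sum_{i=k}^{\min(K, n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

Alongside it the EASE variant (the conservative score used by the DAVID
annotation tool, replacing $k$ by $k-1$) is always reported, and depletion
is tested with the lower tail $P(X \le k)$ rather than $1 - p$, which is
the correct discrete-tail semantics. Bonferroni correction multiplies the
directional p-value by the number of tests performed — by default the
number of categories times the two sets — because the term universe of any
external annotation tool is not reproducible here. On printed selection
counts of the kind above (e.g. 213 of 471 MPRs in a top set of 820), the
plain hypergeometric tail is below $10^{-12}$; such values agree with
DAVID-style reports in direction and magnitude class, not digit-for-digit,
since DAVID's background and multiplicity are unknowable outside the tool.

# Untranslatable transcript design

`design_untranslatable_mimic()` rewrites an ORF segment so that its
interactions are translation-independent while its nucleotide composition —
in particular the windowed U-content profile that encodes the
transmembrane-helix signal — tracks the source:

* every start codon (default set `{ATG}`; `GTG`/`TTG` opt-in, since which
  alternative starts matter is organism- and context-dependent) in the
  scanned frames (default all three) is destroyed by a single-base
  substitution that must not create a new start;
* a TAA stop — the strongest stop codon — is written in frame 0 every 15
  codons (0-based codon indices 14, 29, ...), so a 138-codon fragment
  carries at least 9 in-frame stops;
* Shine-Dalgarno-like motifs, operationalised as any match of 4 or more
  consecutive bases of `AGGAGG`, are disrupted by one substitution. The
  designer removes every such motif: in a start-free transcript any
  remaining motif is 4–14 nt upstream of *some* frame-0 codon boundary, so
  no spacing filter would exclude it. `verify_untranslatable()` separately
  reports which motifs sit at ribosome-binding spacing (4–14 nt) upstream
  of a start codon.

Substitution choice is deterministic but composition-aware: among the valid
single-base changes, the one keeping the running T count closest to the
source is taken — judged first within the local 55-nt neighbourhood, then
globally — with ties broken by position and then the fixed base order T, A,
C, G. A purely fixed trial order was considered and rejected: always
preferring T adds one T per start removal and drifts the composition beyond
the 2-per-100-nt budget the design guarantees. Stop-insertion events may
change up to three bases; when writing TAA costs local T (the codon being
replaced was T-rich), the event spends its remaining budget on an adjacent
compensating substitution. Empirically this keeps the 55-nt windowed
U-profile of the mimic within ±0.05 of the source at every window for the
large majority of random 138-codon fragments, with a worst observed
deviation of 3/55 ≈ 0.055 when two stop writes land on T-rich codons inside
one window; the guaranteed invariant is the global T-fraction difference of
at most 0.02. Designing a mimic a second time produces zero edits
(idempotence).

`u_content_profile()` uses 0-based half-open windows of 55 nt by default —
the resolution at which ~60-nt U-rich stretches are visible — with the step
exposed (default 1 nt) because classic profiling software does not document
its step.

# The synthetic-data generator

`simulate_dataset()` emulates the full experiment so every stage is
testable at desk scale. Its defaults are the study conditions the package
is built around, chosen once:

* **Gene universe**: 2000 genes; category fractions MPR 0.17, CPR 0.50,
  SPR 0.15, CSP 0.005, OTHER 0.175, mirroring the published detected-gene
  composition (471 MPRs and 1363 CPRs of 2731 genes, with nine *csp*
  genes). Counts are apportioned by largest-remainder rounding so the
  composition is exact and reproducible. Lengths are log-normal
  (`meanlog = log(900)`, `sdlog = 0.45`, floored at 90 nt), matching the
  scale of bacterial ORFs.
* **Abundances**: log-normal with `sdlog = 1.5`, giving the ~3 orders of
  magnitude of dynamic range typical of bacterial transcriptomes.
* **Binding**: $\log_2$ propensity = category effect (per condition) +
  gene-level Gaussian noise (sd 0.25), drawn once per gene and shared
  across conditions — a gene's intrinsic affinity, scaled by condition.
  The continuous gene-level term makes the landscape a continuum rather
  than two point masses, as observed in real data. Default effects:
  condition `"Mg2"` (low Mg²⁺) MPR +1, CPR −0.5, SPR −0.5, CSP +1.5;
  condition `"Mg15"` (high Mg²⁺) MPR +1.5, CPR −0.75, SPR −0.75, CSP +1 —
  membrane-protein specificity rises with Mg²⁺ while CSP-mRNA association
  is strongest at low Mg²⁺. All magnitudes are configuration, not
  behaviour.
* **Counts**: negative binomial with a single shared dispersion 0.05
  (variance $\mu + 0.05\mu^2$, the overdispersion scale of well-behaved
  RNA-seq replicates); expected extract counts ∝ abundance × length,
  pull-down counts additionally ∝ propensity; each library is scaled to an
  expected `libsize` of 2 × 10⁶ reads. Because the published experiment's
  depth and replicate variability are not reported, library size,
  replicates (3) and dispersion are free, documented parameters.
* **Ct tables**: `Ct = 35 − log2(abundance) + N(0, noise_sd)`, pull-down
  samples using abundance × propensity. The intercept 35 (abundance 1 →
  Ct 35) is arbitrary but fixed and configurable.
* **Sequences**: `simulate_orf()` builds ATG-initiated, TAA-terminated,
  internally stop-free codon runs whose designated segments carry an exact
  target T count; outside segments bases are uniform (T fraction 0.25).

What the generator does *not* emulate: positional coverage bias, GC
effects, multimapping, batch structure, or any correlation between
U-content of the simulated annotation and its category labels — binding
preference is injected through category effects, not through sequence.
Passing recovery tests therefore demonstrates that the statistical
machinery is correct and calibrated, not that real pull-down data are free
of such confounders.

# Calibration and recovery behaviour

Three properties anchor the test suite (problem sizes chosen to keep the
default run around ten seconds):

* **Null calibration**: 200 simulated datasets with all binding effects
  zero (2000 genes, 3 replicates, one condition) give top-30% MPR
  enrichment p-values consistent with uniformity (Kolmogorov–Smirnov at
  α = 0.01) and median binding scores within [0.8, 1.25]. The p-values are
  discrete, so exact uniformity is not attainable; at these set sizes the
  discreteness is far below the KS detection limit.
* **Effect recovery**: a +1 log₂ MPR effect is detected (top-30%
  enrichment p < 0.01) and the smoothed MPR quota curve rises along the
  deciles (Spearman ρ > 0.8 vs bin index) in at least 95 of 100 seeds.
* **Scale invariance**: expected binding scores are unchanged under a
  10-fold change of library size (RPKM-ratio invariance).

# qPCR arithmetic

One PCR cycle is a factor of two, so the abundance of a transcript in a
fraction relative to the input is $2^{\,\mathrm{Ct_{input}} -
\mathrm{Ct_{fraction}}}$; replicate Cts are averaged on the Ct scale before
the formula (standard practice — Ct is the log-domain quantity), and the
SEM over per-replicate ratios is reported alongside. Relative quantities
use the comparative-Ct scheme against an endogenous control (default
`rnpB`, the RNase P RNA) and a calibrator transcript whose RQ is 1 by
construction; ΔCt is formed within a sample, making RQ invariant to
per-sample plate offsets. Undetermined Cts stay missing and propagate to
undefined ratios — they are never imputed or coerced to zero. Standard
curves are ordinary least squares of Ct on log₁₀ input with efficiency
$10^{-1/\text{slope}} - 1$ and the conventional primer QC window
$-3.6 \le \text{slope} \le -3$, $R^2 > 0.995$.

# Numerical and degenerate-input choices

* All ties (ranking, binning, set membership) break lexicographically by
  gene id; all generators are deterministic given their seed.
* Hypergeometric tails come from `stats::phyper`; the test suite
  cross-checks them against exhaustive enumeration of all draws (N ≤ 12)
  and an independent log-binomial tail sum.
* Fewer defined-score genes than bins, overlapping top/bottom sets
  (`fraction ≥ 0.5`), zero mapped reads, unannotated genes, absent
  control/calibrator genes, and non-ACGTU characters are all hard errors
  with informative messages, not silent coercions.
* `filter_detected` with `min_samples = 0` disables the detection rule but
  still removes non-coding genes.

# Known limitations

* RPKM is the only normalisation offered, by design; the binding score is
  a within-gene ratio, so length and (with pooled counts) depth effects
  cancel, but between-condition comparisons inherit RPKM's
  composition-sensitivity.
* The enrichment background is the detected-gene universe; annotation-tool
  backgrounds (and hence their exact corrected p-values) are out of scope.
* The mimic designer guarantees global composition preservation; per-window
  agreement is empirical (see above) and can reach 0.055 on adversarial
  inputs.
* The generator's category effects are condition-specific constants plus
  gene noise; it does not model sequence-driven binding, so it cannot be
  used to test sequence-level predictors.
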