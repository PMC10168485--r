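---
title: "Methods: phenotype classification and variant scanning for adult-onset hearing loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype classification and variant scanning for adult-onset hearing loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presbyscan)
```

# Overview

presbyscan re-implements, as one tested pipeline, the computational core of
exome studies of age-related hearing loss that combine audiometric
phenotyping with variant-level genetics: (1) classification of audiograms
into presbyacusis phenotypes by decomposition into canonical metabolic and
sensory profiles; (2) consensus merging of genotypes from three variant
callers with a chain of quality filters; (3) gene-level variant-load
outlier regression between phenotype groups with hypergeometric gene-set
enrichment; and (4) a per-variant audiometric threshold-difference scan
with sex-preserving permutation testing. Because the cohorts such studies
use are access-restricted, a synthetic-cohort generator reproduces the
statistical structure the analysis assumes, and every stage is tested
against it.

# The audiogram decomposition model

An audiogram is a vector of pure-tone thresholds $y(f)$ in dB HL over a
frequency grid (default 0.25–8 kHz, both ears). The model is

$$y(f) = m\,M(f) + s\,S(f) + \varepsilon(f), \qquad m, s \ge 0,$$

where $M$ and $S$ are canonical *metabolic* (strial) and *sensory*
(hair-cell) loss profiles and $\varepsilon$ is measurement noise. The fit
minimises the residual sum of squares subject to nonnegativity; with two
components the NNLS problem is solved exactly by comparing the
unconstrained stationary point with the two edge solutions. The *line-fit
error* is the RMS residual in dB; large values flag audiogram shapes (e.g.
corner audiograms) the two components cannot represent.

**Scale of the estimates.** The classification rules below compare $m$ and
$s$ against dB boundaries, so the profiles are stored normalised to unit
maximum: the fitted weights then read directly as each component's dB
magnitude at the frequency where its profile peaks (8 kHz for both default
shapes). Supplying profiles on any overall scale is fine —
`profile_basis()` normalises them.

**Default profiles.** The source studies derive the canonical profiles
from several hundred older-adult audiograms but do not print them. The
package defaults are placeholders parameterised from the standard verbal
description, linear in log2-frequency: metabolic rises from 20 dB at
0.25 kHz to 40 dB at 8 kHz (4 dB/octave, "mildly elevated low frequencies
sloping gently"); sensory is 0 dB through 1 kHz then rises 20 dB/octave to
60 dB at 8 kHz ("normal low frequencies, steeply sloping high
frequencies"). Substitute measured profiles via `profile_basis(grid,
metabolic, sensory)`; grids are matched by interpolation linear in
log-frequency, without extrapolation.

**Open choices resolved.** The line-fit error is RMS (not mean-absolute or
maximum residual), and the fit is constrained to $m, s \ge 0$:
hearing-loss components cannot be negative, and unconstrained fits go
negative on near-normal audiograms.

# Phenotype classification rules

Rules apply strictly in order; the first match wins. Magnitude criteria
use the across-ear mean of each estimate, asymmetry criteria the absolute
left–right difference (the source description says only that estimates are
computed per ear pair; "ear asymmetries" motivates this split).

1. **Unselected** — line-fit error ≥ 15 dB in *either* ear (a single
   uninterpretable ear invalidates the pair).
2. **Older-Normal** — $\bar m + \bar s < 20$ dB HL and both between-ear
   differences < 10 dB (plural "estimates" → applied to both).
3. **Metabolic** — $\bar m \ge 20$, metabolic asymmetry ≤ 15, $\bar s <
   20$, $\bar m > \bar s$.
4. **Sensory** — $\bar s \ge 15$, sensory asymmetry ≤ 20, $\bar m < 25$,
   $\bar s > \bar m$.
5. **Unclassified** otherwise.

All boundaries are implemented literally (≥, <, ≤ as printed) and locked
by tests. Manual audiogram review is not automated; an override table
(`participant_id`, `category`) stands in for it.

# Variant consensus and quality control

Inputs are per-caller genotype calls (GATK with VQSR tranches, BCFtools,
Freebayes), consumed as boolean pass flags plus tranche labels — the
upstream callers and their filter settings are out of scope. The chain:

* **Combination filter** — keep iff (GATK pass in tranche T1 **and**
  BCFtools or Freebayes pass) **or** (tranche T2 **and** BCFtools pass).
  The T2 branch does not consult the GATK pass flag: tranche membership is
  the quality statement for second-tranche calls.
* **Consensus merge** — unanimous or 2-vs-1 → majority; the three-way
  disagreement {hom-ref, het, hom-alt} → het; anything else, including any
  missing call, → missing. Symmetric in caller order.
* **Excess heterozygosity** — one-sided Levene–Haldane exact test for
  heterozygote excess (misalignment signature); drop at $p < \alpha$,
  default Bonferroni $0.05/n$ (the source does not print its threshold).
  Monomorphic variants are kept ($p := 1$).
* **Cohort AF anomaly** — drop iff within-cohort alternate allele
  frequency > catalogue MAF + 0.4 (strict); absent from catalogues →
  MAF 0, the conservative choice for this rule.
* **Impact/MAF** — keep iff high predicted impact and catalogue MAF < 0.1
  (both strict). "High impact" is an input column; its upstream definition
  (VEP consequence classes etc.) is out of scope.
* **Mitochondrial calls** — VAF > 0.95 (strict) → homozygous alternate,
  else heterozygous; calls below 30× depth or VAF 0.40 are missing, the
  floor at which heteroplasmy is reliably detectable from off-target exome
  reads.

Each filter reads only immutable record fields plus the consensus
genotypes, so keep/drop outcomes are order-independent; the order above
fixes only which drop reason is logged. The drop log asserts
$n_{in} = n_{kept} + \sum$ per-reason drops on every run.

# Variant-load outlier regression

Per gene and phenotype group, qualifying variant alleles are summed
(het = 1, hom-alt = 2, missing = 0; homoplasmic mitochondrial calls were
coded homozygous upstream). Allele dosage rather than carrier counting is
the default because "total number of variants" with
homoplasmic-as-homozygote handling implies dosage; `count = "carrier"` is
available. For a comparison, OLS with intercept regresses the response
group's counts on the predictor group's across genes; with $Q_1, Q_3$ the
linear-interpolation quartiles of the residuals and $D = Q_3 - Q_1$, genes
with residuals $> Q_3 + 6D$ (or $< Q_1 - 6D$) carry an exceptionally high
load in the response (predictor) group. The quantile definition matters at
this cutoff and is therefore pinned (R type 7) and oracle-tested. The
$6D$ rule is deliberately extreme: on null matrices it flags almost
nothing, and a 5× inflated load is only detectable on genes whose baseline
load clears roughly $4\mu \gtrsim 8\sqrt{2\bar\mu}$ — an inflated
one-variant gene is invisible by design.

Enrichment of outlier lists against curated sets (known deafness genes,
highly variable genes) uses the one-sided hypergeometric
over-representation test on the analysis universe (genes with ≥ 1 called
variant), sets intersected with the universe first; adjustment defaults to
Bonferroni across all tests in a run (the source prints "adj.p" without
naming a method). List combination across comparisons/cohorts is by union,
with exact Venn-region counts across analyses.

# The threshold-difference scan

For each variant, up to six alternate-allele groups are formed (het,
hom-alt × all/male/female); groups under 5 persons are skipped, and each
group is compared with its sex-matched homozygous-reference participants.
A frequency $f$ in ear $e$ passes iff
$|\bar y_{alt}(f,e) - \bar y_{ref}(f,e)| \ge 20$ dB and the *alternate*
group's sample SD is at or below the band cap (15 dB ≤ 0.5 kHz, 20 dB for
1–2 kHz, 25 dB for 3–4 kHz, 30 dB above 4 kHz; caps on the alternate group
only, as stated — the reference may be arbitrarily variable). A contrast
with ≥ 2 passing frequencies in each ear is a candidate. 20,000
permutations then reassign participants from the alternate ∪ reference
pool to a pseudo-alternate group of identical size and sex composition; a
permutation is *similar* when the permuted grouping itself satisfies the
candidate criterion — the same test the observed grouping had to pass,
which is this package's formalisation of "a similar result" (recorded as
an open question against the original scripts). Strictly more than 1,000
similar permutations rejects the candidate; otherwise it is *detected*.
Detected contrasts are labelled *better* when the mean of the passing
signed differences is negative (lower dB HL = better hearing), *worse*
otherwise, with an exact zero tied toward worse.

Missing thresholds are handled per frequency (pairwise deletion), since
audiometric grids differ between cohorts. The permutation engine is
vectorised (index-matrix resampling per ear-frequency column) and seeded:
a fixed seed reproduces every similar count.

**What the cutoff guarantees.** Under the null, writing $q$ for the
probability that a random same-composition regrouping is a candidate, a
null contrast is detected only when it is itself a candidate *and*
$q \lesssim 1000/20000$; the unconditional false-detection rate is
therefore at most about the nominal 5%. Conditioned on being a candidate,
rejection is certain when $q$ exceeds the nominal level and essentially
never happens when $q$ is below it — the procedure screens out effects
that are easy to reproduce by chance, it does not produce uniform
conditional p-values. The acceptance suite asserts exactly these two
properties on an adversarial bimodal null world.

Second-cohort follow-up re-runs the full scan on the replication cohort
and additionally reports, per detected variant: carrier counts, the net
mean threshold difference on the shared grid, and a qualitative flag —
`absent` (no carriers), `not_comparable` (sex-specific effect, sex absent
from cohort 2), else `similar`/`different` by sign agreement of the net
difference with the detected direction.

# The synthetic world

`simulate_cohort()` generates the structure the analysis assumes — and
only that:

* **Participants** — default n = 500, 55% female (a slight female excess,
  as in the motivating cohorts); ages uniform 55–85; positive
  noise-history flags Bernoulli with sex-specific rates 0.79 (M) / 0.21
  (F), mirroring reported male noise-exposure excess. Ages and noise
  history are reporting-only, never used by inference.
* **Audiograms** — a phenotype category is planted per participant
  (default mix 20/30/30/20% Older-Normal/Metabolic/Sensory/Unclassified);
  one $(m, s)$ pair per participant is drawn from category-specific
  ranges (Older-Normal $m,s \in [0,7]$; Metabolic $m \in [25,40], s \in
  [0,12]$; Sensory $m \in [0,12], s \in [25,45]$; Unclassified-like
  $m,s \in [27,40]$) and shared by both ears, so asymmetries are zero
  before noise and every category rule holds with several-dB margins in
  the noiseless limit. Thresholds are $mM + sS$ plus i.i.d. Gaussian
  noise per frequency and ear (default SD 3 dB, typical audiometric
  test–retest variability), truncated below at −10 dB HL. With these
  margins the analytic estimate SDs under 3 dB noise (≈1.8 dB for
  $\bar m$, ≈2.6 dB for $\bar s$) put expected misclassification around
  1–2%, dominated by Older-Normal asymmetry draws — hence the ≥95%
  recovery criterion holds with room.
* **Genotypes** — per-variant MAF uniform on [0.005, 0.10] (rare to
  intermediate, inside the downstream MAF filter), genotypes
  Binomial(2, MAF). Planted effects add a dB shift vector to carriers'
  thresholds in both ears, optionally sex-restricted. Caller
  disagreements: at the configured rate per call, one caller chosen
  uniformly reports a uniformly chosen different genotype, so every
  disagreement is 2-vs-1 against truth.
* **Not emulated** — linkage disequilibrium, relatedness, batch effects,
  caller-specific error modes, realistic annotation structure, and real
  audiogram shapes beyond the two-component model. A green end-to-end
  test therefore establishes that the *procedures* behave as specified on
  data satisfying their assumptions — not that the assumptions hold in
  any real cohort.

Determinism: identical `sim_config()` (including seed) gives identical
cohorts and byte-identical fixture files.

# Numerical and degenerate-case choices

* NNLS: exact three-candidate solution; collinear bases and all-missing
  threshold vectors are errors, missing thresholds are dropped per
  frequency.
* Exact zero residual fits: outlier comparisons use a relative tolerance
  of $10^{-8}$ so floating-point noise on a perfect fit is not an
  "outlier" (with $D = 0$, any nonzero residual would otherwise flag).
* Quantiles: type 7 everywhere, pinned by oracle tests.
* Monomorphic variants: excess-het $p := 1$ (kept).
* Empty inputs: empty cohorts classify to empty frames, write valid
  headed fixture files, and summarise to all-zero tables.
* Percentages and reported means round half away from zero
  (`round_half_up()`), matching how summary tables are conventionally
  printed.
* Permutation seeds: one `set.seed()` per scan; results are reproducible
  given identical inputs, criteria and seed.

# Known limitations

* The canonical profiles are placeholder shapes; classification boundaries
  interact with profile shape, so results on real data require the real
  profiles.
* The scan treats frequencies as exchangeable apart from SD caps; it does
  not model audiogram smoothness.
* "High impact" and the curated gene sets are inputs; the package does not
  annotate variants or curate lists.
* The permutation "similar result" definition and pool reconstruct the
  published description; the original scripts may differ in detail.
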