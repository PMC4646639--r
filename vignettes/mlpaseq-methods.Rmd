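---
title: "Copy-number calling from sequencing-based MLPA: model and methods"
author: "mlpaseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling from sequencing-based MLPA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpaseq)
```

## The assay and its dosage model

Multiplex ligation-dependent probe amplification (MLPA) measures gene copy
number by hybridising pairs of oligonucleotide probes adjacently on genomic
DNA; only correctly hybridised pairs are ligated and then PCR-amplified, so
the abundance of each amplified probe pair is proportional to the copy
number of its target. In the sequencing-based variant this package
implements, probe pairs carry transposase-adapter overhangs, the amplicons
(~60 bp of probe sequence) are sequenced, and each read is assigned to a
probe by searching for the 20-base *middle key* spanning the ligation
junction. Because the key crosses the junction it only occurs in ligated
products, and because the amplicons are short the assay tolerates the
fragmented DNA typical of FFPE tumour material.

Each sample is assayed in two independent reaction libraries — a *detection*
mix and a *confirmation* mix with distinct probes over the same exons — so
that exon-level results pool measurements that do not share probe-specific
failure modes (e.g. a SNV under one ligation site).

### Normalization and ratios

For library $i$ and probe $k$ with raw count $x_{ik}$:

1. **Depth normalization.** $x'_{ik} = x_{ik} / X_i$, where $X_i$ is the
   arithmetic mean of raw counts over probes of *non-amplification* genes.
   Probes targeting genes under amplification surveillance (*CCNE1*, *EMSY*,
   *ERBB2*, *MET*, *MYC*, *AURKA* in the bundled panel preset) are excluded
   from $X_i$ so that a genuine high-level amplification cannot deflate
   every other probe's value; they are still divided by $X_i$.
2. **Control baseline.** $x''_{ik} = x'_{ik} / \overline{x'}_{k}$, the
   probe's mean depth-normalised value over accumulated copy-neutral control
   samples. Fixed probe-specific efficiency biases cancel exactly in this
   ratio. A ratio of 1.0 corresponds to two copies.
3. **Exon aggregation.** Ratios from the detection library, the confirmation
   library and within-library replicate probes of the same exon are pooled;
   the exon mean and sample SD ($n-1$ denominator; 0 for single-probe exons)
   are reported. With per-probe ratio SD $\sigma \approx 0.103$ at the
   assay's operating point, a two-probe exon has SD
   $\sigma/\sqrt{2} \approx 0.072$.

Arithmetic means are used throughout (a robust median variant of $X_i$ is
deliberately **not** the default; see *Known limitations*). The SD uses the
$n-1$ denominator.

### Classification bands

Exon mean ratios are classified by fixed dimensionless bands
(`classificationConfig()`):

| band | category |
|---|---|
| $r \le 0.3$ | homozygous deletion (~0 copies) |
| $0.3 < r < 0.7$ | heterozygous deletion (~1 copy) |
| $0.7 \le r \le 1.3$ | normal variation |
| $r > 1.3$ (blood) | duplication |
| $1.3 < r \le 1.5$ (tumour) | equivocal gain — not called |
| $r > 1.5$ (tumour) | amplification (>3 copies) |

Band boundaries are assigned to the *normal* category: the description of
the bands leaves 0.7 and 1.3 themselves ambiguous, and placing them in the
normal band is the conservative choice for a diagnostic-style caller. The
tumour-only (1.3, 1.5] zone is surfaced as `equivocal_gain` rather than
silently normal so it can be reviewed. Copies are reported as
$2 \times r$ (autosomal diploid reference; the reference ploidy is a single
configurable constant). Exon SD is reported but not used as a calling
criterion by default; `requireSdSupport = TRUE` additionally demands
$|r - 1| > 2\,\mathrm{SD}$.

Origin assignment compares tumour and paired blood calls per exon: events in
both are germline; tumour-only events are somatic; a tumour homozygous
deletion over a blood heterozygous deletion — or a tumour homozygous
deletion without any paired sample, since the zero-copy state implies a
constitutional first hit — is reported as germline with loss of
heterozygosity. Amplification *level* annotation (low: >3–6, medium: >6–12,
high: >12 copies) is applied to this assay's own copy estimates.

### The mixture / purity model

For a specimen mixing cell populations with fractions $f_j$ and locus
copies $c_j$, the expected ratio is $\sum_j f_j c_j / 2$
(`expectedMixtureRatio()`). A somatic loss of $\Delta$ copies at tumour
purity $p$ therefore shows at ratio $1 - p\Delta/2$, and
`somaticDetectionLimit()` returns the smallest integer $\Delta$ pushing that
below the normal band: one copy at 100 % purity, two (homozygous) at 50 %,
undetectable below ~30 %.

## Read counting

Reads (read 1 only by default — the ~60 bp insert is fully contained in
either mate, so counting both would double-count) are adapter-trimmed at the
leftmost occurrence of the first 10 bases of the downstream adapter, then
scanned for the mix's middle keys, forward and reverse complement, using a
preprocessed constant-width dictionary. Exact matching is the default,
mirroring fixed-key genotyping of the amplicons; `one_mismatch` mode (two
complementary trusted-band dictionaries, allowing one mismatch anywhere in
the 20-mer) is available but off by default — mismatch tolerance would mask
the assay's documented sensitivity to variants under ligation sites rather
than reproduce its behaviour. Reads matching two or more distinct keys are
chimera-like and are discarded as *ambiguous* (counted separately, never
fractionally assigned); bookkeeping reconciles exactly as
`on_target = sum(counts) + ambiguous <= total`.

QC per library: median per-probe coverage must meet the run-design
requirement (default 1000-fold); probes under the 500-fold floor are counted
and flagged; when a no-template control is supplied its mean probe coverage
must stay below 1 % of the sample's mean (the NTC is reported in the
original workflow without a numeric threshold; 1 % is this package's
configurable default).

**Where the coverage floor acts.** The floor flags probes in QC and marks
probes unusable in *baseline construction* (controls are copy-neutral, so
low coverage there is an assay failure). It does **not** remove probes from
the normalization mean or from case-sample ratios: a deletion manifests
precisely as low coverage, and homozygous deletions (ratio ~0) must remain
visible. This also preserves the assay's one documented false-positive
mechanism — a large heterozygous deletion spanning many normalization
probes drags $X_i$ down and inflates every other ratio — which the test
suite asserts directionally rather than corrects, because the published
behaviour is the reference.

## The simulator

`simulateCounts()` draws, for probe $k$,
$\mathrm{Poisson}\bigl(D \cdot e_k \cdot \tfrac{c_k}{2} \cdot
\varepsilon_k\bigr)$ where $D$ is the target depth (default 1000 reads per
probe, the assay's required median coverage), $e_k$ a fixed per-probe
efficiency multiplier (lognormal, log-SD 0.25, drawn once per run and shared
by all libraries so it cancels against the baseline exactly as real probe
biases do), $c_k$ the local copies from the truth set's mixture model, and
$\varepsilon_k$ multiplicative lognormal noise with ratio-scale SD 0.103 —
the empirical per-probe control SD at the assay's operating point. Only the
empirical SD is known, not the generative law; lognormal keeps counts
positive and the noise multiplicative, which matches how the ratios are
formed. The single noise knob deliberately conflates biological, library and
counting variability, as the empirical figure does. Dropout (zero-inflation)
models FFPE/low-input degradation; quality tiers map to (noise multiplier,
dropout) pairs: very_good (1, 0), good (1.2, 0), moderate (1.5, 0.01), poor
(2, 0.05), very_poor (3, 0.10) — the underlying gel-based tiers are
qualitative, so these mappings are the simulator's own calibration.

`simulateDesign()` generates random non-colliding 25-base hybridising arms
(~60 bp ligated inserts, matching the assay's amplicon length);
`preset = "table1"` reproduces the published panel's per-gene probe counts
(157 probes over BRCA1/BRCA2/PTEN, six amplification-surveillance genes,
NF1, RB1, four PTEN-deletion-confirmation genes and seven reference genes).
The published 98/100 detection/confirmation partition cannot be
reconstructed from the per-gene counts alone, so the preset records its own
partition (94/80, with amplification, single-target and reference probes in
both mixes — each library is normalised independently and therefore needs
reference probes) directly in the design table. `simulateFastq()` renders a
count table as reads (insert + downstream adapter, padded to 150 cycles,
constant quality) whose recount is exact, closing the loop between the
counting and quantification stages.

What the simulator does *not* emulate: sequencing errors, chimera formation,
index hopping, PCR duplicates, GC/length bias, SNVs under ligation sites,
and real inter-patient variability. Passing simulation-based tests therefore
demonstrates the pipeline's arithmetic and logic under the assay's stated
noise model, not clinical performance on specimens.

## Problem sizes and numerical choices

The packaged checks run, by choice, at desk scale: the cohort evaluation
uses the 157-probe panel preset with 8 controls plus 50 single-event blood
cases at default noise and depth (≈4,500 truly diploid exon tests), the
noise-propagation check uses $10^5$ two-probe exons, and FASTQ-level
round-trips use single libraries of 10⁴–10⁵ reads. Determinism: every
simulation takes an explicit integer seed; cohort generation derives
per-stage seeds from it. Tolerances: depth-normalised non-amplification
means equal 1 to 1e-12; the noise-propagation SD is accepted within ±0.005
of 0.072; classification uses exact comparisons on the stated bands.
Degenerate inputs: a zero normalizer is a hard error (unusable library);
probes with zero baseline mean or above-cap CV are excluded from ratios with
recorded reasons; exons with no usable probes are emitted as `missing`,
never dropped. Ties/boundaries: band edges fall to `normal`
(conservative), and 0.3 falls to homozygous deletion per its "or less"
definition.

## Known limitations

- The deletion-skew false-positive mechanism is reproduced, not corrected.
  A median-based $X_i$ would mitigate it but would depart from the
  reference behaviour; it is available as a documented extension point, not
  a default.
- Relative dosage only: a genome-wide ploidy shift rescales every ratio and
  is invisible to the assay.
- Sex chromosomes are out of scope (all panel genes are autosomal); the
  diploid reference is a single constant.
- Segmentation is run-length merging of identical categories within a gene;
  no CBS/HMM, no breakpoint estimation, no significance testing of calls.
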