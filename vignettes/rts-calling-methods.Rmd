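---
title: "Methods: simulating and calling rG4-induced RT stalling"
author: "quadstop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calling rG4-induced RT stalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadstop)
```

# Scope and model

`quadstop` implements the computational side of rG4 detection by
reverse-transcriptase stalling (RTS): RNA fragments reverse-transcribed
under K⁺ stall at folded G-quadruplexes, while a Li⁺ library of the same
sample reads through. The 5′-most aligned base of a template-strand read is
the stop position; positions with a significant K⁺-over-Li⁺ excess of stops
are merged into RTS sites and classified structurally from their upstream
sequence. Because the analysis is driven by a ground-truthed simulator, the
statistical behaviour of every stage (FDR control, recovery, bias) is
measurable rather than assumed.

## The per-position test

For a position with stop/coverage counts $(s_K, n_K, s_{Li}, n_{Li})$ we
test $H_1$: K⁺ stop rate > Li⁺ stop rate with the one-sided exact
conditional test on the 2×2 stop/read-through table — the hypergeometric
upper tail with all margins fixed, identical to the one-sided Fisher exact
test (computed vectorised via `phyper`; the test suite cross-checks it
against `fisher.test` and a direct enumeration of the conditional
distribution). The upstream method delegates this step to an external
caller whose internal noise model is not printed anywhere we could
reimplement it from; a transparent, replicate-free exact test plus
Benjamini–Hochberg control was chosen instead and is pluggable through
`callerConfig(test = )`. Whether stops should be contrasted against local
read-through (as here) or a transcript-wide background is not decidable
from the published description; the 2×2 read-through contrast is a design
decision, not an inference of intent.

Gating and correction:

* only positions with $n_K \ge$ `minCov` (default **16**, the typical
  coverage needed for stall detection) are tested; positions with zero Li⁺
  coverage are not testable and are counted separately;
* BH is applied across all tested positions of a run, and a position is
  called when the adjusted p ≤ `alpha` (default **0.05**) *and* the
  empirical K⁺ rate exceeds the Li⁺ rate;
* called positions at gap ≤ `mergeGap` (default **1** nt, the position-0/+1
  anatomy of a stall) merge into one site; singletons are 1-nt sites.

## Classification

Classes are tried in a fixed priority order — canonical, long-loop, bulged,
two-quartet, G-triplex, then "Others" — and the first pattern whose 3′ end
lies exactly at the anchor wins. The anchor is tried at offsets 0 and 1
upstream of the site start, implementing stalls at the motif's 3′-most G
and at its +1 flank. The exact patterns (G-run minima 3, or 2 for
two-quartet; loops 1–7 nt; one long loop 8–12 nt; one 1–7 nt non-G bulge in
a single tract; search window W = 50 nt) are inherited conventions of
G-quadruplex sequence analysis rather than values printed in the source
study, so every one of them is exposed in `classTaxonomy()`. The grouping
used for reporting (canonical → "canonical"; long-loop, bulge →
"non-canonical"; two-quartet, G-triplex → "variant") is likewise
configuration: the membership of the reported groups is nowhere enumerated
in the study this design follows, and a user may regroup freely. The
classifier is verified in the test suite against a regex-free recursive
segmentation oracle on random sequences.

# The simulator and what it does (not) emulate

`simConfig()` fixes the study conditions; the defaults were set once, as
follows, and are not data-fitted:

| parameter | default | rationale |
|---|---|---|
| transcripts | 30, 600–1500 nt | enough positions (~30 k) for FDR behaviour at desk scale |
| abundance | log-normal (meanlog 1, sdlog 1), scaled to 10⁶ TPM | right-skewed bulk transcriptome |
| fragment length | 250 ± 50 nt | heat fragmentation targeting ~250–300 nt |
| θ (stall prob.) | canonical 0.9, long-loop/bulge 0.7, two-quartet/G-triplex 0.4 | decreasing structural stability; variant classes get a per-replicate logit jitter (sd 0.3) reflecting their higher stochasticity |
| stop split | 0.6 / 0.4 between positions 0 / +1 | both anchors observed, 3′-most G favoured |
| background stop ε | 10⁻³ per position, both conditions | sparse spontaneous stops |
| UMI | 10 nt, 5′ of mate 1 | the real protocol does not locate or size its UMI; an abstract 10-mer gives a collision-free key space |
| duplication | 1 + Poisson(12 · cycles / input_ng), 11 cycles | mean PCR copies inversely proportional to input, so library complexity scales with input |
| depth | 20 000 read pairs/library | desk-scale stand-in for 10⁸-pair libraries |
| fates | 5% adapter-only, 10% unalignable, 5% multimapped | ~80% usable reads, the retention regime of a well-behaved library |
| 5′-nt bias | protocol 2.0: 35% A; protocol 1.0: 65% A | the read-start compositions characteristic of the two adapter chemistries |

The 5′-nucleotide bias is modelled as acceptance sampling on the transcript
base at the stop position — the minimal mechanism that reproduces a
protocol-level read-start composition without simulating ligation
chemistry. The acceptance weights are the target frequencies
importance-corrected by the transcriptome's own base composition; without
that correction the realised distribution would be the product of the two
and overshoot the target. Background sequence contains no G–G dinucleotide,
so planted motifs are the only quadruplex-compatible sequence and
sensitivity/false-positive accounting against the truth tables is exact.

Deliberately not modelled: sequencing errors (hence exact-match UMI
deduplication; a mismatch-tolerant mode is left unimplemented), genome
coordinates and splicing (everything is transcript-space, plus strand),
polyA-selection chemistry, and secondary structure of the adapters
themselves. Consequently, passing tests demonstrate the statistical
correctness of the workflow under its stated model — they do not
demonstrate robustness to alignment artefacts, UMI errors or annotation
ambiguity in real data.

# Numerical and degenerate-input choices

* **Scission placement.** USER II cleavage is modelled immediately 5′ of
  each dU with the dU retained on the downstream fragment; this is the only
  placement consistent with both printed fragment pairs (44 → 23 + 21 and
  106 → 85 + 21). The chemically real loss of the excised base is ignored
  because the fragment arithmetic is stated length-conserving.
* **Ligated-product orientation** is cDNA(5′) → adapter(3′), forced by the
  85/21 arithmetic and the adapter's 5′ phosphate.
* **Gel metrics** outside [0, 100] (noisy densitometry, e.g. E > D) are
  clipped and flagged rather than propagated; zero denominators are errors
  naming the formula.
* **Overlap distance** between sites is measured between nearest span
  boundaries with strict `< 5` nt; span overlap is distance 0. The distance
  anchor is unspecified upstream, so boundary distance was fixed here.
* **Guideline intervals** are half-open [4, 8), [8, 16), [16, ∞): the
  printed ranges share endpoints, so a convention was required.
* **Coverage regression** runs in log10 space — with 10–1000× coverages a
  slope/intercept is only interpretable on a log scale.
* **Dedup ties** are broken by lexicographic read id, making the survivor
  deterministic; saturation subsamples are nested prefixes of one seeded
  permutation, making curves non-decreasing by construction.
* **Subsampling** above the available depth returns the input unchanged (no
  up-sampling), matching the stated subsampling protocol.
* **Zero-coverage positions** in either condition are untestable and
  flagged; depth-0 simulations return empty libraries, not errors.
* The "66-nt" versus 62-nt description of the cDNA mimic in the source
  material is resolved as 40 + 22 = 62 nt.

# Problem sizes

The suite and the acceptance script run at desk scale, chosen once: default
simulations use 30 transcripts × ~1 kb × 20 000 read pairs; null-model FDR
checks pool 20 seeded runs of 8 background-only transcripts × 4 000 pairs;
the classifier-oracle comparison uses 1 000 random 60-nt sequences; the
end-to-end determinism check runs the full pipeline twice at 2 500 pairs
and compares md5 sums of every artifact. Canonical-motif recovery is scored
over motif-replicate pairs whose local K⁺ coverage reaches 32×, pooling
both replicates because a single small-scale replicate can leave very few
motifs above that coverage.

# Known limitations

* The exact per-position test is conservative at low counts (discrete
  tables); the realised null call rate is far below the nominal FDR level.
* Replicate handling is call-then-intersect (consensus = agreement of
  per-replicate calls anchored on the first list); no joint replicate model
  is fitted.
* TPM is computed by direct counting on single-isoform transcripts; no
  EM-style isoform deconvolution is attempted or needed at this scale.
* The Alexander–Govern comparison requires ≥2 values per group and fails on
  zero within-group variance by design.
* Real-data ingestion is limited to the documented aligned-read TSV;
  BAM/SAM parsing is intentionally out of scope here.

```{r session}
sessionInfo()
```
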