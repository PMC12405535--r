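---
title: "Methods: barcoded biosensor screening with memory circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcoded biosensor screening with memory circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening system

The pipeline analyses pooled screens of bacterial biosensor libraries built
on a λ-phage memory circuit. Each library strain carries (i) a sensing
component — typically a heterologous two-component system (TCS) or a
promoter region — driving expression of a dominant-negative cI, and (ii) a
unique 106-bp hypervariable DNA barcode. Transient activation of the sensor
flips the cI/cro bistable switch irreversibly ON, de-repressing *lacZ* and
the *aadA* spectinomycin-resistance cassette. After exposure to a test
condition (an in vitro culture or transit through the mouse gut), the pooled
population is split into paired cultures grown with and without
spectinomycin. Because spectinomycin is bacteriostatic, OFF cells persist in
the selective culture without replicating while ON cells grow by the
outgrowth fold change; comparing each barcode's read counts between the two
cultures therefore measures the fraction of its population that switched ON.

`sensorscreen` implements the desk side of this workflow end to end:

1. **`tcs_miner`** — find "grouped" TCSs in annotated genomes and check
   Golden Gate (Type IIS) cloning compatibility.
2. **`barcode_caller`** — derive reference barcodes from short-read amplicon
   data.
3. **`assigner`** — link barcodes to sensors with long reads spanning the
   sensor–barcode junction.
4. **`for_quant`** — quantify activation as fractional odds ratios (FOR).
5. **`qc`** — the three sample-level quality gates and recovery fractions.
6. **`ranker`** — rank condition-responsive sensors.
7. **`synthetic_data`** — a fully seeded simulator providing ground truth
   for all of the above.

## Grouped TCS mining

Most histidine kinases (HK) are encoded within 200 bp of their partner
response regulator (RR). When such a pair sits head-to-head with a
divergently transcribed neighbour, the shared intergenic region plausibly
contains the promoter the pair regulates, and the whole sensing unit
(HK + RR + promoter) can be cloned as one PCR product. The miner:

- pairs every HK with every RR on the same contig and strand whose
  inter-gene gap (`downstream start − upstream end − 1`, 1-based inclusive
  coordinates) is strictly below 200 bp. Overlapping genes are treated as
  gap 0 and flagged rather than rejected. Both genomic orders (HK→RR and
  RR→HK) are accepted — annotations do not reliably order the operon;
- classifies a pair as *grouped* when the nearest annotated gene upstream of
  the pair's transcriptional 5′ end lies on the opposite strand (both
  transcription units point away from the shared intergenic region), with no
  intervening gene and within a 5 kb search window (configurable; the
  biology rarely separates a regulated divergent gene further);
- extracts the sensor region from the boundary adjacent to the divergent
  gene's start codon (the codon itself excluded, since the cloned construct
  replaces the divergent ORF with the memory trigger) through the far end of
  the pair, reverse-complemented so the pair always reads 5′→3′;
- scans both strands for SapI (GCTCTTC) and BsaI (GGTCTC) recognition sites;
  any internal site makes the part incompatible with the corresponding
  Golden Gate strategy. `N` bases never match and so never create
  false-positive sites.

HK/RR roles are taken from a classification table rather than a live
database query, keeping the module offline and testable.

## Barcode calling

Reads from the barcode amplicon are dereplicated, filtered to exactly
106 bp, and clustered greedily at 95% global identity: sequences are
processed in descending-count order (ties broken lexicographically) and each
joins the first existing centroid at ≥ 95% identity, else founds a new
cluster. The processing order guarantees each cluster's reference is its
highest-count member; member counts are summed onto the reference.

Identity is defined as matching columns divided by alignment length under
an optimal global alignment with unit scores (match +1, mismatch −1,
gap −1), so gaps count against identity. The original workflow denoises
reads with DADA2 before clustering; this package substitutes plain
dereplication (optionally dropping singletons) because the 95% clustering
step absorbs substitution-error structure — at a per-base error rate of
10⁻³, an erroneous read carries on average ~0.1 substitutions and clusters
back to its barcode whenever it carries ≤ 5 edits. A re-implementation of
the DADA2 error model is deliberately out of scope. The cost of the
substitution is that rare true barcodes within 95% identity of an abundant
barcode would be absorbed; the library design works against this case
(random 106-mers are pairwise ~55% identical).

## Barcode–sensor linkage

Long reads spanning the sensor and barcode are processed in three steps:

1. **Adapter trimming and length filtering.** One leading and one trailing
   adapter occurrence are removed, allowing ≤ 5 substitutions with ≥ 10
   adapter bases present (occurrences may overhang the read ends).
   Mismatches must additionally stay below a quarter of the matched overlap
   — without this cap, "5 mismatches in a 10 bp overlap" is satisfied by
   random sequence and adapter-less reads are falsely clipped. Reads are
   then required to exceed 400 bp, enough to cover at least part of both
   the sensor and the barcode.
2. **Sensor alignment and tail extraction.** Each read is aligned to all
   sensor references (barcode regions excluded) with an end-gap-free
   (overlap) alignment; candidates are pre-selected by shared 11-mers. The
   best *score* wins — selecting by identity would let a short spurious
   end-overlap at 100% identity outrank a full-length alignment at the
   ~93% identity expected from long-read error — and the winner must still
   reach 75% identity over its aligned span. Score ties leave the read
   unaligned. The read suffix extending past the reference 3′ end is the
   candidate barcode tail; a read contained inside the reference yields an
   empty tail and contributes no barcode evidence.
3. **Dual-criterion assignment.** For each reference barcode, tails are
   matched against the barcode set (same overlap alignment, ≥ 80% identity
   over the barcode span, ties contribute nothing). A barcode is assigned
   to sensor *s* only when *s* maximises **both** the supporting read count
   and the count normalised by the sensor's total long reads, uniquely, with
   at least 5 supporting reads. Disagreement between the two criteria or a
   tie in either discards the barcode as ambiguous; the normalisation
   criterion protects low-coverage sensors from being out-voted by deeply
   sequenced ones. Sensor totals are counted after sensor alignment, before
   barcode matching.

## Fractional odds ratio

For one barcode with reads `BC₊` and `BC₋` in the ±spectinomycin cultures
and positive-normalisation barcodes (constitutively ON strains inside the
library) with counts `PNB₊`, `PNB₋`:

$$OR = \frac{BC_{+}/\mathrm{mean}(PNB_{+})}{BC_{-}/\mathrm{mean}(PNB_{-})},
\qquad FOR = \frac{OR - OR_{neg}}{OR_{pos} - OR_{neg}}$$

where `OR_pos` and `OR_neg` are arithmetic means of the positive and
negative control strains' ORs (the geometric mean appears only in the
fold-change QC, where the paper names it). A fully ON sensor has OR ≈ 1 and
FOR ≈ 1; a fully OFF sensor has OR ≈ 1/G (G the outgrowth fold change) and
FOR ≈ 0. FOR is reported unclipped — values slightly outside [0, 1] carry
information about normalisation noise; clipping is a display decision.

No pseudocounts are used: a barcode with zero −spectinomycin reads has an
undefined OR and is expected to fail the abundance QC; it is flagged, not
patched. Sensors are summarised either as the median FOR over their
QC-passing barcodes (`median` mode) or, for libraries with very many
barcodes per sensor where individual barcode counts are shot-noise limited,
by pooling the sensor's counts before computing OR/FOR (`pooled` mode).
Pooling is triggered by configuration, not inferred: the underlying
"roughly 10-fold more barcodes" judgement belongs to the analyst.

A sensor is called *potentially activated* when FOR strictly exceeds 0.01,
i.e. roughly 1% of its population switched — the lowest level at which
biologically meaningful activation has been observed in this system.

## Quality control

Gates run in a fixed order: positive-barcode exclusion → outgrowth gate →
abundance filter → OR/FOR → fold-change gate.

- **Positive-barcode exclusion**: positive-control barcodes with < 100 reads
  in either culture are dropped from normalisation (low-abundance controls
  add noise exactly where precision matters most).
- **Outgrowth gate**: OLS fit of +spectinomycin vs −spectinomycin read
  fractions across the usable positive barcodes, each normalised within the
  positive-control set so uniform outgrowth gives slope 1 and R² 1
  regardless of the library's overall ON fraction (normalising against
  whole-library totals would make the expected slope depend on mean library
  activation). Pass requires R² > 0.6 and 0.5 < slope < 2; at least 3 usable
  positives are required for a meaningful fit. This catches differential
  lag-phase artefacts among supposedly identical ON strains.
- **Abundance filter**: barcodes must exceed 1/5000 of the −spectinomycin
  culture's reads (strict inequality). The unselected culture is used
  because only it reflects total library composition. The threshold is
  motivated by cell numbers: 1/5000 of a stationary culture at 10⁸–10⁹
  CFU/mL, split 1:1000, is only 20–200 CFU/mL — below that, which culture a
  cell lands in is a coin flip.
- **Fold-change gate**: geometric-mean positive OR over geometric-mean
  negative OR must exceed 30; smaller separation means the selective
  outgrowth was too weak to distinguish ON from OFF. Zero ORs are excluded
  from the geometric means; if nothing usable remains the sample fails with
  an insufficiency reason.

A sample passes overall iff the outgrowth and fold-change gates pass.

## Ranking

Sensors must be OFF in the gavage (inoculum) sample — gavage FOR < 0.25,
strict — to be rankable; a sensor already ON going in cannot report on the
condition. Scores are unweighted mean differences over QC-passing samples:
`mean(faecal FOR) − gavage FOR` for general in-vivo responsiveness, or
`mean(treatment FOR) − mean(control FOR)` for condition specificity (day-2
samples by convention; configurable). Ties break by sensor id. Ranking is
invariant to sample order and to affine rescalings of all FOR values (any
common positive-scale affine map preserves score order); it is *not*
invariant to general monotone transformations, since the score is a
difference of means.

## The synthetic world

The simulator states a complete, seeded world so that every downstream
module can be validated against known truth:

- **Library**: `n_sensors` (default 60) library sensors plus 3 positive
  control sensors sharing 14 barcodes (f = 1 everywhere) and one negative
  sensor with 6 barcodes (f = 0). Barcodes per sensor are log-normal with
  median 5 (the small-library regime; a large promoter library would use
  median 52) clipped to [1, 1000]; per-barcode abundances are log-normal
  (sdlog 1, matching the orders-of-magnitude spread seen in real libraries)
  and normalised. Barcode sequences are rejection-sampled so every pair is
  below 80% global identity — real random 106-mers essentially always are,
  and the cap is what makes the clustering guarantees provable.
- **Growth model** (relative-abundance algebra): −spectinomycin composition
  equals the library composition; +spectinomycin abundance is
  `a·(f·G + (1 − f))` — ON cells grow by G, OFF cells persist unreplicated
  (bacteriostatic selection). This yields `E[OR] = f + (1 − f)/G` and
  `E[FOR] = f` exactly; the noiseless mode reproduces `FOR = f` to machine
  precision, which is the pipeline's strongest self-consistency check.
  G defaults to 1000 (the 1:1000 in vitro dilution; in vivo work uses
  1:100).
- **Reads**: multinomial sampling at 2×10⁵ reads per culture (scaled down
  from the ~1.4 M of a production run; the statistics of interest converge
  well before that). Short reads carry i.i.d. substitutions at 10⁻³ per
  base; long reads are adapter + sensor reference + barcode + adapter with
  7% per-base error split 75% substitutions / 25% geometric-length indels
  (continuation 0.3) — nanopore-era error structure. Simulated sensor
  references are 500 bp (real sensor regions are kb-scale; shortening them
  only shrinks alignment problems, not the logic being tested).
- **Distortions**: optional log-normal per-barcode, per-culture lag-phase
  multipliers exercise the outgrowth gate (its failure rate rises
  monotonically with the multiplier variance); a colonisation bottleneck is
  a multinomial draw of `n_cells` over abundances, survivors being barcodes
  with ≥ 1 cell. The real in-vivo bottleneck size is unknown, so
  `bottleneck_size` is a free parameter rather than a calibrated one.

All randomness flows from the single `seed` in `sim_config()`; identical
configurations reproduce identical FASTQ bytes.

### What a green test does and does not establish

The simulator emulates composition, selection, sampling and sequencing
error. It does **not** emulate chimeric long reads, PCR jackpotting,
quality-score structure, strain fitness differences other than lag-phase
multipliers, or any host/microbiota biology. Green end-to-end tests
therefore establish the pipeline's correctness *given the stated error
model*, not the platform-specific behaviour of a particular sequencer — the
QC gates exist precisely because real samples violate the clean model in
ways the gates are designed to catch.

## Numerical choices and degenerate inputs

- Alignment scoring is unit (+1/−1/−1) throughout; identity denominators
  are alignment lengths, so gaps penalise identity. The clustering
  threshold test `identity ≥ 0.95` is exact: a q-gram lower bound on edit
  distance and an equal-length Hamming shortcut only skip alignments whose
  outcome is already decided.
- Greedy clustering joins the *first* qualifying centroid (not the best);
  with the count-descending order this matches the stated contract and is
  deterministic.
- Strict inequalities everywhere the thresholds are stated as strict:
  gap < 200, fraction > 1/5000, FC > 30, FOR > 0.01, gavage FOR < 0.25.
- Undefined ORs (zero −spectinomycin reads) are `NA`, excluded from control
  means, and fail barcode QC; zero ORs are excluded from geometric means.
- `or_pos ≤ or_neg` is an error (such a sample necessarily fails the
  fold-change gate); an outgrowth fit with < 3 usable positives fails with
  a reason instead of fitting a meaningless line.

## Known limitations

- The q-gram/Hamming accelerations make clustering quadratic in the number
  of *distinct* sequences in the worst case; libraries far beyond ~10⁴
  uniques would want a k-mer index over centroids.
- Tail-to-barcode matching assumes the barcode follows the sensor on the
  read strand, as in the library design; reads from the opposite strand
  should be oriented upstream.
- `pooled` mode reports per-sensor units; barcode-level heterogeneity
  (informative about replicate variability) is unavailable there by
  construction.
- The miner trusts the annotation: unannotated ORFs in the intergenic
  region cannot be detected, and pseudo-genes count as genes.
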