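---
title: "umivar: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{umivar: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umivar)
```

`umivar` calls low-frequency variants from UMI-tagged, primer-anchored
amplicon sequencing of cell-free DNA, and provides the statistical
machinery to validate such an assay against reference standards. This
vignette records the model, the assumptions behind each processing stage,
the tunable parameters, and the design decisions taken where the
underlying procedure admitted more than one reasonable choice.

## The error model the pipeline is built around

Sequencing circulating tumour DNA at variant allele frequencies (VAF)
around 0.1% means the signal sits one to two orders of magnitude below
the raw per-base error rate of short-read sequencers (~0.1–1%). The
pipeline attacks this with molecular redundancy at three levels:

* **Within a read pair.** Both mates cover most of the fragment. Base
  calls below Phred 20 in the primary read are overwritten from the mate
  when the mate is confident, so isolated late-cycle errors are repaired
  before any downstream step.
* **Within a UMI family.** Every original molecule carries a unique
  molecular identifier. PCR and sequencing copies of one molecule are
  collapsed by per-position majority vote, requiring at least three
  copies (UMI >= 3). An error must recur in the majority of a family to
  survive — for independent per-copy errors at rate $e$ this drives the
  consensus error to order $e^2$.
* **Across fragments.** Calls are restricted to a whitelist and
  thresholded on frequency (default 0.09%), so residual consensus errors
  must both match a known target allele exactly and recur in several
  independent molecules.

The deliberate asymmetry — a restrictive whitelist, an exact long-indel
search, a disparity cap, N never supporting a call — trades false
negatives for false positives, which is the right trade for a
confirmatory clinical panel.

## Stage by stage

### Pair merging

Read 2 is reverse-complemented and anchored to read 1 by the longest
suffix–prefix overlap with at least 20 shared bases and at most 10%
mismatches; non-overlapping tails are concatenated. The library geometry
is `[primer <= 44][insert][constant region][UMI][adapter]` on the
sequenced strand, so read 1 starts at the primer and read 2's first
cycles read the UMI — which is why the correction rule inverts in the
terminal UMI segment (read 2 primary there). Corrected positions inherit
the donor base's quality. When both mates are unreliable the primary base
is kept rather than masked: the family vote downstream is the error
filter, and masking would discard information the vote can still use.
Pairs with no acceptable overlap are rejected (`no_overlap`) — under the
default 2 x 150 read length this also bounds the usable fragment length
at 280 nt, and with cfDNA-like 200–300 nt fragments it removes about 20%
of molecules, uniformly with respect to variant status.

### Fuzzy identification and trimming

Primer and constant region are located by an edit-distance ("fuzzy")
search that tolerates up to `floor(0.10 * pattern length)` Levenshtein
operations — substitutions, insertions and deletions all count one.
`floor` means patterns shorter than 10 nt must match exactly. The primer
is sought within the first 44 bases (the maximum primer length); among
acceptable primers the fewest-edits match wins, with ties going to panel
order. Reads whose primer or UMI cannot be determined (UMI containing
`N`, or truncated) are dropped and logged.

### Family collapsing

Families are exact partitions on the key (primer, UMI): no UMI
error-correction networks are applied, because the consolidation being
emulated is exact and UMI errors at realistic rates only fragment a
family (biasing depth slightly down, never calls up). Voting is
restricted to members of the family's modal length — indel sequencing
errors are rarer than substitutions, and mixing lengths would misalign
every position after the indel; ties on modal length go to the shorter
length. Vote ties at a position fall to the larger summed Phred; a still
unresolved tie yields `N`, and `N` never supports a variant call.

### Alignment and variant extraction

Each consensus fragment is aligned to the reference window addressed by
its primer (the segment slice from the insert offset, padded by 15 bp to
tolerate indels) with a semi-global dynamic program: the fragment aligns
end to end, reference overhangs are free. This is the right asymmetry
because primer anchoring guarantees the fragment lies inside its window.
A gap of length $k$ costs `gap_open + (k-1) * gap_extend`; a linear model
is the special case `gap_open == gap_extend`. Three default schemes span
the gap-tolerant/mismatch-tolerant space:

| scheme | model  | match | mismatch | gap open | gap extend |
|--------|--------|------:|---------:|---------:|-----------:|
| S1     | linear | +1    | -1       | -2       | -2         |
| S2     | affine | +1    | -1       | -6       | -1         |
| S3     | affine | +2    | -3       | -5       | -2         |

All schemes are run and the alignment with the fewest variant events is
selected (ties: higher score, then scheme order). Counting events —
one MNP or one indel run is one variant — a fragment with more than
twelve is "too disparate" and discarded; an MNP counts once because the
MNP class exists precisely to group adjacent substitutions. Traceback is
deterministic (diagonal > up > left on equal scores), and extracted
indels are explicitly left-aligned against the reference before being
compared with the whitelist, so representation ambiguity cannot leak
into calling. Indels longer than 10 bp are excluded here: they belong to
the long-indel search, which matches the event plus 5 bp flanks exactly
(one mismatch defeats it by design).

A fragment identical to its reference slice short-circuits the dynamic
program with zero variants; this is purely an optimisation, since a full
end-to-end match is optimal under every scheme with positive match score.

### Tabulation

For each whitelist variant, coverage is the number of emitted fragments
whose aligned span covers the position and count the number supporting
the alternate allele; frequency is `count / coverage * 100`, compared
inclusively against the global threshold (a variant *at* the threshold
passes — the assay is specified as calling down to that frequency). The
table always contains every whitelist and long-indel target, with
zero-count rows for absent ones. Long-indel rows use fragments assigned
to the anchor's primer window as denominator. Frequencies are written to
4 decimals but thresholded unrounded.

## The validation suite

Classification follows the reference-standard logic: at positive VAF
levels an expected variant is a true positive when detected and a false
negative otherwise; at the 0% level any call is a false positive and any
absence a true negative. Per-positive-level predictive values and
accuracy borrow the single 0%-level fp/tn, and pooled counts take them
once — this is the only arithmetic consistent with computing PPV/NPV at a
level where no true negatives were assayed.

Confidence intervals are exact Clopper–Pearson from beta quantiles, with
the conventional closures at `k = 0` (lower bound exactly 0) and
`k = n` (upper bound exactly 1). The implementation agrees with
`binom.test` to machine precision; the test suite uses that agreement as
an independent oracle.

The limit of detection is modelled as a simple logistic regression of
per-trial detection outcome on VAF in percent, untransformed, fitted by
maximum likelihood; `lod_fit()` returns a classed model object with
`print`/`summary`/`coef`/`predict`/`plot` methods, and
$LOD_{90} = (\mathrm{logit}(0.9) - \hat\beta_0)/\hat\beta_1$. Two
modelling choices deserve note. First, the 0% level is **included** in
the fit: its false-detection floor anchors the curve's left end, and the
resulting LOD90 on the reconstructed validation design is 0.179% VAF,
whereas excluding it shifts the estimate to 0.198% — the included fit is
the configuration frozen in the acceptance tests. Second, the covariate
is left untransformed by default (matching common "simple logistic
regression" behaviour in GUI statistics packages); a log10-VAF option
exists but is off by default. Perfect separation is detected before
fitting and reported as an error suggesting more levels, since the MLE
does not exist there.

The threshold scan recomputes specificity and sensitivity over a
candidate grid (default 0.01–0.50% by 0.01) with detection redefined as
`frequency >= t`, choosing the smallest threshold meeting the target
specificity (default 95%). Replicate condensation declares a variant
present when backed by at least two of three replicates.
Reproducibility checks measurements against `expected ± 50% * expected`
(at the 0.5% level: 0.25–0.75%).

## The simulator

`simulate_standard()` emulates a spiked-variant cfDNA reference standard:

* per locus, `round(input_mass_ng * copies_per_ng)` original molecules
  (defaults 20 ng x 300 haploid genome equivalents/ng = 6000; one
  haploid genome is ~3.3 pg);
* variant status per molecule is Bernoulli at the configured VAF, and
  the drawn variant count is recorded exactly in the truth table;
* fragment length uniform in 200–300 nt (cfDNA-like), a random UMI
  (12 nt), and a configurable 11-nt constant region;
* PCR as 1 + Poisson(λ = 5) copies, with polymerase substitutions
  (default 1e-5/base) applied in two stages: once to the molecule
  template, so those errors propagate to all copies (the jackpot
  effect that produces realistic sub-threshold noise), and once
  independently per copy;
* sequencing errors per cycle at `10^(-Q/10)` under a declining profile
  (plateau Q37 over the first half of the read, linear decay to Q25 at
  the last cycle), reflecting quality decay under sequencing by
  synthesis.

`simulate_panel_run()` derives per-(level, replicate) seeds
deterministically from the master seed, so a design is reproducible
run to run and file by file.

What the simulator does **not** emulate: instrument-specific error
spectra, GC and strand bias, index hopping, non-uniform cfDNA
fragmentation, and the ~150,000x raw depth of a production assay (the
desk-scale default of 6000 molecules/locus yields ~4600 consensus
fragments after the overlap and family-size filters, comparable to a
collapsed depth of ~5000x). Passing the end-to-end tests therefore
demonstrates the pipeline's arithmetic, filtering and statistical
behaviour under a realistic molecular-counting model — not robustness to
every artefact class of real instruments.

## Problem sizes and numerical choices in the tests

The end-to-end validation test simulates the full design — 20 targets,
4 VAF levels (0, 0.125, 0.25, 0.5%), 3 replicates, 6000 molecules per
locus — and runs the complete pipeline on all 12 samples; at roughly
720,000 read pairs per sample this is the package's deliberate
desk-scale operating point. Oracle-equivalence tests run the alignment
kernel against an independent plain-R dynamic program on 500 random
pairs per scheme, the fuzzy matcher against brute-force enumeration of
all substrings on 1000 instances, and family voting against exhaustive
enumeration of two-letter families. Stochastic checks (consensus error
bound, interval coverage, LOD recovery) use fixed seeds and state their
Monte-Carlo allowances explicitly next to the bound being tested.

Degenerate inputs are defined behaviour throughout: empty FASTQ yields a
complete zero-count table; a whitelist target without coverage is
reported with frequency 0 and a failing flag; metrics with empty
denominators are absent with a reason rather than NaN; and ties at every
decision point (fuzzy match location, scheme selection, traceback, vote)
break deterministically, so identical inputs always produce
byte-identical outputs.

## Known limitations

* Exact (primer, UMI) grouping slightly deflates family sizes when UMIs
  themselves acquire errors; with 12-nt UMIs and post-merge error rates
  this loses depth, not specificity.
* The aligner is windowed and primer-anchored by design: structural
  variants, split reads and off-panel events are out of scope, and long
  indels are only found if predefined.
* The linear gap scheme can split a multi-base indel into equal-scoring
  pieces; the least-variants selection across schemes is the intended
  mitigation, and left-alignment fixes the representation of what
  remains.
* The logistic LOD model assumes a monotone detection curve across
  levels pooled over targets; strongly target-specific detection would
  call for a mixed or stratified model.
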