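---
title: "Consensus copy-number calling: model, parameters and design notes"
author: "cnvConsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus copy-number calling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvConsensus)
```

# The consensus model

`cnvConsensus` combines three styles of CNV caller output, each with a known
failure mode, into one absolute copy-number profile:

* a **coverage** (read-depth) caller: gap-free absolute copy numbers,
  trusted for deletions and the normal state, but systematically biased —
  its CN frequency histogram peaks slightly off the ploidy;
* a **hybrid** caller (read depth + read-pair signal): trusted for
  amplifications, not gap-free, reporting either log2 ratios against a
  matched sample or non-negative ratios against a simulated zero-coverage
  null alignment, the latter with a distortion that grows exponentially with
  the true amplification;
* a **referee** caller: reliable deletion/amplification *direction*,
  useless magnitudes.

The pipeline (`callConsensus()`) has five stages: harmonisation,
threshold estimation, breakpoint-union segmentation, per-bin rule
application, and merging.

## Harmonisation

The coverage caller's bias is estimated from a length-weighted histogram of
its values: `bias = P - peak_cn`, where the peak is the local maximum
nearest the ploidy `P`. The correction applied to a value `CN` is
`factor * bias` with `factor = min(CN/2, 1)` — small copy numbers show less
bias and are corrected less — and is clamped to ±0.5 CN units. We read the
0.5 cap as a clamp on the *applied* correction (`factor * bias`), not on the
bias estimate itself, since it is the correction that must stay bounded; the
implementation additionally guarantees the bound in floating-point
arithmetic, not only in exact arithmetic.

Matched-sample log2 ratios are centred by the genome-wide median
(length-weighted over bins, since bins differ in size) and mapped as
`P * 2^(log2 - median)`; by construction the weighted median of the output
is the ploidy. Null-alignment ratios `cn` are corrected multiplicatively
with the equalizer `q(cn) = (1 + cn/100)^(0.75 cn)`, which is the identity
at 0, strictly increasing, and at least the identity for positive values.
Referee values are never rescaled because they are never used numerically.

## Thresholds

`T2` is the CN at the local minimum of the normalised coverage histogram
inside the search window (default [2, 2.3] for `P = 2`), with
`T1 = 2P - T2` so that the deletion and amplification boundaries are
symmetric about the ploidy. Values below `T1` classify as deletion, above
`T2` as amplification.

## Segmentation and rules

The genome is partitioned on the union of all callers' interval endpoints
(`GenomicRanges::disjoin`), so each partition bin lies strictly inside or
outside every input interval and no proration is ever needed. Each bin is
then decided by a fixed rule table (`decideBin()`):

| coverage | hybrid | referee | consensus |
|---|---|---|---|
| class X | class X (agree) | — | X; value from coverage for deletion/normal, from hybrid for amplification |
| present | absent | — | coverage call stands (including amplifications) |
| absent | present | — | hybrid call stands |
| conflict | conflict | matches one side | that side's value |
| conflict | conflict | none / matches neither | ploidy |
| absent | absent | — | ploidy, rule `no_evidence` |

Where the sources behind the sparser cells were ambiguous we fixed them as:
agreement selects a single source rather than averaging (the two callers'
values live on the same scale only after harmonisation, and source selection
keeps the provenance of every number auditable); the referee is never a
numeric source; a referee class matching neither conflicting caller yields
the ploidy. Each bin carries the error score `e = (CN_RD - CN_SV)^2` with
the gap conventions: a silent coverage caller counts as CN 0 (it calls
gap-free, so silence means no signal), a silent hybrid caller as the ploidy.

## Merging

Contiguous bins on one chromosome whose copy numbers agree after rounding to
one decimal are merged; merged CN and error score are bin-length-weighted
means, and the reported rule id is the one covering most bases. Chromosomes
are merged independently — segments never span chromosomes, since a CNV is a
within-chromosome event. Rounding is half-away-from-zero (deterministic and
locale-independent, unlike banker's rounding at the x.x5 boundaries that
decide merges); values within 1e-9 of a boundary are treated as on it,
because decimal literals are not exactly representable.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `histogramBinWidth` | 0.05 | CN | fine enough to resolve a 0.1 bias shift, coarse enough that a genome-scale track fills every bin near the ploidy |
| `clampLimit` | 0.5 | CN | half the distance between integer copy numbers; a larger correction would cross into the next state |
| `equalizerBaseDivisor` / `equalizerExponentCoefficient` | 100 / 0.75 | — | calibration of the null-ratio distortion model |
| `t2SearchInterval` | [2, 2.3] | CN | the frequency valley between the diploid peak and the first amplification peak for `P = 2` |
| `bias`, `thresholds` | estimated | — | fixable for reproducible demonstrations or externally calibrated runs |

Gene classes use 1.75 and 2.75 for ploidy 2 (boundary values are normal);
for other ploidies they scale proportionally (`0.875 P`, `1.375 P`), since
the boundaries are stated only for the diploid case.

# The synthetic generator

`simulateScenario()` draws, per chromosome, 30–50 non-overlapping CNV
segments of 10–100 kbp with copy numbers in {0, 1, 3, ..., 8} (never 2) on a
diploid background, then emulates the three tracks:

* coverage: 450-bp bins tiling every base (a typical post-segmentation
  average bin size), value = overlap-weighted truth − `peakShift` (default
  0.1 CN, a realistic systematic bias) + Gaussian noise;
* hybrid: 400-bp bins (the bin size hybrid callers are typically run at),
  value solving `y * q(y) = trueCN` — the exact inverse of the equalizer —
  plus noise, with a fraction `gapRate` of bins dropped;
* referee: a random subset of the true CNV segments, direction always
  correct, magnitude multiplied by a heavy-tailed factor up to
  `magnitudeScale` (default 1000, matching reports of amplification values
  in the tens of thousands).

The "low coverage" regime used by the end-to-end tests sets noise sd 0.5 on
both primary tracks and a hybrid gap rate of 0.3. Test scenarios use one
10-Mb chromosome with 200 genes of 2–20 kbp, which keeps a 20-seed
experiment comfortably interactive while leaving hundreds of CNV-overlapping
genes per seed; the vignette-level conclusions do not change with longer
chromosomes. Where no published noise magnitudes exist (real-data noise was
never quantified), the defaults above are the package's calibration
choices, set once and exposed in the configuration.

What the generator does **not** emulate: GC-content and mappability bias,
read-level sampling noise (reads are never simulated), caller-specific
segmentation artefacts, subclonal mixtures, and inter-caller correlation of
errors (the emulated tracks err independently; real callers sharing one
alignment do not). A passing end-to-end suite therefore shows the consensus
logic behaves as designed under its own model assumptions — it does not
certify accuracy on real sequencing data.

# Numerical and degenerate-input choices

* Histogram bins are centred on multiples of the bin width, so a value
  cluster at 1.9 yields peak 1.9 exactly; peak ties break towards higher
  mass, then smaller CN. A single-bin histogram is a peak, not a flat
  histogram; a genuinely flat histogram yields bias 0 with a warning.
* The `T2` local minimum must be strictly lower than both neighbours; among
  several, lowest frequency wins, ties to smaller CN; with no interior
  minimum the midpoint 2.15 is used with a warning.
* Bias estimation and the log2 median are genome-wide, not per chromosome:
  the bias is a property of the caller, not of a chromosome.
* The equalizer inverse is found by `uniroot` on [0, target] (the map is
  increasing and ≥ identity), tolerance 1e-12, cached per unique value.
* Empty tracks: bias estimation and log2 conversion are errors; an empty
  referee file is a warning (an absent referee is an expected state).
* A weighted median is the lower weighted median (smallest value whose
  cumulative weight reaches half the total).
* Coordinates are stored 1-based closed (the GRanges convention); the file
  dialects (0-based half-open BED-style by default, 1-based on request) are
  converted at the I/O boundary, and the consensus writer emits 0-based
  half-open.

# Known limitations

* The equalizer is a fixed two-parameter correction; a distortion model fit
  per dataset is out of scope.
* The rule table treats exactly one caller per role; multiple coverage
  callers would need a pre-merge step.
* Referee calls with magnitudes exactly at the ploidy carry no direction and
  are treated as absent.
* `T1 = 2P - T2` assumes the deletion boundary mirrors the amplification
  boundary, which is a modelling convenience, not an estimated quantity.
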