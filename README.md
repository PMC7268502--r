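# cnvConsensus

Consensus copy-number calling from the outputs of heterogeneous CNV callers.

## The problem

No single class of copy-number caller is reliable across the whole range of
copy numbers, and all of them degrade on low-coverage data (below ~10x, down
to single-cell 1x). Coverage (read-depth) callers predict gap-free absolute
copy numbers and are good at deletions and the normal state, but their
amplification calls drift; hybrid callers that combine read depth with
read-pair signals are better at amplifications but leave prediction gaps and,
when run against a simulated zero-coverage "null" matched sample, report
non-negative ratios with a distortion that grows exponentially with the true
amplification; a third class produces trustworthy *deletion vs amplification*
direction but wildly unreliable magnitudes (amplification "copy numbers" in
the tens of thousands).

`cnvConsensus` merges the three into one consensus profile. It is aimed at
people benchmarking or combining CNV callers — the package starts from caller
output tables, never from reads or alignments.

## The method

1. **Harmonisation onto the absolute CN scale.**
   The coverage caller's systematic bias is the displacement of its CN
   frequency peak from the ploidy, `bias = P − CN at max(frequency(CN))`,
   and is corrected copy-number-dependently:

       CN_norm = CN + factor × bias,   factor = min(CN / 2, 1)

   with the applied correction clamped to ±0.5 CN units.
   Hybrid log2 ratios against a matched sample are centred by the
   genome-wide median and mapped with `CN = P · 2^(log2 − median)`.
   Hybrid ratios against a null alignment are corrected with the equalizer
   factor

       CN = cn · q(cn),   q(cn) = (1 + cn/100)^(0.75 · cn)

   which undoes the exponential distortion (q(4) = 1.04³ = 1.124864).
2. **Thresholds.** `T2` is the local minimum of the normalised coverage
   caller's CN frequency histogram inside [2, 2.3]; `T1 = 2P − T2`.
   Copy numbers below `T1` are deletions, above `T2` amplifications.
3. **Segmentation.** The genome is partitioned on the union of all callers'
   interval breakpoints, so every bin lies strictly inside or outside each
   caller's intervals.
4. **Rule-based consensus per bin.** Deletions and normal states are accepted
   from the coverage caller, amplifications from the hybrid caller; if one
   caller is silent the other stands; class conflicts are arbitrated by the
   referee caller, whose direction selects the matching caller's value; an
   unresolvable conflict falls back to the ploidy. The referee never
   contributes magnitudes. Each bin carries the error score
   `e = (CN_RD − CN_SV)²` (absent coverage → 0, absent hybrid → P).
5. **Merging.** Contiguous bins with equal one-decimal copy number are merged
   into segments; copy number and error score are bin-length-weighted means.

Predictions are benchmarked per gene (segment-length-weighted copy numbers
with ploidy gap-fill) using MSE, MAE, the mean log ratio error
`MLRE = mean |ln((x+1)/(x̂+1))|`, the variance of residuals around each unique
true CN, and the micro-averaged Matthews correlation coefficient over the
classes deletion (< 1.75), normal, amplification (> 2.75).

A seedable generator (`simulateScenario()`) emulates all three caller styles
from a ground-truth CNV profile so the whole pipeline is testable without any
external data.

## Worked example

```r
library(cnvConsensus)

## a deterministic 7-bin fixture exercising every consensus rule
fx <- makeRuleScenario()
segs <- callConsensus(fx$coverage, fx$hybrid, fx$referee, config = fx$config)
segs
#> GRanges object with 5 ranges and 4 metadata columns:
#>       seqnames    ranges strand |    cnMeta cnMetaRounded  errorScore              ruleId
#>   [1]        1    1-2000      * |   2.00000           2.0 1.88304e+00        agree_normal
#>   [2]        1 2001-3000      * |   4.49946           4.5 2.49456e-01 agree_amplification
#>   [3]        1 3001-4000      * |   0.90000           0.9 2.98065e-05      agree_deletion
#>   [4]        1 4001-5000      * |   4.49946           4.5 6.24728e+00      referee_hybrid
#>   [5]        1 5001-7000      * |   4.00000           4.0 3.88122e+00       coverage_only
```

Reading the output: the first segment merges two bins — a diploid agreement
and a coverage/hybrid conflict that the referee could not arbitrate, which
falls back to copy number 2. Bins where both callers agree take the coverage
caller's value for deletions/normal (0.9) and the hybrid caller's for
amplifications (4.4995); the `referee_hybrid` segment is a conflict the
referee resolved towards the hybrid caller's amplification; the final
segment is an amplification the hybrid caller did not cover at all, so the
coverage caller's call stands. `errorScore` is the squared disagreement of
the two primary callers, averaged over each segment.

On a full synthetic scenario, gene-level accuracy of the consensus vs the
emulated coverage caller alone:

```r
sc   <- simulateScenario(seed = 1)
segs <- callConsensus(sc@coverage, sc@hybrid, sc@referee)
evaluateCalls(segs, sc@genes, sc@truthTable)
#> MetricsReport over 200 gene(s), 9 true CN level(s)
#>   mse               0.0132036
#>   mae               0.092622
#>   mlre              0.0299838
#>   residualVariance  0.0123622
#>   mcc               0.9775
#>   confusion (micro): TP 197, TN 397, FP 3, FN 3
evaluateCalls(calls(sc@coverage), sc@genes, sc@truthTable)@mlre
#> [1] 0.04000613
```

The consensus MLRE (0.030) beats the best single emulated caller (0.040);
the test suite asserts this across 20 seeds.

## Command line

```sh
inst/exec/cnv-consensus simulate --seed 3 --out-dir sim/
inst/exec/cnv-consensus call --coverage sim/coverage.tsv --hybrid sim/hybrid.tsv \
    --referee sim/referee.tsv --out consensus.bed
inst/exec/cnv-consensus evaluate --pred consensus.bed --genes sim/genes.tsv \
    --truth sim/truth.tsv --out report.json
```

All tabular formats are plain TSV (`#` comments, 0-based half-open
coordinates by default, `--dialect one_based` for GFF-style inputs); gene
models are also accepted as GFF3/GTF.

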