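segsGR <- function(start, end, cn, chrom = "1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), cnMeta = cn)
}
geneGR <- function(start, end, id = "g1", chrom = "1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), gene_id = id)
}

test_that("gene copy numbers are segment-length-weighted with ploidy gap fill", {
  ## 1000 bp gene: 600 bp at CN 2, 400 bp at CN 4 -> 2.8
  p <- mapSegmentsToGenes(segsGR(c(1, 601), c(600, 1000), c(2, 4)),
                          geneGR(1, 1000))
  expect_equal(unname(p), 2.8)
  ## gene fully inside one CN 3 segment -> 3
  p2 <- mapSegmentsToGenes(segsGR(1, 5000, 3), geneGR(2001, 3000))
  expect_equal(unname(p2), 3)
  ## half covered at CN 4, half uncovered, ploidy 2 -> 3
  p3 <- mapSegmentsToGenes(segsGR(1, 500, 4), geneGR(1, 1000))
  expect_equal(unname(p3), 3)
  ## no segments on the gene's chromosome: sits at ploidy
  p4 <- mapSegmentsToGenes(segsGR(1, 500, 4), geneGR(1, 1000, chrom = "2"))
  expect_equal(unname(p4), 2)
  ## unknown chromosome: ploidy with a warning
  expect_warning(
    p5 <- mapSegmentsToGenes(segsGR(1, 500, 4),
                             geneGR(1, 1000, chrom = "weird_scaffold")),
    "unrecognised")
  expect_equal(unname(p5), 2)
})

test_that("eval_length truncates partially covered genes", {
  segs <- segsGR(c(1, 501), c(500, 2000), c(4, 2))
  g <- geneGR(1, 1000)
  full <- mapSegmentsToGenes(segs, g)
  expect_equal(unname(full), 3)              # 500 at 4, 500 at 2
  trunc <- mapSegmentsToGenes(segs, g, evalLength = 500)
  expect_equal(unname(trunc), 4)             # only the first 500 bp
})

test_that("weighted gene CN agrees with per-segment arithmetic on random cases", {
  set.seed(31)
  for (k in 1:50) {
    n <- sample(1:8, 1)
    width <- sample(100:1000, n, replace = TRUE)
    gap <- sample(0:300, n, replace = TRUE)
    start <- cumsum(gap) + cumsum(c(0, width[-n])) + 1
    cn <- runif(n, 0, 6)
    gs <- sample(1:2000, 1); ge <- gs + sample(500:3000, 1)
    got <- mapSegmentsToGenes(segsGR(start, start + width - 1, cn),
                              geneGR(gs, ge))
    want <- oracleGeneCN(gs, ge,
                         data.frame(start = start, end = start + width - 1,
                                    cn = cn), P = 2)
    expect_equal(unname(got), want)
    ## mass conservation for fully covered genes
    fullyCovered <- gs >= min(start) && ge <= max(start + width - 1) &&
      all(diff(start) == width[-n])   # no internal gaps
    if (fullyCovered) {
      expect_gte(unname(got), min(cn) - 1e-12)
      expect_lte(unname(got), max(cn) + 1e-12)
    }
  }
})

test_that("error metrics match their definitions", {
  expect_equal(mseCN(c(2, 4), c(2, 4)), 0)
  expect_equal(maeCN(c(2, 4), c(2, 4)), 0)
  expect_equal(mlre(c(2, 4), c(2, 4)), 0)
  expect_equal(mseCN(c(2, 4), c(1, 6)), 2.5)
  expect_equal(maeCN(c(2, 4), c(1, 6)), 1.5)
  expect_equal(mseCN(0, 2), 4)
  expect_equal(maeCN(0, 2), 2)
  expect_equal(mlre(3, 1), log(2))
  expect_equal(mlre(0, 0), 0)               # the +1 guards the log at CN 0
  expect_error(mseCN(numeric(0), numeric(0)), "no gene")
  expect_error(mlre(numeric(0), numeric(0)), "no gene")
})

test_that("residual variance averages population variances per true CN level", {
  ## identical residuals within every group -> 0
  expect_equal(residualVariance(c(2, 2, 4, 4), c(1.5, 1.5, 3, 3)), 0)
  ## one group, residuals {1, -1} -> population variance 1
  expect_equal(residualVariance(c(2, 2), c(1, 3)), 1)
  ## groups with variances 0 and 2 -> mean 1
  expect_equal(residualVariance(c(2, 2, 4, 4), c(2, 2, 4 - sqrt(2), 4 + sqrt(2))), 1)
  ## singleton groups contribute zero variance
  expect_equal(residualVariance(c(2, 4), c(1, 7)), 0)
})

test_that("metrics agree with brute-force implementations on random instances", {
  set.seed(37)
  for (k in 1:300) {
    n <- sample(1:12, 1)
    x <- sample(0:8, n, replace = TRUE) + ifelse(runif(n) < 0.3, runif(n, -0.3, 0.3), 0)
    x <- pmax(x, 0)
    xh <- pmax(x + rnorm(n), 0)
    expect_equal(mseCN(x, xh), oracleMSE(x, xh))
    expect_equal(maeCN(x, xh), oracleMAE(x, xh))
    expect_equal(mlre(x, xh), oracleMLRE(x, xh))
    expect_equal(residualVariance(x, xh), oracleResVar(x, xh))
  }
})

test_that("gene classes use the 1.75 / 2.75 boundaries for ploidy 2", {
  expect_identical(classifyGene(c(2.8, 1.75, 2.75, 0.3, 1.74)),
                   c("amplification", "normal", "normal", "deletion",
                     "deletion"))
  ## boundaries scale proportionally with ploidy
  expect_identical(classifyGene(c(3.4, 3.5, 5.5, 5.6), P = 4),
                   c("deletion", "normal", "normal", "amplification"))
})

test_that("micro-averaged MCC sums one-vs-rest confusion counts", {
  cls <- c("deletion", "normal", "amplification")
  expect_equal(mccMicro(cls, cls), 1)
  expect_equal(
    mccMicro(c("deletion", "deletion", "normal", "amplification"),
             c("deletion", "normal", "normal", "amplification")),
    0.625)
  ## constant "normal" on balanced classes is barely informative
  bal <- rep(cls, each = 4)
  expect_lte(mccMicro(bal, rep("normal", 12)), 0.25)
  ## invariant under permutation of the class labels
  set.seed(41)
  for (k in 1:100) {
    n <- sample(2:15, 1)
    tc <- sample(cls, n, replace = TRUE)
    pc <- sample(cls, n, replace = TRUE)
    expect_equal(mccMicro(tc, pc), oracleMCC(tc, pc))
    perm <- setNames(sample(cls), cls)
    expect_equal(mccMicro(unname(perm[tc]), unname(perm[pc])),
                 mccMicro(tc, pc))
  }
  ## single-class degenerate input: micro-summing keeps the denominator
  ## positive (TP + FP = N), so a perfect constant prediction scores 1
  expect_equal(mccMicro(rep("normal", 3), rep("normal", 3)), 1)
})

test_that("evaluateCalls composes mapping and metrics and reports missing genes", {
  segs <- segsGR(c(1, 1001, 3001), c(1000, 3000, 6000), c(4, 2, 1))
  genes <- c(geneGR(101, 900, "gAmp"), geneGR(1101, 2900, "gNorm"),
             geneGR(3101, 5900, "gDel"))
  truth <- data.frame(gene_id = c("gAmp", "gNorm", "gDel", "gGone"),
                      true_cn = c(4, 2, 1, 6))
  rep <- evaluateCalls(segs, genes, truth)
  expect_s4_class(rep, "MetricsReport")
  v <- metricValues(rep)
  expect_equal(unname(v[c("mse", "mae", "mlre", "residualVariance")]),
               rep(0, 4))
  expect_equal(unname(v["mcc"]), 1)
  expect_identical(rep@missingGenes, "gGone")
  expect_identical(rep@nGenes, 3L)
  expect_error(evaluateCalls(segs, genes,
                             data.frame(gene_id = "nope", true_cn = 2)),
               "no gene")
})
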