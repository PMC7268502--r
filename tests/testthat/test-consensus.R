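test_that("the partition is exactly the union of all callers' breakpoints", {
  cov <- CallerTrack(c("1", "1"), c(1, 101), c(100, 200), c(2, 3),
                     "coverage", "absolute_cn")
  hyb <- CallerTrack("1", 1, 150, 2, "hybrid", "ratio_vs_null")
  part <- unionBreakpoints(list(rd = cov, sv = hyb))
  expect_identical(GenomicRanges::start(part), c(1L, 101L, 151L))
  expect_identical(GenomicRanges::end(part), c(100L, 150L, 200L))
  expect_equal(S4Vectors::mcols(part)$rd, c(2, 3, 3))
  expect_equal(S4Vectors::mcols(part)$sv, c(2, 2, NA))

  ## identical bins: union is idempotent
  same <- unionBreakpoints(list(rd = cov, sv = CallerTrack(
    c("1", "1"), c(1, 101), c(100, 200), c(1, 1),
    "hybrid", "ratio_vs_null")))
  expect_identical(GenomicRanges::start(same), c(1L, 101L))

  ## empty hybrid contributes nothing
  emptyHyb <- CallerTrack(character(), integer(), integer(), numeric(),
                          "hybrid", "ratio_vs_null")
  part2 <- unionBreakpoints(list(rd = cov, sv = emptyHyb))
  expect_identical(GenomicRanges::ranges(part2),
                   GenomicRanges::ranges(calls(cov)))
})

test_that("breakpoint union matches a brute-force endpoint enumeration", {
  set.seed(19)
  for (k in 1:10) {
    a <- randomTrack(sample(2:15, 1))
    b <- randomTrack(sample(2:15, 1), role = "hybrid",
                     scale = "ratio_vs_null")
    part <- unionBreakpoints(list(rd = a, sv = b))
    ## brute force: all endpoints, bins between consecutive ones kept iff
    ## covered by at least one input interval
    pts <- sort(unique(c(GenomicRanges::start(calls(a)),
                         GenomicRanges::end(calls(a)) + 1L,
                         GenomicRanges::start(calls(b)),
                         GenomicRanges::end(calls(b)) + 1L)))
    covered <- function(s, e) {
      inTrack <- function(tr) any(GenomicRanges::start(calls(tr)) <= s &
                                  GenomicRanges::end(calls(tr)) >= e)
      inTrack(a) || inTrack(b)
    }
    keep <- vapply(seq_len(length(pts) - 1L), function(i)
      covered(pts[i], pts[i + 1L] - 1L), logical(1))
    expect_identical(GenomicRanges::start(part), pts[-length(pts)][keep])
    expect_identical(GenomicRanges::end(part), (pts[-1L] - 1L)[keep])
  }
})

test_that("copy numbers classify against T1/T2 as deletion/normal/amplification", {
  th <- Thresholds(2.15)
  expect_identical(classifyCN(c(1.5, 2.0, 2.4, 1.85, 2.15, NA), th),
                   c("deletion", "normal", "amplification",
                     "normal", "normal", NA))
})

test_that("the referee contributes direction only", {
  expect_identical(refereeClass(c(44084, 0, NA, 2), P = 2),
                   c("amplification", "deletion", "none", "none"))
  expect_identical(
    refereeClass(c(NA, NA), P = 2,
                 svClass = c("duplication", "deletion")),
    c("amplification", "deletion"))
})

test_that("the rule table is total over all class/referee combinations", {
  th <- Thresholds(2.15)
  vals <- c(deletion = 1.0, normal = 2.0, amplification = 4.0)
  states <- c(names(vals), "absent")
  refs <- c("deletion", "amplification", "none")
  for (sRd in states) for (sSv in states) for (rf in refs) {
    cnRd <- if (sRd == "absent") NA_real_ else vals[[sRd]]
    cnSv <- if (sSv == "absent") NA_real_ else vals[[sSv]] + 0.01
    got <- decideBin(cnRd, cnSv, rf, th, P = 2)
    expect_equal(got$cnMeta,
                 oracleDecide(sRd, sSv, rf, cnRd, cnSv, 2),
                 info = sprintf("rd=%s sv=%s ref=%s", sRd, sSv, rf))
    expect_false(is.na(got$ruleId))
  }
})

test_that("headline consensus rules match the documented behaviour", {
  th <- Thresholds(2.15)
  ## agreement: class wins, value from coverage for del/normal, hybrid for amp
  expect_identical(decideBin(4, 4.5, "none", th, 2)$cnMeta, 4.5)
  expect_identical(decideBin(0.9, 0.8, "none", th, 2)$cnMeta, 0.9)
  expect_identical(decideBin(2, 2.1, "none", th, 2)$cnMeta, 2)
  ## hybrid absent: the coverage call stands, including amplifications
  expect_identical(decideBin(4, NA, "none", th, 2)$ruleId, "coverage_only")
  expect_identical(decideBin(4, NA, "none", th, 2)$cnMeta, 4)
  ## conflict: referee selects the matching caller's value
  expect_identical(decideBin(4, 2, "amplification", th, 2)$cnMeta, 4)
  expect_identical(decideBin(2, 4, "amplification", th, 2)$cnMeta, 4)
  expect_identical(decideBin(1, 2.4, "deletion", th, 2)$cnMeta, 1)
  ## conflict, no referee evidence: ploidy
  expect_identical(decideBin(4, 2, "none", th, 2)$cnMeta, 2)
  ## conflict the referee matches neither side of: ploidy
  expect_identical(decideBin(2, 1, "amplification", th, 2)$cnMeta, 2)
  ## nothing at all: ploidy, flagged
  expect_identical(decideBin(NA, NA, "none", th, 2)$ruleId, "no_evidence")
})

test_that("error scores square the disagreement with the gap conventions", {
  expect_identical(errorScore(3, 3), 0)
  expect_identical(errorScore(1, 3), 4)
  expect_identical(errorScore(NA, 2, P = 2), 4)    # absent coverage -> 0
  expect_identical(errorScore(3, NA, P = 2), 1)    # absent hybrid -> ploidy
  expect_identical(errorScore(NA, NA, P = 2), 4)   # (0 - 2)^2
  set.seed(23)
  for (k in 1:100) {
    rd <- if (runif(1) < 0.2) NA else runif(1, 0, 6)
    sv <- if (runif(1) < 0.2) NA else runif(1, 0, 6)
    expect_equal(errorScore(rd, sv, 2), oracleErrorScore(rd, sv, 2))
  }
})

test_that("merging combines contiguous one-decimal-equal bins length-weighted", {
  b <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 101), c(100, 400)),
                              cnMeta = c(2.04, 2.01), errorScore = c(0, 4),
                              ruleId = "agree_normal")
  m <- mergeSegments(b)
  expect_identical(length(m), 1L)
  expect_equal(S4Vectors::mcols(m)$cnMeta, 0.25 * 2.04 + 0.75 * 2.01)
  expect_equal(S4Vectors::mcols(m)$errorScore, 3)

  b2 <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1, 101), c(100, 200)),
                               cnMeta = c(2.04, 2.16), errorScore = 0,
                               ruleId = "agree_normal")
  expect_identical(length(mergeSegments(b2)), 2L)   # 2.0 vs 2.2

  single <- mergeSegments(b[1])
  expect_equal(GenomicRanges::ranges(single), GenomicRanges::ranges(b[1]))
  expect_equal(S4Vectors::mcols(single)$cnMeta, 2.04)
})

test_that("merging agrees with a naive repeated-pairwise merge on random bins", {
  set.seed(29)
  for (k in 1:15) {
    n <- sample(2:40, 1)
    width <- sample(50:300, n, replace = TRUE)
    gap <- ifelse(runif(n) < 0.8, 0L, sample(1:50, n, replace = TRUE))
    start <- cumsum(gap) + cumsum(c(0L, width[-n])) + 1L
    cn <- sample(seq(1.95, 2.25, by = 0.01), n, replace = TRUE)
    e <- runif(n, 0, 4)
    bins <- GenomicRanges::GRanges("1", IRanges::IRanges(start, start + width - 1L),
                                   cnMeta = cn, errorScore = e, ruleId = "x")
    got <- mergeSegments(bins)
    want <- oracleMerge(data.frame(chrom = "1", start = start,
                                   end = start + width - 1L, cn = cn, e = e))
    expect_identical(GenomicRanges::start(got), as.integer(want$start))
    expect_identical(GenomicRanges::end(got), as.integer(want$end))
    expect_equal(S4Vectors::mcols(got)$cnMeta, want$cn)
    expect_equal(S4Vectors::mcols(got)$errorScore, want$e)
    ## partition conservation: merged covered length equals input length
    expect_identical(sum(GenomicRanges::width(got)), sum(width))
    ## adjacent contiguous segments differ after rounding
    if (length(got) > 1) {
      r <- S4Vectors::mcols(got)$cnMetaRounded
      contig <- GenomicRanges::start(got)[-1] ==
        GenomicRanges::end(got)[-length(got)] + 1L
      expect_true(all(r[-1][contig] != r[-length(r)][contig]))
    }
  }
})

test_that("a uniformly diploid input yields one diploid segment per chromosome", {
  start <- seq(1L, by = 100L, length.out = 50)
  cov <- CallerTrack(rep(c("1", "2"), each = 50), c(start, start),
                     c(start + 99L, start + 99L), rep(2, 100),
                     "coverage", "absolute_cn")
  hyb <- CallerTrack(rep(c("1", "2"), each = 50), c(start, start),
                     c(start + 99L, start + 99L), rep(2, 100),
                     "hybrid", "ratio_vs_null")
  segs <- callConsensus(cov, hyb,
                        config = consensusConfig(bias = 0,
                                                 thresholds = Thresholds(2.15)))
  expect_identical(length(segs), 2L)     # one per chromosome, never spanning
  ## hybrid 2 equalizes to 2.06; both classes normal, so the consensus value
  ## comes from the coverage caller:
  expect_equal(S4Vectors::mcols(segs)$cnMeta, c(2, 2))
  expect_equal(S4Vectors::mcols(segs)$cnMetaRounded, c(2, 2))
  expect_equal(max(S4Vectors::mcols(segs)$errorScore), (2 - 2 * 1.02^1.5)^2)
})
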