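test_that("call filters enforce minimum coverage and variant frequency", {
  st <- simpleSnpTable("c1", c(100, 200, 300), refCnt = c(0, 7, 3),
                       altCnt = c(5, 3, 3))
  # site 100: coverage 5, variant 100% -> dropped (coverage)
  # site 200: coverage 10, variant 30% -> dropped (frequency)
  # site 300: coverage 6, A:3 G:3 -> kept, primary 50%
  f <- snpCalls(applyCallFilters(st, scanConfig()))
  expect_equal(f$pos, 300L)
  expect_equal(f$primaryFreqPct, 50)
})

test_that("merging pools forms the sorted union with per-pool missing cells", {
  sel <- simpleSnpTable("c1", c(100, 200), 3, 7, pool = "sel")
  uns <- simpleSnpTable("c1", c(200, 300), 4, 6, pool = "uns")
  m <- mergedRows(mergePools(sel, uns))
  expect_equal(m$pos, c(100L, 200L, 300L))
  expect_true(is.na(m$unselFreqPct[1]) && is.na(m$selFreqPct[3]))

  expect_equal(length(mergePools(sel, sel)), length(sel))
  disjointA <- simpleSnpTable("c1", 1:4 * 10, 3, 7)
  disjointB <- simpleSnpTable("c1", 1:3 * 1000, 3, 7)
  expect_equal(length(mergePools(disjointA, disjointB)), 7L)

  dup <- sel
  dup@calls <- rbind(snpCalls(sel), snpCalls(sel)[1, ])  # corrupt deliberately
  expect_error(mergePools(dup, uns), "duplicate position")
})

test_that("window averages skip missing cells like a spreadsheet AVERAGE", {
  m <- makeMergedTable("c1", c(100, 200, 300),
                       sel = c(100, NA, 80), unsel = c(60, 70, 50))
  w <- profileWindows(windowAverage(m, 3))
  expect_equal(nrow(w), 1L)
  expect_equal(w$selMeanPct, 90)
  expect_equal(w$unselMeanPct, 60)
  expect_equal(w$nSel, 2L)
  expect_equal(c(w$firstPos, w$lastPos), c(100L, 300L))

  # constant input, stride one
  m2 <- makeMergedTable("c1", 1:3 * 10, rep(100, 3), rep(50, 3))
  w2 <- profileWindows(windowAverage(m2, 2))
  expect_equal(w2$selMeanPct, c(100, 100))

  # fewer rows than the window: one whole-sequence window, with a warning
  expect_warning(p3 <- windowAverage(m2, 5), "whole-sequence")
  expect_equal(nrow(profileWindows(p3)), 1L)
  expect_error(windowAverage(m2, 0), "windowSize")
})

test_that("window count and overlap structure follow the dynamic-window definition", {
  set.seed(11)
  for (w in c(1, 5, 17)) {
    n <- 40
    m <- randomMergedTable(n, 0.2)
    prof <- profileWindows(windowAverage(m, w))
    expect_equal(nrow(prof), n - w + 1L)
    d <- mergedRows(m)
    expect_equal(prof$firstPos, d$pos[seq_len(n - w + 1L)])
    expect_equal(prof$lastPos, d$pos[seq_len(n - w + 1L) + w - 1L])
  }
})

test_that("windows never cross sequence boundaries", {
  m <- makeMergedTable(rep(c("a", "b"), each = 4), rep(1:4 * 10L, 2),
                       sel = rep(90, 8), unsel = rep(60, 8))
  w <- profileWindows(windowAverage(m, 3))
  expect_equal(table(w$seqId)[["a"]], 2L)
  expect_equal(table(w$seqId)[["b"]], 2L)
  expect_true(all(w$firstPos >= 10 & w$lastPos <= 40))
})

test_that("window size routing follows sequence length and SNP count", {
  cfg <- scanConfig()
  expect_equal(chooseWindowSize(2e7, 50000, cfg), 300L)
  expect_equal(chooseWindowSize(2e5, 30, cfg), 30L)
  expect_equal(chooseWindowSize(2e5, 1, cfg), 1L)
  expect_equal(chooseWindowSize(2e5, 500, cfg), 50L)
  cfg40 <- scanConfig(windowScaffold = 40)
  expect_equal(chooseWindowSize(2e5, 500, cfg40), 40L)
})

test_that("candidate regions are maximal runs of differential-homozygosity windows", {
  cfg <- scanConfig(minWindows = 2)
  p <- makeProfile(c(70, 95, 98, 96, 72), c(65, 66, 64, 67, 66))
  r <- callCandidateRegions(p, cfg)
  expect_equal(length(r), 1L)
  w <- profileWindows(p)
  expect_equal(GenomicRanges::start(r), w$firstPos[2])
  expect_equal(GenomicRanges::end(r), w$lastPos[4])
  expect_equal(S4Vectors::mcols(r)$nWindows, 3L)

  # no differential signal
  expect_equal(length(callCandidateRegions(
    makeProfile(rep(65, 5), rep(65, 5)), cfg)), 0L)
  # shared fixed differences: both pools homozygous, not differential
  expect_equal(length(callCandidateRegions(
    makeProfile(rep(100, 5), rep(100, 5)), cfg)), 0L)
  # run shorter than minWindows is not called
  expect_equal(length(callCandidateRegions(
    makeProfile(c(95, 96, 70, 70), c(60, 60, 60, 60)),
    scanConfig(minWindows = 3))), 0L)
})

test_that("raising the selected threshold never grows the called regions", {
  set.seed(21)
  for (k in 1:10) {
    sel <- runif(60, 70, 100)
    sel[20:35] <- runif(16, 88, 100)
    uns <- runif(60, 50, 80)
    p <- makeProfile(sel, uns)
    prevSpan <- Inf
    prevWins <- Inf
    for (thr in c(86, 90, 95)) {
      r <- callCandidateRegions(p, scanConfig(selMinPct = thr, minWindows = 2))
      span <- if (length(r)) sum(GenomicRanges::width(r)) else 0
      wins <- if (length(r)) sum(S4Vectors::mcols(r)$nWindows) else 0
      expect_lte(span, prevSpan)
      expect_lte(wins, prevWins)
      prevSpan <- span
      prevWins <- wins
    }
  }
})

test_that("duplicating a dense concordant SNP cluster does not change the call", {
  sel <- c(rep(60, 10), rep(98, 12), rep(60, 10))
  uns <- rep(65, 32)
  pos <- seq_len(32) * 100L
  m <- makeMergedTable("c1", pos, sel, uns)
  cfg <- scanConfig(minWindows = 2)
  call1 <- callCandidateRegions(windowAverage(m, 5), cfg)
  # duplicate the cluster inside the region (extra concordant sites)
  ins <- 16
  m2 <- makeMergedTable("c1", sort(c(pos, 1:12 * 3L + 1500L)),
                        append(sel, rep(98, 12), after = ins),
                        append(uns, rep(65, 12), after = ins))
  call2 <- callCandidateRegions(windowAverage(m2, 5), cfg)
  expect_equal(length(call1) > 0, length(call2) > 0)
  expect_true(length(call1) == 1L)
})

test_that("the full scan is deterministic and routes scaffold windows", {
  sel <- simpleSnpTable("sc1", 1:30 * 100, 0, 8, pool = "s")
  uns <- simpleSnpTable("sc1", 1:30 * 100, 4, 4, pool = "u")
  res <- scanPools(sel, uns)
  expect_s4_class(res, "ScanResult")
  expect_equal(windowSizes(scanProfile(res))[["sc1"]], 30L)  # scaffold routing
  res2 <- scanPools(sel, uns)
  expect_identical(profileWindows(scanProfile(res)),
                   profileWindows(scanProfile(res2)))
  # identical pools: no differential homozygosity anywhere
  same <- scanPools(sel, sel)
  expect_equal(length(candidateRegions(same)), 0L)
})
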