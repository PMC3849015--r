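test_that("Mendelian chi-square uses the tested denominator against 1:2:1", {
  h <- mendelianChisq(24, 48, 24, 96)
  expect_equal(unname(h$statistic), 0)
  expect_equal(h$expected, c(rr = 24, rs = 48, ss = 24))
  # n tested may differ from the genotyped total; expectations follow n tested
  h2 <- mendelianChisq(28, 41, 27, nTested = 94)
  expect_equal(unname(h2$statistic), sum((c(28, 41, 27) - c(23.5, 47, 23.5))^2 /
                                           c(23.5, 47, 23.5)))
  expect_equal(unname(h2$parameter), 1)
  expect_equal(h2$p.value, pchisq(unname(h2$statistic), 1, lower.tail = FALSE))
  expect_error(mendelianChisq(0, 0, 0, 96), "zero")
})

test_that("G test matches its log-likelihood-ratio closed form", {
  expect_equal(unname(gTest121(24, 48, 24)$statistic), 0)
  expect_equal(unname(gTest121(0, 0, 96)$statistic), 2 * 96 * log(96 / 24),
               tolerance = 1e-12)
  set.seed(14)
  for (k in 1:20) {
    o <- as.vector(rmultinom(1, sample(20:200, 1), c(.3, .45, .25)))
    g <- unname(gTest121(o[1], o[2], o[3])$statistic)
    e <- sum(o) * c(.25, .5, .25)
    oracle <- 2 * sum(ifelse(o > 0, o * log(o / e), 0))
    expect_equal(g, oracle, tolerance = 1e-9)
  }
})

test_that("chi-square and G agree asymptotically and hold their type-I error", {
  set.seed(15)
  n <- 10000
  draws <- 2000
  rejC <- rejG <- logical(draws)
  for (i in seq_len(draws)) {
    o <- as.vector(rmultinom(1, n, c(.25, .5, .25)))
    c2 <- mendelianChisq(o[1], o[2], o[3], df = 2)
    g <- gTest121(o[1], o[2], o[3])
    if (i <= 200)
      expect_lt(abs(unname(c2$statistic) - unname(g$statistic)),
                0.05 * max(unname(c2$statistic), 1))
    rejC[i] <- c2$p.value < 0.05
    rejG[i] <- g$p.value < 0.05
  }
  expect_lt(abs(mean(rejC) - 0.05), 0.015)   # ~3 SE at 2000 draws
  expect_lt(abs(mean(rejG) - 0.05), 0.015)
})

test_that("allele frequencies use the genotyped denominator and sum to one", {
  f <- alleleFrequencies(20, 52, 22)
  expect_equal(unname(f["p"] + f["q"]), 1)
  expect_equal(round(f[["p"]], 2), 0.49)
  expect_equal(alleleFrequencies(10, 0, 0)[["p"]], 1)
  expect_equal(alleleFrequencies(6, 15, 9), alleleFrequencies(12, 30, 18))
})

test_that("the literal Hardy-Weinberg test differs from the 1:2:1 test", {
  expect_equal(unname(hweChisq(25, 50, 25)$statistic), 0)
  # heterozygote-rich 1:2:1-deviant sample: HWE barely deviates while the
  # Mendelian test is extreme
  expect_equal(unname(hweChisq(38, 48, 8)$statistic), 1.77, tolerance = 0.01)
  expect_gt(unname(mendelianChisq(38, 48, 8, 96)$statistic), 18)
  expect_equal(unname(hweChisq(50, 0, 50)$statistic), 100)  # N, complete deficit
  expect_error(hweChisq(10, 0, 0), "monomorphic")
})

test_that("the Kosambi function behaves and round-trips with its inverse", {
  expect_equal(kosambiCM(0), 0)
  expect_equal(kosambiCM(0.1), 25 * log(1.2 / 0.8))
  expect_equal(kosambiCM(0.01), 1.0001, tolerance = 1e-4)
  r <- seq(0, 0.49, by = 0.01)
  d <- kosambiCM(r)
  expect_true(all(diff(d) > 0))                  # strictly increasing
  expect_true(all(d[-1] > 100 * r[-1]))          # exceeds 100 r off the origin
  expect_equal(kosambiR(d), r, tolerance = 1e-9)
  expect_error(kosambiCM(0.6), "outside")
  expect_error(kosambiR(-1), ">= 0")
})

test_that("two-point estimates match a fine grid-search oracle", {
  set.seed(16)
  grid <- seq(0, 0.5, by = 1e-4)
  for (k in 1:50) {
    r <- runif(1, 0.01, 0.45)
    P <- poolBSA:::f2ClassProbs(r)
    cnt <- matrix(rmultinom(1, sample(10:50, 1), as.vector(P)), 3)
    if (sum(rowSums(cnt) > 0) < 2 || sum(colSums(cnt) > 0) < 2) next
    est <- estimateRF2(cnt)
    ll <- vapply(grid, poolBSA:::f2LogLik, 0, counts = cnt)
    i <- which.max(ll)
    expect_lt(abs(est$rHat - grid[i]), 5e-4)
    lodOracle <- (ll[i] - poolBSA:::f2LogLik(0.5, cnt)) / log(10)
    expect_lt(abs(est$lod - lodOracle), 1e-3)
  }
})

test_that("two-point degenerate configurations are handled explicitly", {
  coseg <- diag(c(24, 50, 26))
  est <- estimateRF2(coseg)
  expect_equal(est$rHat, 0)
  expect_gt(est$lod, 0)
  indep <- outer(c(25, 50, 25), c(25, 50, 25)) / 100
  est2 <- estimateRF2(round(indep))
  expect_gt(est2$rHat, 0.45)
  expect_lt(est2$lod, 0.1)
  mono <- matrix(c(0, 0, 0, 0, 0, 0, 10, 20, 10), 3)
  expect_warning(est3 <- estimateRF2(mono), "monomorphic")
  expect_true(is.na(est3$rHat))
  expect_error(estimateRF2(matrix(c(1, rep(0, 8)), 3)), "at least 2")
})

test_that("recombinant counts in selected intercross survivors give map distances", {
  expect_equal(advancedIntercrossDistance(9, 48, 3), 3.125)
  expect_equal(round(advancedIntercrossDistance(9, 48, 3), 1), 3.1)
  expect_equal(advancedIntercrossDistance(0, 48, 3), 0)
  expect_equal(advancedIntercrossDistance(7, 48, 3), 100 * 7 / 288)
  expect_equal(advancedIntercrossDistance(9, 48, 3, method = "kosambi"),
               kosambiCM(9 / 288))
  expect_error(advancedIntercrossDistance(300, 48, 1), "2Ng")
})

test_that("full-cycle: simulated selection at one marker recovers the distance to another", {
  # two markers 3.125 cM apart; select homozygotes at the first in F4 and
  # score recombinants at the second across g = 3 meioses
  d <- 2 * 3.125
  reps <- 40
  ks <- Ns <- numeric(reps)
  for (s in seq_len(reps)) {
    cfg <- simConfig(chromosomes = data.frame(name = "c1", lengthBp = 1e5,
                                              lengthCM = d, nSites = 2L),
                     resistanceLoci = data.frame(chrom = "c1", posBp = 25e3),
                     nF2 = 194, cohortSize = 400, generations = 4,
                     seed = 9000 + s)
    set.seed(cfg@seed)
    pop <- advanceGenerations(makeParents(cfg), cfg)
    surv <- selectSurvivors(pop, 0.8)
    H <- surv@hap$c1
    other <- H[, 2]                                  # the unselected marker
    k <- sum(other[seq(1, length(other), 2)] + other[seq(2, length(other), 2)] != 2L)
    ks[s] <- k; Ns[s] <- surv@n
  }
  est <- advancedIntercrossDistance(sum(ks), sum(Ns), 3)
  # Analytic oracle: under random mating the frequency of the recombinant
  # haplotype among gametes follows h_{t+1} = (1-r) h_t + r/4 (meioses in
  # parents already homozygous across the interval produce no observable
  # recombinants), starting from h_1 = r/2 at the F1 meiosis.  A surviving
  # F4 individual is scored recombinant when either chromosome carries the
  # recombinant haplotype.
  r1 <- 0.5 * (1 - exp(-2 * 3.125 / 100))        # Haldane r for 3.125 cM
  h <- r1 / 2
  for (t in 2:3) h <- (1 - r1) * h + r1 / 4
  pInd <- 1 - (1 - 2 * h)^2
  oracle <- 100 * pInd / (2 * 3)
  expect_lt(abs(est - oracle), 0.25)
  # consequence: the k/(2Ng) formula underestimates the true 3.125 cM in a
  # closed intercross because g overstates the effective meiosis count
  expect_lt(est, 3.125)
  expect_gt(est, 1.0)
})

test_that("epistasis tabulation ranks genotype classes by maximum survival dose", {
  tb <- readDoseSurvivors(system.file("extdata", "phosphine_dose_survivors.csv",
                                      package = "poolBSA"))
  s <- epistasisSummary(tb, referenceLc = 0.02)
  expect_equal(nrow(s), 9L)
  ssss <- s[s$genotype1 == "ss" & s$genotype2 == "ss", ]
  rrrr <- s[s$genotype1 == "rr" & s$genotype2 == "rr", ]
  expect_equal(ssss$maxDose, 0.02)
  expect_equal(rrrr$maxDose, 4.0)
  expect_gte(rrrr$resistanceRatio, 200)
  expect_true(rrrr$lowerBound)                 # survivors at the top tested dose
  expect_equal(which(s$genotype1 == "rr" & s$genotype2 == "rr"), 9L)

  none <- tb
  none$survivors[!is.na(none$doseValue)] <- 0L
  s2 <- epistasisSummary(none, 0.02)
  expect_true(all(is.na(s2$maxDose)))
  expect_true(all(is.na(s2$resistanceRatio)))
  expect_error(epistasisSummary(tb, 0), "positive")
})
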