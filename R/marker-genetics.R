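checkCounts <- function(rr, rs, ss, nTested) {
  stopifnot(length(rr) == 1L, length(rs) == 1L, length(ss) == 1L,
            rr >= 0, rs >= 0, ss >= 0)
  if (rr + rs + ss < 1) stop("all genotype counts are zero")
  if (nTested < 1) stop("nTested must be >= 1")
  invisible(NULL)
}

#' Mendelian 1:2:1 segregation chi-square test
#'
#' Compares observed rr/rs/ss genotype counts with the 1:2:1 expectation
#' computed from \code{nTested}, the number of insects tested, which need
#' not equal the number genotyped.  The default df of 1 matches common
#' reporting practice for this test in the resistance-genetics literature;
#' a three-class goodness-of-fit test canonically has df = 2, which is
#' available via the \code{df} argument.
#'
#' @param rr,rs,ss observed genotype counts (resistant homozygote,
#'   heterozygote, susceptible homozygote).
#' @param nTested number of individuals tested; defaults to
#'   \code{rr + rs + ss}.
#' @param df degrees of freedom for the p-value (default 1).
#' @return An object of class \code{"htest"} with \code{statistic},
#'   \code{parameter} (df), \code{p.value} and \code{expected}.
#' @examples
#' mendelianChisq(34, 43, 17, nTested = 94)   # chi2 = 6.83
#' @export
mendelianChisq <- function(rr, rs, ss, nTested = rr + rs + ss, df = 1) {
  checkCounts(rr, rs, ss, nTested)
  expected <- nTested * c(rr = 0.25, rs = 0.5, ss = 0.25)
  obs <- c(rr = rr, rs = rs, ss = ss)
  chi2 <- sum((obs - expected)^2 / expected)
  structure(list(
    statistic = c("X-squared" = chi2),
    parameter = c(df = df),
    p.value = stats::pchisq(chi2, df, lower.tail = FALSE),
    expected = expected, observed = obs,
    method = "Chi-square test of 1:2:1 Mendelian segregation",
    data.name = sprintf("rr=%g, rs=%g, ss=%g (n tested %g)", rr, rs, ss, nTested)
  ), class = "htest")
}

#' G test of 1:2:1 segregation
#'
#' Log-likelihood-ratio test of the 1:2:1 genotype expectation,
#' \eqn{G = 2 \sum O \ln(O/E)} with expectations from \code{nTested};
#' zero observed cells contribute zero.  The p-value uses df = 2 by default.
#'
#' @inheritParams mendelianChisq
#' @param df degrees of freedom (default 2).
#' @return An \code{"htest"} object.
#' @examples
#' gTest121(24, 48, 24)        # G = 0
#' @export
gTest121 <- function(rr, rs, ss, nTested = rr + rs + ss, df = 2) {
  checkCounts(rr, rs, ss, nTested)
  expected <- nTested * c(rr = 0.25, rs = 0.5, ss = 0.25)
  obs <- c(rr = rr, rs = rs, ss = ss)
  terms <- ifelse(obs > 0, obs * log(obs / expected), 0)
  g <- 2 * sum(terms)
  structure(list(
    statistic = c(G = g),
    parameter = c(df = df),
    p.value = stats::pchisq(g, df, lower.tail = FALSE),
    expected = expected, observed = obs,
    method = "G test of 1:2:1 Mendelian segregation",
    data.name = sprintf("rr=%g, rs=%g, ss=%g (n tested %g)", rr, rs, ss, nTested)
  ), class = "htest")
}

#' Allele frequencies from genotype counts
#'
#' \eqn{p = (2 rr + rs) / (2 (rr + rs + ss))}, the resistant-allele
#' frequency, with \eqn{q = 1 - p}; the denominator is the number of
#' genotyped individuals, not the number tested.
#'
#' @inheritParams mendelianChisq
#' @return Named numeric vector \code{c(p = ..., q = ...)}.
#' @examples
#' alleleFrequencies(20, 52, 22)   # p = 0.49
#' @export
alleleFrequencies <- function(rr, rs, ss) {
  checkCounts(rr, rs, ss, rr + rs + ss)
  p <- (2 * rr + rs) / (2 * (rr + rs + ss))
  c(p = p, q = 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' The literal HWE goodness-of-fit test: expected genotype counts
#' \eqn{(\hat p^2 N, 2 \hat p \hat q N, \hat q^2 N)} with \eqn{\hat p}
#' estimated from the same counts and \eqn{N} the genotyped total; df = 1.
#' Monomorphic samples have no heterozygote expectation and are rejected.
#'
#' @inheritParams mendelianChisq
#' @return An \code{"htest"} object.
#' @examples
#' hweChisq(25, 50, 25)   # chi2 = 0
#' @export
hweChisq <- function(rr, rs, ss) {
  checkCounts(rr, rs, ss, rr + rs + ss)
  n <- rr + rs + ss
  p <- alleleFrequencies(rr, rs, ss)[["p"]]
  if (p <= 0 || p >= 1)
    stop("monomorphic sample: Hardy-Weinberg test undefined")
  expected <- n * c(rr = p^2, rs = 2 * p * (1 - p), ss = (1 - p)^2)
  obs <- c(rr = rr, rs = rs, ss = ss)
  chi2 <- sum((obs - expected)^2 / expected)
  structure(list(
    statistic = c("X-squared" = chi2),
    parameter = c(df = 1),
    p.value = stats::pchisq(chi2, 1, lower.tail = FALSE),
    expected = expected, observed = obs,
    method = "Chi-square test of Hardy-Weinberg equilibrium",
    data.name = sprintf("rr=%g, rs=%g, ss=%g", rr, rs, ss)
  ), class = "htest")
}

#' Kosambi map function and its inverse
#'
#' \code{kosambiCM} converts a recombination fraction to a map distance,
#' \eqn{d = 25 \ln((1+2r)/(1-2r))} cM; \code{kosambiR} is the inverse,
#' \eqn{r = \tanh(d/50)/2}.  They round-trip to better than 1e-9.
#' \code{r = 0.5} maps to infinite distance.
#'
#' @param r recombination fraction(s) in [0, 0.5].
#' @param d map distance(s) in cM, >= 0.
#' @return Numeric vector of distances (cM) or fractions.
#' @examples
#' kosambiCM(0.1)          # 10.137 cM
#' kosambiR(kosambiCM(0.2))
#' @export
kosambiCM <- function(r) {
  if (any(r < 0 | r > 0.5)) stop("recombination fraction outside [0, 0.5]")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambiCM
#' @export
kosambiR <- function(d) {
  if (any(d < 0)) stop("map distance must be >= 0")
  0.5 * tanh(d / 50)
}

## F2 intercross 9-class joint genotype probabilities, phase known.
## Rows index copies of the marker-1 resistant allele (0, 1, 2) = (ss, rs, rr),
## columns likewise for marker 2.
f2ClassProbs <- function(r) {
  g <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)    # AB, Ab, aB, ab
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  P <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    a <- hap[i, 1] + hap[j, 1]
    b <- hap[i, 2] + hap[j, 2]
    P[a + 1, b + 1] <- P[a + 1, b + 1] + g[i] * g[j]
  }
  P
}

f2LogLik <- function(r, counts) {
  P <- f2ClassProbs(r)
  ok <- counts > 0
  if (any(P[ok] == 0)) return(-Inf)
  sum(counts[ok] * log(P[ok]))
}

#' Two-point recombination estimate from F2 genotypes
#'
#' Maximum-likelihood estimate of the recombination fraction between two
#' codominant markers scored in an F2 intercross with known linkage phase
#' (parents genotyped), using the standard 9-class joint genotype
#' probabilities and bounded 1-D optimisation.  The LOD score compares the
#' maximised likelihood with free recombination (r = 0.5), and the Kosambi
#' map distance is attached.
#'
#' @param counts 3x3 matrix of joint genotype counts; rows are marker-1
#'   classes (ss, rs, rr), columns marker-2 classes.  A data.frame from
#'   [readMarkerGenotypes()] plus two marker names may be supplied instead
#'   via [crossTabGenotypes()].
#' @return A list with \code{rHat}, \code{lod}, \code{cmKosambi} and
#'   \code{n} (individuals used).  Monomorphic markers give \code{rHat = NA}
#'   with a warning.
#' @examples
#' cnt <- matrix(c(24, 1, 0, 1, 48, 1, 0, 1, 24), 3)
#' estimateRF2(cnt)
#' @export
estimateRF2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3L, 3L)), all(counts >= 0))
  n <- sum(counts)
  if (n < 2) stop("need at least 2 individuals scored at both markers")
  if (sum(rowSums(counts) > 0) < 2L || sum(colSums(counts) > 0) < 2L) {
    warning("a marker is monomorphic; recombination fraction undefined")
    return(list(rHat = NA_real_, lod = NA_real_, cmKosambi = NA_real_, n = n))
  }
  opt <- stats::optimize(f2LogLik, c(0, 0.5), counts = counts,
                         maximum = TRUE, tol = 1e-8)
  ll0 <- f2LogLik(0, counts)    # the boundary can beat the interior optimum
  rHat <- if (ll0 > opt$objective) 0 else opt$maximum
  llHat <- max(ll0, opt$objective)
  lod <- (llHat - f2LogLik(0.5, counts)) / log(10)
  list(rHat = rHat, lod = lod, cmKosambi = kosambiCM(min(rHat, 0.5)), n = n)
}

#' Cross-tabulate two markers' genotypes
#'
#' @param genotypes long data.frame from [readMarkerGenotypes()].
#' @param markerA,markerB marker identifiers.
#' @return 3x3 count matrix (classes ss, rs, rr) over individuals
#'   non-missing at both markers, suitable for [estimateRF2()].
#' @export
crossTabGenotypes <- function(genotypes, markerA, markerB) {
  lv <- c("ss", "rs", "rr")
  a <- genotypes[genotypes$marker == markerA, c("individual", "genotype")]
  b <- genotypes[genotypes$marker == markerB, c("individual", "genotype")]
  m <- merge(a, b, by = "individual")
  m <- m[!is.na(m$genotype.x) & !is.na(m$genotype.y), ]
  table(factor(m$genotype.x, lv), factor(m$genotype.y, lv))
}

#' Map distance from recombinants in selected advanced-intercross survivors
#'
#' In survivors of a discriminating dose at generation Fn, each individual
#' contributes two scored chromosomes that have each passed through
#' \code{g = n - 1} meioses since the F1 gametes; the recombination fraction
#' is therefore \eqn{r = k / (2 N g)} for \code{k} recombinant individuals
#' among \code{N} scored.  The distance is reported as \eqn{100 r} cM by
#' default; the Kosambi correction is negligible at these scales and can be
#' switched on.
#'
#' @param k recombinant individuals (0 <= k <= 2 N g).
#' @param N individuals scored.
#' @param g meiotic generations separating the F1 gametes from the scored
#'   cohort (F4 => 3).
#' @param method \code{"morgan"} (\eqn{100 r}) or \code{"kosambi"}.
#' @return Map distance in cM.
#' @examples
#' advancedIntercrossDistance(9, 48, 3)   # 3.125 cM
#' @export
advancedIntercrossDistance <- function(k, N, g, method = c("morgan", "kosambi")) {
  method <- match.arg(method)
  stopifnot(N >= 1, g >= 1, k >= 0)
  if (k > 2 * N * g) stop("more recombinants than scored meioses (k > 2Ng)")
  r <- k / (2 * N * g)
  if (method == "kosambi") kosambiCM(min(r, 0.5)) else 100 * r
}

#' Summarise genotype-by-dose survival (epistasis tabulation)
#'
#' For each two-locus genotype class: total survivors across the dose
#' series, the maximum dose with at least one survivor, and the resistance
#' ratio of that dose to a reference lethal concentration.  When survivors
#' remain at the top tested dose the ratio is flagged as a lower bound.
#' Classes are ordered by maximum survival dose.
#'
#' @param table data.frame from [readDoseSurvivors()].
#' @param referenceLc reference lethal concentration (mg/L), e.g. the
#'   fully susceptible strain's LC99.9.
#' @return data.frame with one row per genotype pair: \code{genotype1},
#'   \code{genotype2}, \code{totalSurvivors} (selected doses only),
#'   \code{maxDose}, \code{resistanceRatio}, \code{lowerBound}.
#' @export
epistasisSummary <- function(table, referenceLc = 0.02) {
  if (referenceLc <= 0) stop("referenceLc must be positive")
  need <- c("genotype1", "genotype2", "dose", "survivors", "doseValue")
  stopifnot(all(need %in% names(table)))
  sel <- table[!is.na(table$doseValue), , drop = FALSE]
  topDose <- max(sel$doseValue)
  key <- interaction(sel$genotype1, sel$genotype2, drop = TRUE)
  out <- do.call(rbind, lapply(split(sel, key), function(d) {
    alive <- d$doseValue[d$survivors > 0]
    maxDose <- if (length(alive)) max(alive) else NA_real_
    data.frame(
      genotype1 = d$genotype1[1], genotype2 = d$genotype2[1],
      totalSurvivors = sum(d$survivors),
      maxDose = maxDose,
      resistanceRatio = maxDose / referenceLc,
      lowerBound = !is.na(maxDose) && maxDose == topDose &&
        any(d$survivors[d$doseValue == topDose] > 0),
      stringsAsFactors = FALSE)
  }))
  out <- out[order(out$maxDose, out$totalSurvivors, na.last = FALSE), ]
  rownames(out) <- NULL
  out
}
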