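#' Construct a SnpTable from site components
#'
#' Computes coverage, the primary variant and its percentage frequency from a
#' matrix of per-allele read counts.  Ties for the maximal count are broken
#' toward the alphabetically first base; this is deterministic and only
#' affects sites at exactly 50% frequency, where the scan statistic is
#' symmetric.  Any \code{N} counts must be removed upstream: only A/C/G/T
#' columns are accepted.
#'
#' @param seqId character vector of sequence identifiers.
#' @param pos integer vector of 1-based positions.
#' @param refBase character vector of declared reference bases (A/C/G/T/N).
#' @param counts numeric matrix with columns A, C, G, T of read counts.
#' @param pool optional pool label.
#' @return A \linkS4class{SnpTable}, sorted by (seqId, pos).
#' @examples
#' SnpTable("chr8", 5975000L, "A",
#'          matrix(c(3, 0, 7, 0), 1, dimnames = list(NULL, c("A","C","G","T"))))
#' @export
SnpTable <- function(seqId, pos, refBase, counts, pool = NA_character_) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) && ncol(counts) == 4L) colnames(counts) <- BASES
  stopifnot(all(BASES %in% colnames(counts)))
  counts <- counts[, BASES, drop = FALSE]
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  if (length(seqId) == 1L) seqId <- rep(seqId, n)
  if (length(refBase) == 1L) refBase <- rep(refBase, n)
  stopifnot(length(seqId) == n, length(pos) == n, length(refBase) == n)
  coverage <- as.integer(rowSums(counts))
  pi <- max.col(counts, ties.method = "first")  # alphabetical tie-break
  mx <- counts[cbind(seq_len(n), pi)]
  df <- data.frame(
    seqId = as.character(seqId), pos = as.integer(pos),
    refBase = toupper(as.character(refBase)),
    counts,
    coverage = coverage,
    primaryBase = BASES[pi],
    primaryFreqPct = 100 * mx / coverage,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$seqId, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  new("SnpTable", calls = df, pool = as.character(pool))
}

emptySnpTable <- function(pool = NA_character_) {
  SnpTable(character(), integer(), character(),
           matrix(integer(), 0, 4, dimnames = list(NULL, BASES)), pool)
}

#' @describeIn SnpTable-class the underlying data.frame of calls.
#' @param x,object a \code{SnpTable}.
#' @export
snpCalls <- function(x) {
  stopifnot(is(x, "SnpTable"))
  x@calls
}

#' @describeIn SnpTable-class pool label.
#' @export
poolLabel <- function(x) {
  stopifnot(is(x, "SnpTable"))
  x@pool
}

#' @export
setMethod("length", "SnpTable", function(x) nrow(x@calls))

setMethod("show", "SnpTable", function(object) {
  df <- object@calls
  cat(sprintf("SnpTable (pool: %s) with %d called sites on %d sequence(s)\n",
              object@pool, nrow(df), length(unique(df$seqId))))
  if (nrow(df)) {
    cat(sprintf("  median coverage %.0f, median primary-variant freq %.1f%%\n",
                stats::median(df$coverage), stats::median(df$primaryFreqPct)))
  }
})

#' @describeIn MergedSnpTable-class the merged rows.
#' @param x,object a \code{MergedSnpTable}.
#' @export
mergedRows <- function(x) {
  stopifnot(is(x, "MergedSnpTable"))
  x@rows
}

#' @describeIn MergedSnpTable-class source table identifiers.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "MergedSnpTable"))
  x@provenance
}

#' @export
setMethod("length", "MergedSnpTable", function(x) nrow(x@rows))

setMethod("show", "MergedSnpTable", function(object) {
  df <- object@rows
  cat(sprintf("MergedSnpTable: %d sites on %d sequence(s) [%s vs %s]\n",
              nrow(df), length(unique(df$seqId)),
              object@provenance[1], object@provenance[2]))
  if (nrow(df))
    cat(sprintf("  selected-only %d, unselected-only %d, shared %d\n",
                sum(is.na(df$unselFreqPct)), sum(is.na(df$selFreqPct)),
                sum(!is.na(df$selFreqPct) & !is.na(df$unselFreqPct))))
})

#' @describeIn WindowProfile-class the per-window table.
#' @param x,object a \code{WindowProfile}.
#' @export
profileWindows <- function(x) {
  stopifnot(is(x, "WindowProfile"))
  x@windows
}

#' @describeIn WindowProfile-class SNP-count window used per sequence.
#' @export
windowSizes <- function(x) {
  stopifnot(is(x, "WindowProfile"))
  x@windowSizes
}

setMethod("show", "WindowProfile", function(object) {
  df <- object@windows
  cat(sprintf("WindowProfile: %d windows on %d sequence(s)\n",
              nrow(df), length(unique(df$seqId))))
  for (s in names(object@windowSizes))
    cat(sprintf("  %s: window %d SNPs, %d windows\n",
                s, object@windowSizes[[s]], sum(df$seqId == s)))
})

#' Scan configuration constructor
#'
#' @param windowChrom SNP-count window for chromosome-scale sequences.
#' @param windowScaffold SNP-count window for short/unplaced sequences.
#' @param scaffoldLenCutoff sequence length (bp) below which
#'   \code{windowScaffold} applies.
#' @param minCov minimum coverage for a site to be called.
#' @param minVarFreqPct minimum variant-allele frequency (%) for a call.
#' @param selMinPct selected-pool window-mean threshold for region calling.
#' @param unselMaxPct unselected-pool window-mean ceiling for region calling.
#' @param minWindows minimum consecutive qualifying windows per region.
#' @param seqLengths optional named vector of sequence lengths in bp.
#' @return A validated \linkS4class{ScanConfig}.
#' @examples
#' scanConfig(windowScaffold = 40)
#' @export
scanConfig <- function(windowChrom = 300, windowScaffold = 50,
                       scaffoldLenCutoff = 1e6, minCov = 6,
                       minVarFreqPct = 35, selMinPct = 90,
                       unselMaxPct = 85, minWindows = 3,
                       seqLengths = numeric()) {
  new("ScanConfig",
      windowChrom = as.integer(windowChrom),
      windowScaffold = as.integer(windowScaffold),
      scaffoldLenCutoff = as.numeric(scaffoldLenCutoff),
      minCov = as.integer(minCov),
      minVarFreqPct = as.numeric(minVarFreqPct),
      selMinPct = as.numeric(selMinPct),
      unselMaxPct = as.numeric(unselMaxPct),
      minWindows = as.integer(minWindows),
      seqLengths = seqLengths)
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig\n")
  cat(sprintf("  windows: %d SNPs (chromosomes), %d SNPs (sequences < %g bp)\n",
              object@windowChrom, object@windowScaffold, object@scaffoldLenCutoff))
  cat(sprintf("  call filters: coverage >= %d, variant freq >= %g%%\n",
              object@minCov, object@minVarFreqPct))
  cat(sprintf("  region rule: selected mean >= %g%%, unselected mean <= %g%%, >= %d windows\n",
              object@selMinPct, object@unselMaxPct, object@minWindows))
})

#' Simulator configuration constructor
#'
#' Defaults emulate a scaled-down version of the sequenced advanced
#' intercross: two parental strains fixed for alternative alleles at every
#' site, an F2 cohort of 194 from a single F1 sibling pair, free mating at a
#' census of 750 thereafter, selection of double homozygotes at F4, pools of
#' 100 beetles sequenced at 5x mean coverage with a 0.1% per-read error.
#' Each simulated chromosome carries 1,000 SNP sites over 400 kb (matching
#' the ~2.5 called-SNPs/kb density of real pooled data) and 100 cM.
#'
#' @param chromosomes data.frame(name, lengthBp, lengthCM, nSites).
#' @param resistanceLoci data.frame(chrom, posBp); default one locus per
#'   chromosome at the 40% position.
#' @param nF2 F2 cohort size.
#' @param cohortSize census of each later cohort.
#' @param generations target cohort (4 = F4).
#' @param selectionDose nominal discriminating dose in mg/L (metadata).
#' @param poolSize individuals per sequenced pool.
#' @param meanCoverage Poisson mean coverage per site per pool.
#' @param seqError per-read miscall probability.
#' @param seed master seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' simConfig(seed = 1)
#' @export
simConfig <- function(chromosomes = data.frame(
                        name = c("chr1", "chr2"),
                        lengthBp = 4e5, lengthCM = 100, nSites = 1000L),
                      resistanceLoci = NULL,
                      nF2 = 194, cohortSize = 750, generations = 4,
                      selectionDose = 0.8, poolSize = 100,
                      meanCoverage = 5, seqError = 0.001, seed = 1) {
  if (is.null(resistanceLoci))
    resistanceLoci <- data.frame(
      chrom = chromosomes$name,
      posBp = round(0.4 * chromosomes$lengthBp))
  new("SimConfig",
      chromosomes = chromosomes, resistanceLoci = resistanceLoci,
      nF2 = as.integer(nF2), cohortSize = as.integer(cohortSize),
      generations = as.integer(generations),
      selectionDose = as.numeric(selectionDose),
      poolSize = as.integer(poolSize),
      meanCoverage = as.numeric(meanCoverage),
      seqError = as.numeric(seqError), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  ch <- object@chromosomes
  cat(sprintf("SimConfig: %d chromosome(s), %d SNP site(s), %d resistance locus/loci\n",
              nrow(ch), sum(ch$nSites), nrow(object@resistanceLoci)))
  cat(sprintf("  F2 census %d, later cohorts %d, target F%d, pool %d\n",
              object@nF2, object@cohortSize, object@generations, object@poolSize))
  cat(sprintf("  sequencing: lambda = %g, error = %g, seed = %d\n",
              object@meanCoverage, object@seqError, object@seed))
})

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult\n")
  show(object@merged)
  show(object@profile)
  cat(sprintf("  %d candidate region(s)\n", length(object@regions)))
})

#' @describeIn ScanResult-class candidate regions as a GRanges.
#' @param x,object a \code{ScanResult}.
#' @export
candidateRegions <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@regions
}

#' @describeIn ScanResult-class the merged two-pool table.
#' @export
scanMerged <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@merged
}

#' @describeIn ScanResult-class the window profile.
#' @export
scanProfile <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@profile
}
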