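#' @import methods
NULL

BASES <- c("A", "C", "G", "T")

#' Table of called SNPs in one sequenced pool
#'
#' One row per called variant site: sequence identifier, 1-based position,
#' declared reference base, per-allele read counts (A/C/G/T), total coverage,
#' and the primary variant -- the most common allele at the site regardless of
#' reference identity -- with its frequency expressed as a percentage of
#' coverage.  The primary-variant frequency is the statistic that the regional
#' averaging scan operates on.
#'
#' @slot calls data.frame with columns \code{seqId}, \code{pos},
#'   \code{refBase}, \code{A}, \code{C}, \code{G}, \code{T}, \code{coverage},
#'   \code{primaryBase}, \code{primaryFreqPct}, sorted by (seqId, pos).
#' @slot pool character label for the pool (e.g. "selected").
#'
#' @seealso [SnpTable()] for the constructor, [readSnpTable()],
#'   [readVcfPool()], [sequencePool()].
#' @export
setClass("SnpTable",
  representation(calls = "data.frame", pool = "character"),
  prototype(calls = data.frame(), pool = NA_character_)
)

setValidity("SnpTable", function(object) {
  df <- object@calls
  need <- c("seqId", "pos", "refBase", BASES, "coverage",
            "primaryBase", "primaryFreqPct")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  cnt <- as.matrix(df[BASES])
  if (any(cnt < 0L)) return("negative allele counts")
  if (any(df$pos < 1L)) return("positions must be >= 1")
  if (!all(df$coverage == rowSums(cnt)))
    return("coverage must equal the sum of allele counts")
  if (any(df$coverage < 1L)) return("coverage must be >= 1")
  mx <- do.call(pmax, df[BASES])
  if (!isTRUE(all.equal(df$primaryFreqPct, 100 * mx / df$coverage)))
    return("primaryFreqPct inconsistent with allele counts")
  if (!all(cnt[cbind(seq_len(nrow(df)), match(df$primaryBase, BASES))] == mx))
    return("primaryBase does not attain the maximal count")
  if (anyDuplicated(df[c("seqId", "pos")]))
    return("duplicate (seqId, pos)")
  if (is.unsorted(order(df$seqId, df$pos)))
    return("calls must be sorted by (seqId, pos)")
  TRUE
})

#' Merged two-pool SNP table
#'
#' The union of the selected and unselected pools' called sites, sorted by
#' sequence and position, with one primary-variant frequency column per pool.
#' A pool's cell is \code{NA} where that pool called no SNP at the site, so
#' that window averages can skip it exactly as a spreadsheet AVERAGE skips
#' blank cells.
#'
#' @slot rows data.frame with columns \code{seqId}, \code{pos},
#'   \code{selFreqPct}, \code{unselFreqPct}.
#' @slot provenance character(2): identifiers of the two source tables.
#' @seealso [mergePools()], [windowAverage()]
#' @export
setClass("MergedSnpTable",
  representation(rows = "data.frame", provenance = "character"),
  prototype(rows = data.frame(), provenance = c(NA_character_, NA_character_))
)

setValidity("MergedSnpTable", function(object) {
  df <- object@rows
  need <- c("seqId", "pos", "selFreqPct", "unselFreqPct")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(is.na(df$selFreqPct) & is.na(df$unselFreqPct)))
    return("every row needs at least one pool frequency")
  if (anyDuplicated(df[c("seqId", "pos")]))
    return("duplicate (seqId, pos)")
  if (is.unsorted(order(df$seqId, df$pos)))
    return("rows must be sorted by (seqId, pos)")
  ok <- function(x) all(is.na(x) | (x > 0 & x <= 100))
  if (!ok(df$selFreqPct) || !ok(df$unselFreqPct))
    return("frequencies must lie in (0, 100]")
  TRUE
})

#' Sliding-window profile of averaged primary-variant frequencies
#'
#' Per sequence, one entry per dynamic window: a block of \code{windowSize}
#' consecutive merged rows, advancing one SNP per step.  Window means are
#' computed per pool over the non-missing cells in the block.
#'
#' @slot windows data.frame with columns \code{seqId}, \code{windowIndex},
#'   \code{firstPos}, \code{lastPos}, \code{selMeanPct}, \code{unselMeanPct},
#'   \code{nSel}, \code{nUnsel}.
#' @slot windowSizes named integer: the SNP-count window used per sequence.
#' @seealso [windowAverage()], [callCandidateRegions()]
#' @export
setClass("WindowProfile",
  representation(windows = "data.frame", windowSizes = "integer"),
  prototype(windows = data.frame(), windowSizes = integer())
)

setValidity("WindowProfile", function(object) {
  df <- object@windows
  need <- c("seqId", "windowIndex", "firstPos", "lastPos",
            "selMeanPct", "unselMeanPct", "nSel", "nUnsel")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(df$firstPos > df$lastPos)) return("firstPos must be <= lastPos")
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 100))
  if (!ok(df$selMeanPct) || !ok(df$unselMeanPct))
    return("window means must lie in [0, 100]")
  if (!all(unique(df$seqId) %in% names(object@windowSizes)))
    return("windowSizes must name every sequence in the profile")
  TRUE
})

#' Configuration for the regional-averaging scan
#'
#' Holds the SNP call filters and the window/threshold parameters of the
#' differential-homozygosity scan.  Defaults follow the published analysis:
#' 300-SNP windows on chromosome-scale sequences, 50-SNP windows on short
#' sequences, calls restricted to coverage >= 6 with a variant-allele
#' frequency >= 35%, and regions requiring the selected pool near
#' homozygosity (window mean >= 90%) while the unselected pool stays
#' heterozygous (<= 85%).
#'
#' @slot windowChrom integer, SNP-count window for chromosome-scale sequences.
#' @slot windowScaffold integer, SNP-count window for short sequences.
#' @slot scaffoldLenCutoff numeric, sequence length (bp) below which
#'   \code{windowScaffold} applies.
#' @slot minCov integer, minimum site coverage for a call.
#' @slot minVarFreqPct numeric, minimum variant-allele frequency (%) for a call.
#' @slot selMinPct numeric, selected-pool window-mean threshold.
#' @slot unselMaxPct numeric, unselected-pool window-mean ceiling.
#' @slot minWindows integer, minimum consecutive qualifying windows per region.
#' @slot seqLengths named numeric or NULL-length, sequence lengths in bp; when
#'   empty, lengths are estimated from the data as the maximal SNP position.
#' @seealso [scanConfig()], [scanPools()]
#' @export
setClass("ScanConfig",
  representation(
    windowChrom = "integer", windowScaffold = "integer",
    scaffoldLenCutoff = "numeric", minCov = "integer",
    minVarFreqPct = "numeric", selMinPct = "numeric",
    unselMaxPct = "numeric", minWindows = "integer",
    seqLengths = "numeric"
  )
)

setValidity("ScanConfig", function(object) {
  if (object@windowChrom < 1L || object@windowScaffold < 1L)
    return("window sizes must be >= 1")
  thr <- c(object@minVarFreqPct, object@selMinPct, object@unselMaxPct)
  if (any(thr <= 0) || any(thr > 100))
    return("percentage thresholds must lie in (0, 100]")
  if (object@selMinPct <= object@unselMaxPct)
    return("selMinPct must exceed unselMaxPct")
  if (object@minCov < 1L) return("minCov must be >= 1")
  if (object@minWindows < 1L) return("minWindows must be >= 1")
  TRUE
})

#' Configuration for the advanced-intercross pool-seq simulator
#'
#' Describes the cross and the sequencing step: chromosomes (physical and
#' genetic length, number of fixed biallelic SNP sites), resistance loci,
#' cohort sizes, target generation, selection, pool size, mean sequencing
#' coverage and the per-read error rate.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{lengthBp},
#'   \code{lengthCM}, \code{nSites}.
#' @slot resistanceLoci data.frame with columns \code{chrom}, \code{posBp}.
#' @slot nF2 integer, size of the F2 cohort.
#' @slot cohortSize integer, census of each later generational cohort.
#' @slot generations integer, target cohort index (4 = F4).
#' @slot selectionDose numeric, nominal discriminating dose (mg/L) recorded
#'   with the run; the default rule is all-or-nothing in genotype, not dose.
#' @slot poolSize integer, individuals per sequenced pool.
#' @slot meanCoverage numeric, Poisson mean coverage per site per pool.
#' @slot seqError numeric, per-read miscall probability.
#' @slot seed integer, master seed for the run.
#' @seealso [simConfig()], [simulateExperiment()]
#' @export
setClass("SimConfig",
  representation(
    chromosomes = "data.frame", resistanceLoci = "data.frame",
    nF2 = "integer", cohortSize = "integer", generations = "integer",
    selectionDose = "numeric", poolSize = "integer",
    meanCoverage = "numeric", seqError = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  ch <- object@chromosomes
  if (!all(c("name", "lengthBp", "lengthCM", "nSites") %in% names(ch)))
    return("chromosomes needs columns name, lengthBp, lengthCM, nSites")
  if (nrow(ch) < 1L) return("at least one chromosome required")
  if (any(ch$nSites < 1L)) return("every chromosome needs at least one SNP site")
  if (any(ch$lengthBp <= 0) || any(ch$lengthCM < 0))
    return("chromosome lengths must be positive (cM may be 0)")
  rl <- object@resistanceLoci
  if (nrow(rl)) {
    if (!all(c("chrom", "posBp") %in% names(rl)))
      return("resistanceLoci needs columns chrom, posBp")
    if (!all(rl$chrom %in% ch$name))
      return("resistance locus on unknown chromosome")
    len <- ch$lengthBp[match(rl$chrom, ch$name)]
    if (any(rl$posBp < 1 | rl$posBp > len))
      return("resistance locus position outside its chromosome")
  }
  if (object@nF2 < 2L || object@cohortSize < 2L)
    return("cohort census must be >= 2")
  if (object@generations < 2L)
    return("target generation must be F2 or later")
  if (object@poolSize < 1L) return("poolSize must be >= 1")
  if (object@meanCoverage <= 0) return("meanCoverage must be positive")
  if (object@seqError < 0 || object@seqError >= 0.25)
    return("seqError must lie in [0, 0.25)")
  TRUE
})

#' Result of a full two-pool scan
#'
#' Bundles the merged table, the window profile, the called candidate regions
#' (a \linkS4class{GRanges}) and the configuration used.
#'
#' @slot merged a \linkS4class{MergedSnpTable}.
#' @slot profile a \linkS4class{WindowProfile}.
#' @slot regions a \code{GRanges} of candidate regions (1-based closed).
#' @slot config the \linkS4class{ScanConfig} used.
#' @seealso [scanPools()]
#' @export
setClass("ScanResult",
  representation(
    merged = "MergedSnpTable", profile = "WindowProfile",
    regions = "GRanges", config = "ScanConfig"
  )
)
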