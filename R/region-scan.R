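#' Apply the SNP call filters
#'
#' Keeps a site iff its coverage reaches \code{minCov} and at least one
#' allele differing from the declared reference base has a frequency of at
#' least \code{minVarFreqPct} percent of coverage.  Order is preserved.
#'
#' @param x a \linkS4class{SnpTable}.
#' @param config a \linkS4class{ScanConfig} supplying \code{minCov} and
#'   \code{minVarFreqPct}.
#' @return The filtered \linkS4class{SnpTable}.
#' @export
applyCallFilters <- function(x, config = scanConfig()) {
  stopifnot(is(x, "SnpTable"), is(config, "ScanConfig"))
  df <- snpCalls(x)
  if (nrow(df) == 0L) return(x)
  cnt <- as.matrix(df[BASES])
  ref <- match(df$refBase, BASES)          # NA for N references: all alleles count
  nonRef <- cnt
  has <- !is.na(ref)
  nonRef[cbind(which(has), ref[has])] <- 0L
  maxVar <- do.call(pmax, as.data.frame(nonRef))
  keep <- df$coverage >= config@minCov &
    100 * maxVar / df$coverage >= config@minVarFreqPct
  initialize(x, calls = { d <- df[keep, , drop = FALSE]; rownames(d) <- NULL; d })
}

#' Merge two pools' SNP tables into one aligned table
#'
#' One row per site in the union of the two pools' call sets, sorted by
#' sequence then position; a pool's primary-variant frequency cell is missing
#' (\code{NA}) where that pool called no SNP at the site.
#'
#' @param selected,unselected \linkS4class{SnpTable}s of the two pools
#'   (already filtered).
#' @return A \linkS4class{MergedSnpTable}.
#' @export
mergePools <- function(selected, unselected) {
  stopifnot(is(selected, "SnpTable"), is(unselected, "SnpTable"))
  take <- function(x, col) {
    df <- snpCalls(x)
    d <- anyDuplicated(df[c("seqId", "pos")])
    if (d)
      stop("duplicate position within one pool: ",
           df$seqId[d], ":", df$pos[d])
    out <- df[c("seqId", "pos")]
    out[[col]] <- df$primaryFreqPct
    out
  }
  m <- merge(take(selected, "selFreqPct"), take(unselected, "unselFreqPct"),
             by = c("seqId", "pos"), all = TRUE)
  m <- m[order(m$seqId, m$pos), , drop = FALSE]
  rownames(m) <- NULL
  new("MergedSnpTable", rows = m,
      provenance = c(poolLabel(selected), poolLabel(unselected)))
}

#' Choose the SNP-count window for one sequence
#'
#' Chromosome-scale sequences (length above \code{scaffoldLenCutoff}) use the
#' full window; shorter sequences use the scaffold window, capped at the
#' number of SNPs actually called on the sequence.
#'
#' @param seqLength sequence length in bp.
#' @param nSnps number of merged SNP rows on the sequence (>= 1).
#' @param config a \linkS4class{ScanConfig}.
#' @return A positive integer window size.
#' @examples
#' chooseWindowSize(2e7, 50000)   # 300
#' chooseWindowSize(2e5, 30)      # 30
#' @export
chooseWindowSize <- function(seqLength, nSnps, config = scanConfig()) {
  stopifnot(nSnps >= 1L)
  if (seqLength > config@scaffoldLenCutoff) config@windowChrom
  else min(config@windowScaffold, as.integer(nSnps))
}

## NA-skipping rolling mean over fixed-count blocks, stride 1.
rollMeanSkipNA <- function(v, w) {
  n <- length(v)
  s <- cumsum(ifelse(is.na(v), 0, v))
  k <- cumsum(!is.na(v))
  i <- seq_len(n - w + 1L)
  sums <- s[i + w - 1L] - c(0, s)[i]
  cnts <- k[i + w - 1L] - c(0, k)[i]
  list(mean = ifelse(cnts > 0L, sums / cnts, NA_real_), n = cnts)
}

#' Dynamic-window averages of primary-variant frequencies
#'
#' For each sequence with at least \code{windowSize} merged rows, computes
#' one entry per contiguous block of \code{windowSize} rows, advancing one
#' SNP per step.  Each pool's mean is taken over the non-missing cells in
#' the block, mirroring spreadsheet averaging of two frequency columns with
#' blanks; a mean is missing only when a pool has no cell in the window.
#' Sequences with fewer rows than the window produce a single whole-sequence
#' window, with a warning.  Windows never cross sequence boundaries.
#'
#' @param merged a \linkS4class{MergedSnpTable}.
#' @param windowSize a single SNP-count window, or a named vector giving one
#'   per sequence.
#' @return A \linkS4class{WindowProfile}.
#' @examples
#' sel <- SnpTable(rep("s", 3), 1:3 * 100L, "A",
#'                 matrix(c(0,10,9, 0,0,0, 10,0,1, 0,0,0), 3,
#'                        dimnames = list(NULL, c("A","C","G","T"))))
#' windowAverage(mergePools(sel, sel), 2)
#' @export
windowAverage <- function(merged, windowSize) {
  stopifnot(is(merged, "MergedSnpTable"))
  if (any(windowSize < 1L)) stop("windowSize must be >= 1")
  df <- mergedRows(merged)
  seqs <- unique(df$seqId)
  pieces <- vector("list", length(seqs))
  used <- integer(length(seqs))
  names(used) <- seqs
  for (si in seq_along(seqs)) {
    s <- seqs[si]
    d <- df[df$seqId == s, , drop = FALSE]
    w <- if (length(windowSize) > 1L) {
      if (!s %in% names(windowSize))
        stop("no window size given for sequence ", s)
      as.integer(windowSize[[s]])
    } else as.integer(windowSize)
    if (nrow(d) < w) {
      warning("sequence ", s, " has ", nrow(d), " SNPs < window ", w,
              "; using one whole-sequence window")
      w <- nrow(d)
    }
    used[si] <- w
    selR <- rollMeanSkipNA(d$selFreqPct, w)
    unsR <- rollMeanSkipNA(d$unselFreqPct, w)
    i <- seq_len(nrow(d) - w + 1L)
    pieces[[si]] <- data.frame(
      seqId = s, windowIndex = i,
      firstPos = d$pos[i], lastPos = d$pos[i + w - 1L],
      selMeanPct = selR$mean, unselMeanPct = unsR$mean,
      nSel = selR$n, nUnsel = unsR$n,
      stringsAsFactors = FALSE)
  }
  new("WindowProfile", windows = do.call(rbind, pieces), windowSizes = used)
}

#' Call candidate regions of differential homozygosity
#'
#' Scans each sequence's window profile for maximal runs of at least
#' \code{minWindows} consecutive windows in which the selected pool's mean
#' primary-variant frequency reaches \code{selMinPct} (near homozygosity)
#' while the unselected pool's mean stays at or below \code{unselMaxPct}
#' (still heterozygous).  Each run becomes one region spanning the first
#' qualifying window's first SNP to the last qualifying window's last SNP.
#'
#' @param profile a \linkS4class{WindowProfile}.
#' @param config a \linkS4class{ScanConfig}.
#' @param merged optional \linkS4class{MergedSnpTable} used to count the
#'   SNPs inside each region (\code{nSnps} is \code{NA} without it).
#' @return A \code{GRanges} (1-based closed) sorted by sequence then start,
#'   with metadata columns \code{regionId}, \code{meanSelPct},
#'   \code{meanUnselPct}, \code{nWindows}, \code{nSnps}.
#' @export
callCandidateRegions <- function(profile, config = scanConfig(), merged = NULL) {
  stopifnot(is(profile, "WindowProfile"), is(config, "ScanConfig"))
  df <- profileWindows(profile)
  out <- list()
  for (s in unique(df$seqId)) {
    d <- df[df$seqId == s, , drop = FALSE]
    qual <- !is.na(d$selMeanPct) & !is.na(d$unselMeanPct) &
      d$selMeanPct >= config@selMinPct & d$unselMeanPct <= config@unselMaxPct
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= config@minWindows)
    for (h in hit) {
      i <- starts[h]:ends[h]
      out[[length(out) + 1L]] <- data.frame(
        seqId = s, start = d$firstPos[starts[h]], end = d$lastPos[ends[h]],
        meanSelPct = mean(d$selMeanPct[i]),
        meanUnselPct = mean(d$unselMeanPct[i]),
        nWindows = length(i), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(GenomicRanges::GRanges(
      regionId = character(), meanSelPct = numeric(),
      meanUnselPct = numeric(), nWindows = integer(), nSnps = integer()))
  reg <- do.call(rbind, out)
  reg <- reg[order(reg$seqId, reg$start), , drop = FALSE]
  nSnps <- rep(NA_integer_, nrow(reg))
  if (!is.null(merged)) {
    m <- mergedRows(merged)
    for (i in seq_len(nrow(reg)))
      nSnps[i] <- sum(m$seqId == reg$seqId[i] &
                        m$pos >= reg$start[i] & m$pos <= reg$end[i])
  }
  GenomicRanges::GRanges(
    seqnames = reg$seqId,
    ranges = IRanges::IRanges(start = reg$start, end = reg$end),
    regionId = sprintf("region_%d", seq_len(nrow(reg))),
    meanSelPct = reg$meanSelPct, meanUnselPct = reg$meanUnselPct,
    nWindows = reg$nWindows, nSnps = nSnps)
}

#' Run the full two-pool regional-averaging scan
#'
#' Reads (if given paths) and filters the two pools' SNP tables, merges them,
#' chooses a per-sequence window (chromosome vs scaffold routing by sequence
#' length), computes the dynamic-window averages and calls candidate regions.
#' Deterministic given inputs and configuration.
#'
#' @param selected,unselected \linkS4class{SnpTable}s or file paths readable
#'   by [readSnpTable()].
#' @param config a \linkS4class{ScanConfig}.  When \code{config@seqLengths}
#'   is empty, each sequence's length is estimated as its maximal SNP
#'   position (this only matters for window routing).
#' @param dialect dialect passed to [readSnpTable()] when paths are given.
#' @return A \linkS4class{ScanResult}.
#' @export
scanPools <- function(selected, unselected, config = scanConfig(),
                      dialect = "counts") {
  if (is.character(selected)) selected <- readSnpTable(selected, dialect)
  if (is.character(unselected)) unselected <- readSnpTable(unselected, dialect)
  selF <- applyCallFilters(selected, config)
  unsF <- applyCallFilters(unselected, config)
  merged <- mergePools(selF, unsF)
  df <- mergedRows(merged)
  if (nrow(df) == 0L)
    stop("no SNPs survive the call filters in either pool")
  seqs <- unique(df$seqId)
  lens <- config@seqLengths
  w <- vapply(seqs, function(s) {
    n <- sum(df$seqId == s)
    L <- if (s %in% names(lens)) lens[[s]] else max(df$pos[df$seqId == s])
    chooseWindowSize(L, n, config)
  }, integer(1))
  names(w) <- seqs
  profile <- windowAverage(merged, w)
  regions <- callCandidateRegions(profile, config, merged)
  new("ScanResult", merged = merged, profile = profile,
      regions = regions, config = config)
}
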