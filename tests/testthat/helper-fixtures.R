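# fixture builders shared across test files; everything is generated in code

writeCountsTsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("seq_id\tpos\tref_base\tallele_counts\tcoverage", rows), path)
  path
}

writeFreqTsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(paste("seq_id", "pos", "ref_base", "variant_base", "coverage",
                     "var_freq_pct", sep = "\t"), rows), path)
  path
}

writeMiniVcf <- function(bodyRows, path = tempfile(fileext = ".vcf"),
                         format = "DP:AD") {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr8>", "##contig=<ID=chr9>",
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpool1")
  writeLines(c(hdr, bodyRows), path)
  path
}

# a SnpTable from positions and a single variant base count pattern
simpleSnpTable <- function(seqId, pos, refCnt, altCnt,
                           ref = "A", alt = "G", pool = NA_character_) {
  n <- length(pos)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[, ref] <- as.integer(refCnt)
  counts[, alt] <- counts[, alt] + as.integer(altCnt)
  SnpTable(seqId, as.integer(pos), ref, counts, pool)
}

makeMergedTable <- function(seqId, pos, sel, unsel) {
  new("MergedSnpTable",
      rows = data.frame(seqId = seqId, pos = as.integer(pos),
                        selFreqPct = sel, unselFreqPct = unsel),
      provenance = c("selected", "unselected"))
}

makeProfile <- function(selMeans, unselMeans, seqId = "chr1", windowSize = 2L) {
  n <- length(selMeans)
  new("WindowProfile",
      windows = data.frame(seqId = seqId, windowIndex = seq_len(n),
                           firstPos = seq_len(n) * 100L,
                           lastPos = seq_len(n) * 100L + 100L,
                           selMeanPct = selMeans, unselMeanPct = unselMeans,
                           nSel = windowSize, nUnsel = windowSize),
      windowSizes = stats::setNames(windowSize, seqId))
}

# independent per-window recomputation (spreadsheet AVERAGE over each block)
bruteWindowMeans <- function(v, w) {
  n <- length(v)
  vapply(seq_len(n - w + 1L), function(i) {
    x <- v[i:(i + w - 1L)]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, 0)
}

# random merged table with a given fraction of one-pool-only rows
randomMergedTable <- function(n, naFrac) {
  sel <- runif(n, 35, 100)
  uns <- runif(n, 35, 100)
  selNA <- runif(n) < naFrac / 2
  unsNA <- runif(n) < naFrac / 2 & !selNA
  sel[selNA] <- NA
  uns[unsNA] <- NA
  makeMergedTable("chrX", seq_len(n) * 10L, sel, uns)
}

haldaneCM <- function(r) -50 * log(1 - 2 * r)
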