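## On-disk formats
##
## SNP table, dialect "counts" (tab-separated, header required):
##   seq_id  pos  ref_base  allele_counts  coverage
## with allele_counts a comma list such as "A:3,G:7".
##
## SNP table, dialect "freq" (the shape of variant-caller exports that give a
## single variant with its percentage frequency):
##   seq_id  pos  ref_base  variant_base  coverage  var_freq_pct
## Counts are reconstructed by rounding coverage * frequency.
##
## Marker genotypes (CSV): individual, marker, genotype  (rr/rs/ss or blank).
## Dose-survivor counts (CSV): genotype1, genotype2, dose, survivors with
## dose either "unselected" or a concentration in mg/L.

#' Read a per-pool SNP table
#'
#' Reads one pool's called variants from a tab-separated table in either the
#' \code{counts} dialect (per-allele read counts) or the \code{freq} dialect
#' (one variant base with its percentage frequency, from which counts are
#' reconstructed by rounding \code{coverage * freq / 100}).  \code{N} allele
#' counts are dropped before the primary variant is computed.  Malformed rows
#' (unparsable counts, non-positive coverage, bad bases) are rejected with a
#' single warning giving the count.
#'
#' @param path file path.
#' @param dialect \code{"counts"} or \code{"freq"}.
#' @param pool optional pool label; defaults to the file name.
#' @return A \linkS4class{SnpTable} sorted by (seqId, pos).
#' @export
readSnpTable <- function(path, dialect = c("counts", "freq"), pool = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("format error: file not found: ", path)
  if (is.null(pool)) pool <- basename(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  need <- if (dialect == "counts")
    c("seq_id", "pos", "ref_base", "allele_counts", "coverage")
  else
    c("seq_id", "pos", "ref_base", "variant_base", "coverage", "var_freq_pct")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty SNP table: ", path)
    return(emptySnpTable(pool))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  cov <- suppressWarnings(as.numeric(df$coverage))
  counts <- matrix(0L, nrow(df), 4, dimnames = list(NULL, BASES))
  bad <- is.na(pos) | pos < 1L
  if (dialect == "counts") {
    parsed <- strsplit(df$allele_counts, ",", fixed = TRUE)
    for (i in seq_along(parsed)) {
      kv <- strsplit(parsed[[i]], ":", fixed = TRUE)
      b <- toupper(vapply(kv, `[`, "", 1L))
      n <- suppressWarnings(as.integer(vapply(kv, `[`, "", 2L)))
      keep <- b %in% BASES & !is.na(n) & n >= 0L   # drops N alleles
      if (any(!(b %in% c(BASES, "N"))) || anyNA(n)) bad[i] <- TRUE
      if (any(keep)) counts[i, b[keep]] <- n[keep]
    }
  } else {
    freq <- suppressWarnings(as.numeric(df$var_freq_pct))
    vb <- toupper(df$variant_base)
    rb <- toupper(df$ref_base)
    ok <- !is.na(freq) & freq > 0 & freq <= 100 & vb %in% BASES &
      rb %in% BASES & !is.na(cov) & cov > 0
    bad <- bad | !ok
    vn <- as.integer(round(cov * freq / 100))
    for (i in which(ok)) {
      counts[i, vb[i]] <- vn[i]
      counts[i, rb[i]] <- counts[i, rb[i]] + as.integer(cov[i]) - vn[i]
    }
  }
  bad <- bad | rowSums(counts) < 1L
  if (any(bad))
    warning(sum(bad), " malformed row(s) rejected from ", path)
  keep <- !bad
  SnpTable(df$seq_id[keep], pos[keep], df$ref_base[keep],
           counts[keep, , drop = FALSE], pool)
}

#' Write a SnpTable in the counts dialect
#'
#' Only alleles with positive counts are listed, so a write/read round trip
#' reproduces (seqId, pos, allele counts) exactly.
#'
#' @param x a \linkS4class{SnpTable}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSnpTable <- function(x, path) {
  stopifnot(is(x, "SnpTable"))
  df <- snpCalls(x)
  cnt <- as.matrix(df[BASES])
  alleles <- apply(cnt, 1L, function(v) {
    i <- which(v > 0L)
    paste(sprintf("%s:%d", BASES[i], v[i]), collapse = ",")
  })
  if (nrow(df) == 0L) alleles <- character()
  out <- data.frame(seq_id = df$seqId, pos = df$pos, ref_base = df$refBase,
                    allele_counts = alleles, coverage = df$coverage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pooled sample from a VCF
#'
#' Converts a single-pool VCF with per-allele depths (the \code{AD} genotype
#' field) into a \linkS4class{SnpTable}.  Multiallelic SNVs contribute every
#' single-base allele; records without allele depths, or whose alleles are
#' not single bases, are skipped and counted in a warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @param pool optional pool label.
#' @return A \linkS4class{SnpTable}.
#' @export
readVcfPool <- function(path, pool = NULL) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  if (is.null(pool)) pool <- basename(path)
  vcf <- VariantAnnotation::readVcf(path)
  g <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(g))
    stop("format error: no per-allele depth (AD) field in ", path)
  adRaw <- g$AD
  ad <- if (length(dim(adRaw)) == 3L)   # fixed-length AD comes back as an array
    lapply(seq_len(dim(adRaw)[1L]), function(i) adRaw[i, 1L, ])
  else adRaw[, 1L]
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(rr$REF)
  alts <- VariantAnnotation::alt(vcf)
  n <- length(rr)
  seqId <- character(n); pos <- integer(n); refB <- character(n)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  skipped <- 0L
  kept <- logical(n)
  sq <- as.character(GenomicRanges::seqnames(rr))
  st <- GenomicRanges::start(rr)
  for (i in seq_len(n)) {
    a <- ad[[i]]
    al <- c(refs[i], as.character(alts[[i]]))
    if (is.null(a) || all(is.na(a)) || length(a) != length(al) ||
        !all(al %in% BASES)) {
      skipped <- skipped + 1L
      next
    }
    a[is.na(a)] <- 0L
    if (sum(a) < 1L) { skipped <- skipped + 1L; next }
    kept[i] <- TRUE
    seqId[i] <- sq[i]; pos[i] <- st[i]; refB[i] <- refs[i]
    for (j in seq_along(al)) counts[i, al[j]] <- counts[i, al[j]] + as.integer(a[j])
  }
  if (!any(kept) && n > 0L)
    stop("format error: no VCF record carried usable allele depths")
  if (skipped)
    warning(skipped, " VCF record(s) without usable allele depths skipped")
  SnpTable(seqId[kept], pos[kept], refB[kept], counts[kept, , drop = FALSE], pool)
}

#' Write candidate regions as BED
#'
#' Internal coordinates are 1-based closed; BED lines are 0-based half-open,
#' so a single-SNP region becomes an interval of length 1.  The score column
#' carries the mean selected window average rescaled to [0, 1000].
#' Overlapping regions are written as-is.
#'
#' @param regions a \code{GRanges} as returned by [callCandidateRegions()].
#' @param path output file path.
#' @param config optional \linkS4class{ScanConfig} echoed into the header.
#' @return invisibly, \code{path}.
#' @export
writeRegionsBed <- function(regions, path, config = NULL) {
  hdr <- "# poolBSA candidate regions; score = mean selected window average scaled to [0,1000]"
  if (!is.null(config))
    hdr <- c(hdr, sprintf("# region rule: selected mean >= %g%%, unselected mean <= %g%%, >= %d consecutive windows",
                          config@selMinPct, config@unselMaxPct, config@minWindows))
  writeLines(hdr, path)
  if (length(regions) == 0L) return(invisible(path))
  m <- S4Vectors::mcols(regions)
  nm <- if ("regionId" %in% names(m)) m$regionId
        else sprintf("region_%d", seq_along(regions))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    name = nm,
    score = as.integer(round(10 * m$meanSelPct))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write the merged two-pool table
#'
#' @param x a \linkS4class{MergedSnpTable}.
#' @param path output path (tab-separated; empty cells where a pool called
#'   no SNP).
#' @return invisibly, \code{path}.
#' @export
writeMergedTable <- function(x, path) {
  stopifnot(is(x, "MergedSnpTable"))
  df <- mergedRows(x)
  out <- data.frame(seq_id = df$seqId, pos = df$pos,
                    sel_freq_pct = df$selFreqPct,
                    unsel_freq_pct = df$unselFreqPct)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a window profile
#'
#' @param x a \linkS4class{WindowProfile}.
#' @param path output path (tab-separated).
#' @return invisibly, \code{path}.
#' @export
writeProfile <- function(x, path) {
  stopifnot(is(x, "WindowProfile"))
  df <- profileWindows(x)
  names(df) <- c("seq_id", "window_index", "first_pos", "last_pos",
                 "sel_mean_pct", "unsel_mean_pct", "n_sel", "n_unsel")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format marker genotype table
#'
#' @param path CSV with columns \code{individual}, \code{marker},
#'   \code{genotype}; genotypes are \code{rr}, \code{rs}, \code{ss} or blank
#'   for missing (\code{sr} is normalised to \code{rs}).
#' @return data.frame with those three columns, genotype \code{NA} where
#'   missing.
#' @export
readMarkerGenotypes <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("individual", "marker", "genotype")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  g <- tolower(trimws(df$genotype))
  g[g == "sr"] <- "rs"
  g[g %in% c("", "na", "missing", ".")] <- NA_character_
  bad <- !is.na(g) & !g %in% c("rr", "rs", "ss")
  if (any(bad))
    stop("format error: invalid genotype code(s): ",
         paste(unique(df$genotype[bad]), collapse = ", "))
  data.frame(individual = df$individual, marker = df$marker, genotype = g,
             stringsAsFactors = FALSE)
}

#' Read a genotype-by-dose survivor count table
#'
#' @param path CSV with columns \code{genotype1}, \code{genotype2},
#'   \code{dose}, \code{survivors}; \code{dose} is \code{"unselected"} or a
#'   concentration in mg/L.
#' @return data.frame with an added numeric \code{doseValue} column
#'   (\code{NA} for the unselected sentinel).
#' @export
readDoseSurvivors <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype1", "genotype2", "dose", "survivors")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(is.na(df$survivors)) || any(df$survivors < 0))
    stop("format error: survivor counts must be non-negative")
  dv <- suppressWarnings(as.numeric(df$dose))
  if (any(is.na(dv) & tolower(df$dose) != "unselected"))
    stop("format error: dose must be numeric or 'unselected'")
  df$doseValue <- dv
  df
}
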