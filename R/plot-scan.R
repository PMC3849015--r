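#' Plot the regional-averaging scan
#'
#' One panel per sequence, with the selected and unselected window means
#' traced against the window index.  As in the spreadsheet analysis the
#' x-axis is a non-linear scale determined by the number of SNPs: each step
#' is one SNP, not a fixed physical distance; physical positions are
#' annotated at the tick marks.  Called candidate regions are shaded.
#'
#' @param profile a \linkS4class{WindowProfile}.
#' @param regions optional \code{GRanges} from [callCandidateRegions()].
#' @param file output image path; when \code{NULL}, draws on the current
#'   device.
#' @param format \code{"png"} or \code{"svg"} (used when \code{file} is
#'   given).
#' @param annotatePositions label x ticks with physical positions?
#' @return invisibly, \code{file} (or \code{NULL} when the profile is
#'   empty: nothing is drawn and a warning is raised).
#' @export
plotScan <- function(profile, regions = NULL, file = NULL,
                     format = c("png", "svg"), annotatePositions = TRUE) {
  stopifnot(is(profile, "WindowProfile"))
  format <- match.arg(format)
  df <- profileWindows(profile)
  if (nrow(df) == 0L) {
    warning("empty window profile: nothing to plot")
    return(invisible(NULL))
  }
  seqs <- unique(df$seqId)
  if (!is.null(file)) {
    if (format == "png")
      grDevices::png(file, width = 960, height = 280 * length(seqs))
    else
      grDevices::svg(file, width = 10, height = 3 * length(seqs))
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(length(seqs), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (s in seqs) {
    d <- df[df$seqId == s, , drop = FALSE]
    graphics::plot(NA, xlim = range(d$windowIndex), ylim = c(0, 100),
                   xlab = "window (one step = one SNP)",
                   ylab = "mean primary variant freq (%)",
                   main = s, xaxt = if (annotatePositions) "n" else "s")
    if (annotatePositions) {
      at <- pretty(d$windowIndex)
      at <- at[at >= min(d$windowIndex) & at <= max(d$windowIndex)]
      lab <- sprintf("%.2f Mb", d$firstPos[match(at, d$windowIndex)] / 1e6)
      graphics::axis(1, at = at, labels = lab)
    }
    if (!is.null(regions) && length(regions)) {
      hits <- which(as.character(GenomicRanges::seqnames(regions)) == s)
      for (h in hits) {
        inside <- d$lastPos >= GenomicRanges::start(regions)[h] &
          d$firstPos <= GenomicRanges::end(regions)[h]
        if (any(inside))
          graphics::rect(min(d$windowIndex[inside]), 0,
                         max(d$windowIndex[inside]), 100,
                         col = grDevices::rgb(0.85, 0.85, 0.6, 0.5),
                         border = NA)
      }
    }
    graphics::lines(d$windowIndex, d$selMeanPct, col = "firebrick", lwd = 1.5)
    graphics::lines(d$windowIndex, d$unselMeanPct, col = "steelblue", lwd = 1.5)
    graphics::legend("bottomleft", legend = c("selected", "unselected"),
                     col = c("firebrick", "steelblue"), lwd = 1.5, bty = "n",
                     cex = 0.8)
  }
  invisible(file)
}
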