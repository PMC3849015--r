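#' Population of diploid individuals in the simulated cross
#'
#' Haplotypes are coded per chromosome as integer matrices with one row per
#' haplotype (rows 2i-1 and 2i belong to individual i) and one column per
#' fixed SNP site; 1 marks the resistant-strain allele, 0 the susceptible
#' strain.  Because the two parental strains are fully homozygous and differ
#' at every site, allele origin fully describes a haplotype.
#'
#' @slot hap named list of integer matrices (2N x nSites), one per chromosome.
#' @slot sites named list of data.frames with \code{posBp}, \code{posCM}.
#' @slot alleles named list of data.frames with \code{refBase} (susceptible
#'   strain) and \code{altBase} (resistant strain) per site.
#' @slot lociIdx data.frame \code{chrom}, \code{site} (column index),
#'   \code{posBp}: the resistance loci snapped to their nearest SNP site.
#' @slot n integer, number of individuals.
#' @export
setClass("CrossPopulation",
  representation(hap = "list", sites = "list", alleles = "list",
                 lociIdx = "data.frame", n = "integer"))

setMethod("show", "CrossPopulation", function(object) {
  cat(sprintf("CrossPopulation: %d individuals, %d chromosome(s), %d SNP site(s)\n",
              object@n, length(object@hap),
              sum(vapply(object@hap, ncol, 0L))))
})

#' @describeIn CrossPopulation-class number of individuals.
#' @param x,object a \code{CrossPopulation}.
#' @export
setMethod("length", "CrossPopulation", function(x) as.integer(x@n))

#' Construct the two parental genomes
#'
#' Parent 1 is the fully homozygous resistant strain (carrying the resistant
#' allele at every fixed SNP site, including the resistance loci), parent 2
#' the fully homozygous susceptible strain.  SNP sites are evenly spaced
#' along each chromosome; reference (susceptible) and alternative bases are
#' drawn at random per site.  Resistance loci are snapped to the nearest SNP
#' site.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{CrossPopulation} of the two parents (individual 1
#'   resistant, individual 2 susceptible).
#' @export
makeParents <- function(config) {
  stopifnot(is(config, "SimConfig"))
  ch <- config@chromosomes
  hap <- sites <- alleles <- stats::setNames(vector("list", nrow(ch)), ch$name)
  for (i in seq_len(nrow(ch))) {
    ns <- ch$nSites[i]
    if (ns < 1L) stop("chromosome ", ch$name[i], " has no SNP sites")
    posBp <- unique(pmax(1L, as.integer(round((seq_len(ns) - 0.5) * ch$lengthBp[i] / ns))))
    if (length(posBp) < ns)
      stop("chromosome ", ch$name[i], " too short for ", ns, " distinct sites")
    ref <- sample(BASES, ns, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "")
    hap[[i]] <- rbind(rep(1L, ns), rep(1L, ns), rep(0L, ns), rep(0L, ns))
    sites[[i]] <- data.frame(posBp = posBp,
                             posCM = posBp / ch$lengthBp[i] * ch$lengthCM[i])
    alleles[[i]] <- data.frame(refBase = ref, altBase = unname(alt))
  }
  rl <- config@resistanceLoci
  lociIdx <- data.frame(chrom = character(), site = integer(), posBp = integer())
  if (nrow(rl)) {
    idx <- integer(nrow(rl)); snapped <- integer(nrow(rl))
    for (j in seq_len(nrow(rl))) {
      sp <- sites[[rl$chrom[j]]]$posBp
      idx[j] <- which.min(abs(sp - rl$posBp[j]))
      snapped[j] <- sp[idx[j]]
    }
    lociIdx <- data.frame(chrom = rl$chrom, site = idx, posBp = snapped)
  }
  new("CrossPopulation", hap = hap, sites = sites, alleles = alleles,
      lociIdx = lociIdx, n = 2L)
}

#' One meiosis: recombine two haplotypes into a gamete
#'
#' Crossovers are Poisson with mean equal to the chromosome's genetic length
#' in Morgans, placed uniformly on the genetic map, with no interference
#' (Haldane model); the starting haplotype is chosen with probability 1/2.
#'
#' @param hapA,hapB integer vectors, the parent's two haplotypes.
#' @param posCM numeric vector of the sites' genetic positions (cM).
#' @param lengthCM the chromosome's genetic length (cM).
#' @return An integer vector, the gamete.
#' @examples
#' meiosis(rep(1L, 5), rep(0L, 5), c(10, 20, 30, 40, 50), 60)
#' @export
meiosis <- function(hapA, hapB, posCM, lengthCM) {
  nco <- stats::rpois(1L, lengthCM / 100)
  first <- stats::runif(1L) < 0.5
  if (nco == 0L) return(if (first) hapA else hapB)
  seg <- findInterval(posCM, sort(stats::runif(nco, 0, lengthCM)))
  useA <- (seg %% 2L == 0L) == first
  out <- hapB
  out[useA] <- hapA[useA]
  out
}

## gametes from many (possibly repeated) parents on one chromosome
gameteMatrix <- function(H, parentIdx, posCM, lengthCM) {
  out <- matrix(0L, length(parentIdx), ncol(H))
  for (i in seq_along(parentIdx)) {
    p <- parentIdx[i]
    out[i, ] <- meiosis(H[2L * p - 1L, ], H[2L * p, ], posCM, lengthCM)
  }
  out
}

nextGeneration <- function(pop, mothers, fathers, config) {
  ch <- config@chromosomes
  nOff <- length(mothers)
  hap <- pop@hap
  for (c_ in names(hap)) {
    lenCM <- ch$lengthCM[match(c_, ch$name)]
    posCM <- pop@sites[[c_]]$posCM
    gm <- gameteMatrix(hap[[c_]], mothers, posCM, lenCM)
    gf <- gameteMatrix(hap[[c_]], fathers, posCM, lenCM)
    H <- matrix(0L, 2L * nOff, ncol(hap[[c_]]))
    H[seq(1L, 2L * nOff, by = 2L), ] <- gm
    H[seq(2L, 2L * nOff, by = 2L), ] <- gf
    hap[[c_]] <- H
  }
  initialize(pop, hap = hap, n = nOff)
}

#' Advance the cross to the target generational cohort
#'
#' F1 is produced by crossing the two parents (all F1 are identical
#' heterozygotes, since the parents are fixed for alternative alleles); the
#' F2 cohort comes from a single F1 sibling pair; later cohorts are produced
#' by free mating (monoecious, parents drawn with replacement) at the
#' configured census, in discrete non-overlapping generations.
#'
#' @param parents the \linkS4class{CrossPopulation} from [makeParents()].
#' @param config a \linkS4class{SimConfig}; \code{config@generations} is the
#'   target cohort (4 = F4).
#' @return The \linkS4class{CrossPopulation} at the target cohort.
#' @export
advanceGenerations <- function(parents, config) {
  stopifnot(is(parents, "CrossPopulation"), is(config, "SimConfig"))
  if (config@cohortSize < 2L) stop("cohort census must be >= 2")
  f1 <- nextGeneration(parents, c(1L, 1L), c(2L, 2L), config)  # one F1 pair
  pop <- nextGeneration(f1, rep(1L, config@nF2), rep(2L, config@nF2), config)
  g <- 2L
  while (g < config@generations) {
    mothers <- sample.int(pop@n, config@cohortSize, replace = TRUE)
    fathers <- sample.int(pop@n, config@cohortSize, replace = TRUE)
    pop <- nextGeneration(pop, mothers, fathers, config)
    g <- g + 1L
  }
  pop
}

#' Resistance-locus genotypes of a population
#'
#' @param pop a \linkS4class{CrossPopulation}.
#' @return Integer matrix, individuals x loci, counting resistant alleles
#'   (0, 1 or 2) at each configured resistance locus.
#' @export
resistGenotypes <- function(pop) {
  stopifnot(is(pop, "CrossPopulation"))
  li <- pop@lociIdx
  out <- matrix(0L, pop@n, nrow(li))
  for (j in seq_len(nrow(li))) {
    h <- pop@hap[[li$chrom[j]]][, li$site[j]]
    out[, j] <- h[seq(1L, length(h), by = 2L)] + h[seq(2L, length(h), by = 2L)]
  }
  out
}

#' All-or-nothing discriminating-dose survival rule
#'
#' At any positive dose only individuals homozygous resistant at every
#' resistance locus survive; at dose zero everyone survives.  This is the
#' idealised high discriminating dose used to isolate resistance
#' homozygotes.
#'
#' @return A function \code{(rCounts, dose) -> survival probability vector},
#'   where \code{rCounts} is the matrix from [resistGenotypes()].
#' @export
hardSelectionRule <- function() {
  function(rCounts, dose) {
    if (dose <= 0) return(rep(1, nrow(rCounts)))
    as.numeric(apply(rCounts == 2L, 1L, all))
  }
}

#' Select phosphine-exposure survivors
#'
#' Each individual survives independently with the probability given by the
#' selection rule for its genotype at the resistance loci.
#'
#' @param pop a \linkS4class{CrossPopulation}.
#' @param dose exposure dose in mg/L (0 = unexposed).
#' @param rule a rule function as returned by [hardSelectionRule()].
#' @return The surviving \linkS4class{CrossPopulation}.
#' @export
selectSurvivors <- function(pop, dose, rule = hardSelectionRule()) {
  stopifnot(is(pop, "CrossPopulation"))
  p <- rule(resistGenotypes(pop), dose)
  stopifnot(length(p) == pop@n, all(p >= 0 & p <= 1))
  keep <- which(stats::runif(pop@n) < p)
  if (!length(keep))
    stop("no survivors at dose ", dose,
         "; increase the cohort size or lower the dose")
  subsetPopulation(pop, keep)
}

subsetPopulation <- function(pop, idx) {
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  hap <- lapply(pop@hap, function(H) H[rows, , drop = FALSE])
  initialize(pop, hap = hap, n = length(idx))
}

#' Draw a sequencing pool from a population
#'
#' Samples \code{size} distinct individuals; if the population is smaller
#' than \code{size} the whole population is pooled.
#'
#' @param pop a \linkS4class{CrossPopulation}.
#' @param size target pool size.
#' @return A \linkS4class{CrossPopulation}.
#' @export
samplePool <- function(pop, size) {
  stopifnot(is(pop, "CrossPopulation"))
  if (pop@n <= size) return(pop)
  subsetPopulation(pop, sort(sample.int(pop@n, size)))
}

#' Sequence a pool at low coverage
#'
#' Per site, coverage is Poisson(\code{meanCoverage}); each read samples one
#' of the pool's 2N chromosomes with replacement (individuals equimolar) and
#' is miscalled to one of the three other bases with probability
#' \code{seqError}.  Sites with zero coverage are absent from the output.
#' With \code{applyFilters = TRUE} (the default) the records then pass
#' through [applyCallFilters()] with the susceptible-strain allele as the
#' reference base.
#'
#' @param pool a \linkS4class{CrossPopulation}.
#' @param config a \linkS4class{SimConfig} (supplies \code{meanCoverage} and
#'   \code{seqError}).
#' @param applyFilters apply the coverage / variant-frequency call filters?
#' @param filterConfig \linkS4class{ScanConfig} supplying the filters.
#' @param pool.label label stored in the result.
#' @return A \linkS4class{SnpTable}.
#' @export
sequencePool <- function(pool, config, applyFilters = TRUE,
                         filterConfig = scanConfig(), pool.label = "pool") {
  stopifnot(is(pool, "CrossPopulation"), is(config, "SimConfig"))
  if (pool@n < 1L) stop("empty pool")
  pieces <- vector("list", length(pool@hap))
  for (ci in seq_along(pool@hap)) {
    c_ <- names(pool@hap)[ci]
    H <- pool@hap[[c_]]
    f <- colMeans(H)
    ns <- ncol(H)
    cov <- stats::rpois(ns, config@meanCoverage)
    nR <- stats::rbinom(ns, cov, f)
    nS <- cov - nR
    eps <- config@seqError
    eR <- if (eps > 0) stats::rbinom(ns, nR, eps) else integer(ns)
    eS <- if (eps > 0) stats::rbinom(ns, nS, eps) else integer(ns)
    al <- pool@alleles[[c_]]
    counts <- matrix(0L, ns, 4, dimnames = list(NULL, BASES))
    counts[cbind(seq_len(ns), match(al$refBase, BASES))] <- nS - eS
    counts[cbind(seq_len(ns), match(al$altBase, BASES))] <-
      counts[cbind(seq_len(ns), match(al$altBase, BASES))] + (nR - eR)
    for (i in which(eR + eS > 0L)) {     # rare: distribute miscalled reads
      err <- c(sample(setdiff(BASES, al$altBase[i]), eR[i], replace = TRUE),
               sample(setdiff(BASES, al$refBase[i]), eS[i], replace = TRUE))
      tb <- table(err)
      counts[i, names(tb)] <- counts[i, names(tb)] + as.integer(tb)
    }
    keep <- cov > 0L
    pieces[[ci]] <- list(seqId = rep(c_, sum(keep)),
                         pos = pool@sites[[c_]]$posBp[keep],
                         ref = al$refBase[keep],
                         counts = counts[keep, , drop = FALSE])
  }
  tab <- SnpTable(
    unlist(lapply(pieces, `[[`, "seqId")),
    unlist(lapply(pieces, `[[`, "pos")),
    unlist(lapply(pieces, `[[`, "ref")),
    do.call(rbind, lapply(pieces, `[[`, "counts")),
    pool = pool.label)
  if (applyFilters) applyCallFilters(tab, filterConfig) else tab
}

#' Simulate a full bulk-segregant sequencing experiment
#'
#' Runs the whole pipeline: parental genomes, advance to the target cohort,
#' split into a selected pool (discriminating-dose survivors, sampled down
#' to the pool size) and an unselected pool (random sample), sequence both
#' pools, and emit a truth table of the simulated loci.  Fully reproducible
#' from \code{config@seed}: a master seed drives separate streams for
#' parents, pedigree, selection/pooling and sequencing.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param applySelection apply the discriminating dose to the selected pool?
#'   With \code{FALSE} both pools are independent random samples (a negative
#'   control).
#' @param rule selection rule, see [hardSelectionRule()].
#' @param filterConfig \linkS4class{ScanConfig} supplying the call filters.
#' @param outDir if non-NULL, write \code{selected.tsv}, \code{unselected.tsv}
#'   (counts dialect), \code{truth.tsv} and \code{config-echo.yaml} there.
#' @return A list with elements \code{selected} and \code{unselected}
#'   (\linkS4class{SnpTable}s, filtered), \code{truth} (data.frame of loci),
#'   \code{generations} (data.frame of cohort metadata), \code{nSurvivors},
#'   and the \code{config}.
#' @export
simulateExperiment <- function(config, applySelection = TRUE,
                               rule = hardSelectionRule(),
                               filterConfig = scanConfig(), outDir = NULL) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config@seed)
  ss <- sample.int(.Machine$integer.max - 1L, 4L)
  set.seed(ss[1]); parents <- makeParents(config)
  set.seed(ss[2]); pop <- advanceGenerations(parents, config)
  set.seed(ss[3])
  nSurv <- NA_integer_
  if (applySelection) {
    surv <- selectSurvivors(pop, config@selectionDose, rule)
    nSurv <- surv@n
    selPool <- samplePool(surv, config@poolSize)
  } else {
    selPool <- samplePool(pop, config@poolSize)
  }
  unselPool <- samplePool(pop, config@poolSize)
  set.seed(ss[4])
  selTab <- sequencePool(selPool, config, filterConfig = filterConfig,
                         pool.label = "selected")
  unselTab <- sequencePool(unselPool, config, filterConfig = filterConfig,
                           pool.label = "unselected")
  truth <- parents@lociIdx
  truth$expSelFreq <- if (applySelection) 1.0 else 0.5
  gens <- data.frame(
    generation = c(1L, 2L, seq_len(max(0L, config@generations - 2L)) + 2L),
    census = c(2L, config@nF2,
               rep(config@cohortSize, max(0L, config@generations - 2L))))
  gens$selected <- gens$generation == config@generations & applySelection
  res <- list(selected = selTab, unselected = unselTab, truth = truth,
              generations = gens, nSurvivors = nSurv, config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSnpTable(selTab, file.path(outDir, "selected.tsv"))
    writeSnpTable(unselTab, file.path(outDir, "unselected.tsv"))
    utils::write.table(truth, file.path(outDir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(simConfigAsList(config), file.path(outDir, "config-echo.yaml"))
  }
  res
}

simConfigAsList <- function(config) {
  list(
    chromosomes = as.list(config@chromosomes),
    resistance_loci = as.list(config@resistanceLoci),
    n_f2 = config@nF2, cohort_size = config@cohortSize,
    generations = config@generations, selection_dose = config@selectionDose,
    pool_size = config@poolSize, mean_coverage = config@meanCoverage,
    seq_error = config@seqError, seed = config@seed)
}
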