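# Whole-clone simulation: draw a set of rearrangement events under a
# genotype profile, apply them to one haplotype, and report the observables
# (junctions + binned copy number) together with the ground-truth event
# list.

#' Built-in genotype simulation profiles
#'
#' `"wild_type"` clones acquire 8-12 simple intrachromosomal events
#' (deletions, tandem duplications, inversions) with sizes below 10 kb.
#' `"rtel1_null"` clones acquire 15-35 events with a wider class spectrum:
#' more and larger deletions (up to hundreds of kb), templated duplications
#' with distant intra-chromosomal insertion, breakage-fusion-bridge tails
#' and occasional chromothripsis.  Event sizes are drawn log-uniformly
#' within their ranges; positions are uniform with rejection of overlap
#' against previously placed events.
#'
#' @param name `"wild_type"` or `"rtel1_null"`.
#' @return A profile list understood by [simulateClone()]; fields can be
#'   overridden before use (see [readProfile()] for file-based profiles).
#' @export
cloneProfile <- function(name = c("wild_type", "rtel1_null")) {
  name <- match.arg(name)
  base <- list(
    name = name,
    genome = list(length = 1e8, baselineCN = 2L, chrom = "chr1"),
    cnBinSize = 1000L,
    maxRetries = 1000L)
  if (name == "wild_type") {
    c(base, list(
      nEvents = c(8L, 12L),
      classProbs = c(deletion = 0.50, tandem_duplication = 0.35,
                     inversion = 0.15),
      sizes = list(deletion = c(5e2, 1e4),
                   tandem_duplication = c(5e2, 1e4),
                   inversion = c(1e3, 1e4))))
  } else {
    c(base, list(
      nEvents = c(15L, 35L),
      classProbs = c(deletion = 0.40, tandem_duplication = 0.18,
                     inversion = 0.07, templated_insertion = 0.20,
                     bfb = 0.10, chromothripsis = 0.05),
      sizes = list(deletion = c(1e3, 5e5),
                   tandem_duplication = c(1e3, 1e5),
                   inversion = c(1e3, 1e5)),
      templatedInsertion = list(bounds = templatedInsertionBounds(),
                                invertedProb = 0.8),
      bfb = list(cycles = c(1L, 3L), windowFrac = 0.1),
      chromothripsis = list(regionLen = c(1e6, 2e6),
                            nFragments = c(12L, 20L),
                            retainProb = 0.7)))
  }
}

.logUnif <- function(n, range) exp(runif(n, log(range[1L]), log(range[2L])))

# uniform integer on [a, b], safe for a == b
.unifInt <- function(a, b) a + sample.int(b - a + 1L, 1L) - 1L

.overlapsAny <- function(iv, footprints) {
  for (f in footprints)
    if (iv[1L] < f[2L] && f[1L] < iv[2L]) return(TRUE)
  FALSE
}

#' Sample templated-insertion parameter sets under the default bounds
#'
#' Draws template length log-uniformly within the template-length bounds,
#' the insertion distance (template midpoint to insertion point)
#' log-uniformly within the distance bounds on a random side, the
#' insertion-site deletion length uniformly on its integer range, and the
#' inverted flag with probability `invertedProb`.
#'
#' @param n Number of parameter sets.
#' @param genomeLength Reference length in bp.
#' @param bounds Sampling bounds, see [templatedInsertionBounds()].
#' @param invertedProb Probability of inverted orientation.
#' @param placeLimit Upper bp limit for template and site placement
#'   (defaults to the full genome).
#' @param footprints Optional list of `c(start, end)` intervals the drawn
#'   template and site must avoid; accepted draws are appended.
#' @param maxRetries Rejection-sampling retry cap per draw.
#' @return List of [TemplatedInsertionParams()] objects.
#' @export
sampleTemplatedInsertionParams <- function(n, genomeLength,
    bounds = templatedInsertionBounds(), invertedProb = 0.8,
    placeLimit = genomeLength, footprints = list(),
    maxRetries = 1000L) {
  out <- vector("list", n)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(maxRetries)) {
      tlen <- round(.logUnif(1L, bounds$templateLen))
      d <- round(.logUnif(1L, bounds$distance))
      sdel <- bounds$siteDeletionLen[1L] +
        sample.int(bounds$siteDeletionLen[2L] - bounds$siteDeletionLen[1L] +
                     1L, 1L) - 1L
      t0 <- floor(runif(1L, 0, placeLimit - tlen))
      mid <- t0 + tlen / 2
      ip <- round(mid + sample(c(-1, 1), 1L) * d)
      if (ip < 0 || ip + sdel > placeLimit) next
      tEnd <- t0 + tlen
      if (ip < tEnd && ip + sdel > t0) next
      iv1 <- c(t0, tEnd); iv2 <- c(ip, ip + sdel)
      if (.overlapsAny(iv1, footprints) || .overlapsAny(iv2, footprints))
        next
      p <- tryCatch(
        TemplatedInsertionParams(t0, tlen, ip, sdel,
                                 inverted = runif(1L) < invertedProb,
                                 bounds = bounds),
        error = function(e) NULL)
      if (is.null(p)) next
      out[[k]] <- p
      footprints <- c(footprints, list(iv1, iv2))
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place a templated insertion after ", maxRetries,
           " retries")
  }
  out
}

.placeInterval <- function(size, placeLimit, footprints, maxRetries) {
  for (try in seq_len(maxRetries)) {
    start <- floor(runif(1L, 0, placeLimit - size))
    iv <- c(start, start + size)
    if (!.overlapsAny(iv, footprints)) return(iv)
  }
  stop("could not place a ", format(size),
       " bp event after ", maxRetries, " retries")
}

#' Simulate one subclone's rearrangement landscape
#'
#' Draws an event count and event classes from the genotype profile,
#' places the events with overlap rejection-resampling, applies them
#' sequentially to one haplotype of a fresh genome, and derives the
#' observables a sequencing pipeline would report.  At most one
#' breakage-fusion-bridge and one chromothripsis event are drawn per clone;
#' a breakage-fusion-bridge event is applied last and acts on the distal
#' end of the chromosome, which is reserved for it during placement.
#'
#' @param profile A profile name (`"wild_type"`, `"rtel1_null"`) or a
#'   profile list from [cloneProfile()] / [readProfile()].
#' @param seed Integer seed; identical seed and profile give identical
#'   observables.
#' @return List with elements `junctions` ([JunctionSet-class]), `cn`
#'   ([CNProfile-class]), `events` (ground-truth list of event records,
#'   each with `eventClass` and `params`), `derivative`
#'   ([DerivativeChromosome-class]) and `genotype`.
#' @examples
#' cl <- simulateClone("wild_type", seed = 1)
#' length(cl$junctions)
#' @export
simulateClone <- function(profile = "wild_type", seed = 1L) {
  if (is.character(profile)) profile <- cloneProfile(profile)
  set.seed(seed)
  g <- profile$genome
  L <- g$length
  dc <- newGenome(L, baselineCN = g$baselineCN, chrom = g$chrom)
  n <- .unifInt(profile$nEvents[1L], profile$nEvents[2L])
  classes <- sample(names(profile$classProbs), n, replace = TRUE,
                    prob = profile$classProbs)
  # at most one BFB tail and one chromothripsis region per clone
  for (cls in c("bfb", "chromothripsis")) {
    extra <- which(classes == cls)[-1L]
    if (length(extra)) {
      simple <- setdiff(names(profile$classProbs),
                        c("bfb", "chromothripsis"))
      classes[extra] <- sample(simple, length(extra), replace = TRUE,
                               prob = profile$classProbs[simple])
    }
  }
  hasBfb <- "bfb" %in% classes
  placeLimit <- if (hasBfb) 0.8 * L else L
  footprints <- list()
  events <- list()
  mr <- profile$maxRetries
  for (cls in classes[classes != "bfb"]) {
    if (cls %in% c("deletion", "tandem_duplication", "inversion")) {
      size <- round(.logUnif(1L, profile$sizes[[cls]]))
      iv <- .placeInterval(size, placeLimit, footprints, mr)
      footprints <- c(footprints, list(iv))
      dc <- switch(cls,
        deletion = applyDeletion(dc, iv),
        tandem_duplication = applyTandemDuplication(dc, iv),
        inversion = applyInversion(dc, iv))
      events <- c(events, list(list(eventClass = cls,
                                    params = list(interval = iv))))
    } else if (cls == "templated_insertion") {
      ti <- profile$templatedInsertion
      p <- sampleTemplatedInsertionParams(1L, L, bounds = ti$bounds,
             invertedProb = ti$invertedProb, placeLimit = placeLimit,
             footprints = footprints, maxRetries = mr)[[1L]]
      footprints <- c(footprints,
        list(c(p$templateStart, p$templateStart + p$templateLen),
             c(p$insertionPos, p$insertionPos + p$siteDeletionLen)))
      dc <- applyTemplatedInsertion(dc, p)
      events <- c(events, list(list(eventClass = "templated_insertion",
                                    params = p)))
    } else if (cls == "chromothripsis") {
      ct <- profile$chromothripsis
      size <- round(runif(1L, ct$regionLen[1L], ct$regionLen[2L]))
      iv <- .placeInterval(size, placeLimit, footprints, mr)
      footprints <- c(footprints, list(iv))
      nf <- .unifInt(ct$nFragments[1L], ct$nFragments[2L])
      dc <- applyChromothripsis(dc, iv, nFragments = nf,
                                retainProb = ct$retainProb)
      events <- c(events, list(list(eventClass = "chromothripsis",
        params = list(region = iv, nFragments = nf,
                      retainProb = ct$retainProb))))
    }
  }
  if (hasBfb) {
    bf <- profile$bfb
    cyc <- .unifInt(bf$cycles[1L], bf$cycles[2L])
    dc <- applyBfbCycles(dc, cyc, windowFrac = bf$windowFrac)
    events <- c(events, list(list(eventClass = "bfb",
      params = list(nCycles = cyc, windowFrac = bf$windowFrac))))
  }
  list(junctions = deriveJunctions(dc),
       cn = deriveCopyNumber(dc, binSize = profile$cnBinSize),
       events = events,
       derivative = dc,
       genotype = profile$name)
}
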