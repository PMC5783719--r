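# Inference of SV classes from junction + copy-number observables.

#' Default classifier thresholds
#'
#' @return Named list: `foldBackGap` (bp separating the breakends of a
#'   fold-back inversion, default 10 kb), `minBreakpoints` and
#'   `maxGap` for chromothripsis breakend clustering, `maxCnStates` and
#'   `alpha` for the chromothripsis copy-number and orientation tests,
#'   `minCnSegLen` (CN segments shorter than this are treated as binning
#'   artefacts when counting states),
#'   `tiBounds` for templated-insertion geometry, and
#'   `inversionPairTol` (bp tolerance when matching reciprocal
#'   inversion junction pairs).
#' @export
classifierConfig <- function() {
  list(foldBackGap = 1e4, minBreakpoints = 8L, maxGap = 1e6,
       maxCnStates = 2L, alpha = 0.05, minCnSegLen = 5e3,
       tiBounds = templatedInsertionBounds(),
       inversionPairTol = 50)
}

#' Classify single junctions by breakend geometry
#'
#' For an intra-chromosomal junction with canonically ordered breakends
#' (`posA <= posB`): sides `(R, L)` give `deletion_type`, `(L, R)`
#' `duplication_type`, `(R, R)` head-to-head inversion (`inversion_HH`),
#' `(L, L)` tail-to-tail inversion (`inversion_TT`).  An inverted junction
#' whose breakends lie within `foldBackGap` of each other is the signature
#' of a sister-chromatid end fusion and is labelled `fold_back`.
#' Inter-chromosomal junctions get the label `interchromosomal` and are
#' excluded from the five intra-chromosomal types.
#'
#' @param junctions A [JunctionSet-class] (or its `data.frame`).
#' @param foldBackGap Maximum breakend separation of a fold-back, in bp.
#' @return Character vector of labels, one per junction.
#' @examples
#' js <- deriveJunctions(applyDeletion(newGenome(1e3), c(100, 200)))
#' classifyJunctions(js)
#' @export
classifyJunctions <- function(junctions, foldBackGap = 1e4) {
  j <- if (is(junctions, "JunctionSet")) junctions@junctions else junctions
  if (nrow(j) == 0L) return(character(0))
  lab <- character(nrow(j))
  inter <- j$chromA != j$chromB
  lab[inter] <- "interchromosomal"
  intra <- !inter
  ss <- paste0(j$sideA, j$sideB)
  lab[intra & ss == "RL"] <- "deletion_type"
  lab[intra & ss == "LR"] <- "duplication_type"
  lab[intra & ss == "RR"] <- "inversion_HH"
  lab[intra & ss == "LL"] <- "inversion_TT"
  fb <- intra & ss %in% c("RR", "LL") & (j$posB - j$posA) <= foldBackGap
  lab[fb] <- "fold_back"
  lab
}

# mean (length-weighted) CN over [start, end)
.cnMean <- function(cn, start, end) {
  seg <- cn@segments
  s <- pmax(seg$start, start); e <- pmin(seg$end, end)
  w <- pmax(e - s, 0)
  if (sum(w) == 0) return(NA_real_)
  sum(seg$cn * w) / sum(w)
}

# length-weighted modal CN of the whole profile
.cnMode <- function(cn) {
  seg <- cn@segments
  w <- tapply(seg$end - seg$start, seg$cn, sum)
  as.numeric(names(w)[which.max(w)])
}

#' Detect templated duplications with distant intra-chromosomal insertion
#'
#' Searches junction pairs `(j1, j2)` such that one breakend of each flanks
#' a common template interval whose copy number exceeds its neighbourhood
#' by at least one, the remaining two breakends flank a small
#' insertion-site deletion (within the configured 6 bp to 1 kb range), the
#' template-to-site distance lies within the configured window, and the
#' breakend sides are consistent with either an inverted or a direct
#' insertion.  When candidate pairings overlap, the pairing with the
#' smallest insertion-site deletion is kept (ties: leftmost template).
#'
#' @param junctions A [JunctionSet-class].
#' @param cn A [CNProfile-class].
#' @param config Thresholds, see [classifierConfig()].
#' @param use Optional logical vector marking junctions still available
#'   for assignment.
#' @return List of events; each has `eventClass = "templated_insertion"`,
#'   `junctions` (indices into the junction set), `template`
#'   (`c(start, end)`), `insertionPos`, `siteDeletionLen` and `inverted`.
#' @export
detectTemplatedInsertions <- function(junctions, cn,
                                      config = classifierConfig(),
                                      use = NULL) {
  j <- junctions@junctions
  n <- nrow(j)
  if (is.null(use)) use <- rep(TRUE, n)
  cand <- list()
  if (n >= 2L) {
    idx <- which(use & j$chromA == j$chromB)
    maxSite <- config$tiBounds$siteDeletionLen[2L] + 1
    for (a in idx) for (b in idx[idx > a]) {
      # prefilter: some breakend of a must lie within the site-deletion
      # range of some breakend of b
      pa <- c(j$posA[a], j$posB[a]); pb <- c(j$posA[b], j$posB[b])
      if (min(abs(outer(pa, pb, "-"))) > maxSite) next
      hit <- .tiPairGeometry(
        pa, c(j$sideA[a], j$sideB[a]),
        pb, c(j$sideA[b], j$sideB[b]), config$tiBounds)
      if (is.null(hit)) next
      # template must be amplified relative to its flanks
      tlen <- hit$template[2L] - hit$template[1L]
      cnT <- .cnMean(cn, hit$template[1L], hit$template[2L])
      flank <- max(tlen, 1e4)
      cnL <- .cnMean(cn, max(0, hit$template[1L] - flank), hit$template[1L])
      cnR <- .cnMean(cn, hit$template[2L],
                     min(cn@length, hit$template[2L] + flank))
      cnN <- mean(c(cnL, cnR), na.rm = TRUE)
      if (is.na(cnT) || is.na(cnN) || cnT < cnN + 0.5) next
      cand[[length(cand) + 1L]] <-
        c(hit, list(junctions = c(a, b)))
    }
  }
  if (!length(cand)) return(list())
  # greedy conflict resolution: minimal site deletion, then leftmost template
  ord <- order(vapply(cand, function(x) x$siteDeletionLen, numeric(1)),
               vapply(cand, function(x) x$template[1L], numeric(1)))
  taken <- rep(FALSE, n)
  out <- list()
  for (k in ord) {
    ji <- cand[[k]]$junctions
    if (any(taken[ji])) next
    taken[ji] <- TRUE
    ev <- cand[[k]]
    ev$eventClass <- "templated_insertion"
    out[[length(out) + 1L]] <- ev
  }
  out
}

# geometry test for one junction pair; returns NULL or the interpreted
# event.  pos1/side1 and pos2/side2 hold the two breakends of each
# junction.
.tiPairGeometry <- function(pos1, side1, pos2, side2, bounds) {
  pos <- c(pos1, pos2); side <- c(side1, side2)
  junction <- c(1L, 1L, 2L, 2L)
  # choose one breakend per junction as the site-side flank; the other two
  # must delimit the template (one L at its start, one R at its end)
  for (s1 in 1:2) for (s2 in 3:4) {
    si <- c(s1, s2); ti <- setdiff(1:4, si)
    if (!(sum(side[ti] == "L") == 1L && sum(side[ti] == "R") == 1L)) next
    if (!(sum(side[si] == "L") == 1L && sum(side[si] == "R") == 1L)) next
    iR <- si[side[si] == "R"]; iL <- si[side[si] == "L"]
    if (pos[iR] >= pos[iL]) next
    d <- pos[iL] - pos[iR] - 1
    if (d < bounds$siteDeletionLen[1L] || d > bounds$siteDeletionLen[2L])
      next
    t0 <- pos[ti[side[ti] == "L"]]
    t1 <- pos[ti[side[ti] == "R"]] + 1
    if (t1 <= t0) next
    tlen <- t1 - t0
    if (tlen < bounds$templateLen[1L] || tlen > bounds$templateLen[2L]) next
    ip <- pos[iR] + 1
    dist <- abs(ip - (t0 + tlen / 2))
    if (dist < bounds$distance[1L] || dist > bounds$distance[2L]) next
    if (ip < t1 && pos[iL] > t0) next   # template and site overlap
    # orientation: inverted pairs site-R with template-R on one junction
    inverted <- junction[ti[side[ti] == "R"]] == junction[iR]
    return(list(template = c(t0, t1), insertionPos = ip,
                siteDeletionLen = d, inverted = inverted))
  }
  NULL
}

#' Detect a breakage-fusion-bridge event
#'
#' Reports an event when at least one fold-back junction co-occurs with
#' copy-number amplification immediately proximal to the outermost
#' fold-back position and copy-number loss distal to it extending to the
#' chromosome end.  The estimated cycle count is the number of fold-back
#' junctions.
#'
#' @inheritParams detectTemplatedInsertions
#' @return List with zero or one event; the event has
#'   `eventClass = "bfb"`, `junctions`, `cycleEstimate` and `foldBackPos`.
#' @export
detectBfb <- function(junctions, cn, config = classifierConfig(),
                      use = NULL) {
  j <- junctions@junctions
  if (is.null(use)) use <- rep(TRUE, nrow(j))
  lab <- classifyJunctions(junctions, config$foldBackGap)
  fb <- which(use & lab == "fold_back")
  if (!length(fb)) return(list())
  outer <- max(j$posB[fb])
  modal <- .cnMode(cn)
  distal <- .cnMean(cn, outer + 1, cn@length)
  proximalWin <- max(1e4, 0.05 * (outer + 1))
  proximal <- .cnMean(cn, max(0, outer - proximalWin), outer)
  if (is.na(distal) || is.na(proximal)) return(list())
  if (!(distal < modal && proximal > distal)) return(list())
  list(list(eventClass = "bfb", junctions = fb,
            cycleEstimate = length(fb),
            foldBackPos = sort(j$posA[fb])))
}

#' Detect chromothripsis regions
#'
#' Clusters intra-chromosomal junction breakends by gap (`maxGap`),
#' retains the largest span-interleaved junction component of each cluster
#' (shattering interleaves junction spans; independent events that merely
#' lie nearby do not), and calls a shattered region when the component
#' holds at least `minBreakpoints` breakends, the copy number inside occupies
#' at most `maxCnStates` integer states, and the four junction-type
#' categories of the clustered junctions are compatible with uniformity
#' (chi-squared goodness of fit, p > `alpha`).  Raising `minBreakpoints`
#' can only reduce the number of calls.
#'
#' @inheritParams detectTemplatedInsertions
#' @param minBreakpoints Minimum clustered breakends (default 8).
#' @return List of events with `eventClass = "chromothripsis"`,
#'   `junctions`, `region`, `nBreakends`, `cnStates` and `orientationP`.
#' @export
detectChromothripsis <- function(junctions, cn,
                                 config = classifierConfig(),
                                 minBreakpoints = config$minBreakpoints,
                                 use = NULL) {
  j <- junctions@junctions
  if (is.null(use)) use <- rep(TRUE, nrow(j))
  idx <- which(use & j$chromA == j$chromB)
  if (!length(idx)) return(list())
  be <- data.frame(pos = c(j$posA[idx], j$posB[idx]),
                   junction = c(idx, idx))
  be <- be[order(be$pos), ]
  cl <- cumsum(c(1, diff(be$pos) > config$maxGap))
  out <- list()
  for (g in unique(cl)) {
    members <- be[cl == g, ]
    if (nrow(members) < minBreakpoints) next
    # junctions with both breakends in this cluster
    tab <- table(members$junction)
    cand <- as.integer(names(tab)[tab == 2L])
    if (length(cand) < minBreakpoints / 2) next
    # shattering interleaves junction spans; an independent simple event
    # that merely lies nearby does not overlap them.  Keep the largest
    # connected component of the span-overlap graph.
    cand <- cand[order(j$posA[cand])]
    comp <- cumsum(c(1, j$posA[cand][-1L] >
                       cummax(j$posB[cand])[-length(cand)]))
    compSize <- table(comp)
    big <- as.integer(names(compSize)[which.max(compSize)])
    inside <- cand[comp == big]
    if (2L * length(inside) < minBreakpoints) next
    region <- c(min(j$posA[inside]), max(j$posB[inside]) + 1)
    # CN inside the region must oscillate between few integer states;
    # segments shorter than minCnSegLen are binning artefacts at fragment
    # boundaries and are ignored
    seg <- cn@segments
    ov <- seg$end > region[1L] & seg$start < region[2L] &
      (pmin(seg$end, region[2L]) - pmax(seg$start, region[1L])) >=
        config$minCnSegLen
    states <- unique(seg$cn[ov])
    if (length(states) > config$maxCnStates) next
    # junction orientations approximately uniform over the four categories
    lab <- classifyJunctions(
      JunctionSet(j[inside, , drop = FALSE]), foldBackGap = 0)
    cats <- table(factor(lab, levels = c("deletion_type",
      "duplication_type", "inversion_HH", "inversion_TT")))
    p <- suppressWarnings(
      chisq.test(as.vector(cats), p = rep(0.25, 4))$p.value)
    if (is.na(p) || p <= config$alpha) next
    out[[length(out) + 1L]] <-
      list(eventClass = "chromothripsis", junctions = inside,
           region = region, nBreakends = 2L * length(inside),
           cnStates = sort(states), orientationP = p)
  }
  out
}

#' Classify one sample's observables into SV events
#'
#' Greedy hierarchical assignment, complex before simple.  Reciprocal
#' head-to-head / tail-to-tail junction pairs at matching positions are
#' first set aside as clean inversions (they would otherwise masquerade as
#' fold-backs); then chromothripsis regions are called and consume their
#' junctions, then breakage-fusion-bridge, then templated insertions;
#' every remaining junction is labelled by [classifyJunctions()].  Every
#' junction ends up in exactly one event or simple class.
#'
#' @param junctions A [JunctionSet-class].
#' @param cn A [CNProfile-class].
#' @param config Thresholds, see [classifierConfig()].
#' @return A [SampleReport-class].
#' @examples
#' cl <- simulateClone("wild_type", seed = 1)
#' classCounts(classifySample(cl$junctions, cl$cn))
#' @export
classifySample <- function(junctions, cn, config = classifierConfig()) {
  j <- junctions@junctions
  n <- nrow(j)
  assignment <- rep(NA_character_, n)
  events <- list()
  use <- rep(TRUE, n)

  addEvents <- function(evs) {
    for (ev in evs) {
      id <- sprintf("%s#%d", ev$eventClass, length(events) + 1L)
      assignment[ev$junctions] <<- id
      use[ev$junctions] <<- FALSE
      events[[length(events) + 1L]] <<- ev
    }
  }
  # reciprocal inversion pairing first: an HH and a TT junction at
  # matching positions are the two joins of one clean inverted interval
  # and must not be mistaken for fold-backs or shattering debris
  lab <- classifyJunctions(junctions, config$foldBackGap)
  rawLab <- classifyJunctions(junctions, foldBackGap = 0)
  hh <- which(use & rawLab == "inversion_HH")
  tt <- which(use & rawLab == "inversion_TT")
  tol <- config$inversionPairTol
  for (a in hh) {
    if (!use[a]) next
    match <- tt[use[tt] &
                  abs(j$posA[tt] - j$posA[a]) <= tol &
                  abs(j$posB[tt] - j$posB[a]) <= tol]
    if (length(match)) {
      b <- match[1L]
      assignment[c(a, b)] <- "inversion"
      use[c(a, b)] <- FALSE
    }
  }

  addEvents(detectChromothripsis(junctions, cn, config, use = use))
  # templated insertions before BFB: an inserted copy lying close to its
  # template produces an inverted junction with a small breakend gap that
  # would otherwise be mistaken for a fold-back, whereas two genuine
  # fold-backs essentially never satisfy the paired insertion geometry
  addEvents(detectTemplatedInsertions(junctions, cn, config, use = use))
  addEvents(detectBfb(junctions, cn, config, use = use))
  assignment[use] <- lab[use]
  new("SampleReport", junctions = junctions, cn = cn,
      assignment = assignment, events = events)
}

#' Per-class junction counts of a sample report
#'
#' Complex events are counted through their event class (all junctions of
#' one event share its label); simple junctions through their junction
#' type.  Counts sum to the number of junctions in the report.
#'
#' @param report A [SampleReport-class].
#' @return Named integer vector of junction counts per class.
#' @export
classCounts <- function(report) {
  stopifnot(is(report, "SampleReport"))
  cls <- sub("#.*$", "", report@assignment)
  tab <- table(cls)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

setMethod("show", "SampleReport", function(object) {
  cat(sprintf("SampleReport: %d junction(s), %d complex event(s)\n",
              length(object@junctions), length(object@events)))
  if (length(object@assignment)) {
    tab <- classCounts(object)
    for (k in seq_along(tab))
      cat(sprintf("  %-22s %d\n", names(tab)[k], tab[k]))
  }
})
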