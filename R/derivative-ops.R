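# Event operations on DerivativeChromosome objects.  All intervals are
# 0-based half-open reference coordinates and must fall inside a single
# currently-present, forward-oriented segment of the derivative.

.checkInterval <- function(interval, len) {
  if (length(interval) != 2L || any(!is.finite(interval)))
    stop("interval must be c(start, end)")
  start <- interval[1L]; end <- interval[2L]
  if (start < 0 || end > len || start >= end)
    stop(sprintf("interval [%s, %s) out of bounds for a %s bp genome",
                 format(start), format(end), format(len)))
  c(start, end)
}

# index of the forward segment wholly containing [start, end)
.findForwardSegment <- function(dc, start, end) {
  seg <- dc@segments
  hit <- which(seg$strand == "+" & seg$start <= start & seg$end >= end)
  if (length(hit) == 0L)
    stop(sprintf(paste0("interval [%s, %s) does not lie within a ",
                        "forward-retained region of the derivative"),
                 format(start), format(end)))
  hit[1L]
}

.spliceSegments <- function(dc, i, replacement) {
  seg <- dc@segments
  out <- rbind(if (i > 1L) seg[seq_len(i - 1L), ],
               replacement,
               if (i < nrow(seg)) seg[seq(i + 1L, nrow(seg)), ])
  rownames(out) <- NULL
  # keep zero-length rows out
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  new("DerivativeChromosome", genome = dc@genome, segments = out)
}

.seg <- function(start, end, strand) {
  data.frame(start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Delete a reference interval from the derivative
#'
#' Removes `[start, end)` from the haplotype.  The derivative shortens by
#' `end - start`, one deletion-type junction appears joining breakends
#' `(start - 1, R)` and `(end, L)`, and derived copy number over the
#' interval drops by 1.
#'
#' @param dc A [DerivativeChromosome-class].
#' @param interval `c(start, end)`, 0-based half-open, inside a
#'   forward-retained region.
#' @return The modified [DerivativeChromosome-class].
#' @examples
#' dc <- applyDeletion(newGenome(1e3), c(100, 200))
#' derivativeLength(dc)
#' @export
applyDeletion <- function(dc, interval) {
  iv <- .checkInterval(interval, dc@genome@length)
  i <- .findForwardSegment(dc, iv[1L], iv[2L])
  s <- dc@segments[i, ]
  .spliceSegments(dc, i, rbind(.seg(s$start, iv[1L], "+"),
                               .seg(iv[2L], s$end, "+")))
}

#' Tandem-duplicate a reference interval
#'
#' Duplicates `[start, end)` in place.  The derivative lengthens by
#' `end - start`, one duplication-type junction appears joining
#' `(end - 1, R)` to `(start, L)`, and copy number over the interval rises
#' by 1.
#'
#' @inheritParams applyDeletion
#' @return The modified [DerivativeChromosome-class].
#' @export
applyTandemDuplication <- function(dc, interval) {
  iv <- .checkInterval(interval, dc@genome@length)
  i <- .findForwardSegment(dc, iv[1L], iv[2L])
  s <- dc@segments[i, ]
  .spliceSegments(dc, i, rbind(.seg(s$start, iv[2L], "+"),
                               .seg(iv[1L], s$end, "+")))
}

#' Invert a reference interval
#'
#' Replaces `[start, end)` with its reverse complement in place.  Length
#' and copy number are unchanged; two inversion-type junctions appear (one
#' head-to-head `R/R`, one tail-to-tail `L/L`), unless a join falls at a
#' derivative end.
#'
#' @inheritParams applyDeletion
#' @return The modified [DerivativeChromosome-class].
#' @export
applyInversion <- function(dc, interval) {
  iv <- .checkInterval(interval, dc@genome@length)
  i <- .findForwardSegment(dc, iv[1L], iv[2L])
  s <- dc@segments[i, ]
  .spliceSegments(dc, i, rbind(.seg(s$start, iv[1L], "+"),
                               .seg(iv[1L], iv[2L], "-"),
                               .seg(iv[2L], s$end, "+")))
}

#' Parameters of a templated duplication with distant insertion
#'
#' Describes the novel rearrangement class in which a template region is
#' copied and inserted elsewhere on the same chromosome, usually in
#' inverted orientation, replacing a small stretch at the insertion site.
#' The default bounds encode the observed ranges: templates of 2 kb to
#' 100 kb, inserted 10 kb to 5 Mb away (template midpoint to insertion
#' point), with a 6 bp to 1 kb deletion at the insertion site.
#'
#' @param templateStart 0-based start of the copied template.
#' @param templateLen Template length in bp.
#' @param insertionPos 0-based position where the copy is inserted.
#' @param siteDeletionLen Length of sequence replaced at the insertion
#'   site, in bp.
#' @param inverted Logical; is the copy inserted in inverted orientation?
#' @param bounds Named list of sampling bounds used for validation:
#'   `templateLen`, `distance`, `siteDeletionLen`, each `c(min, max)`.
#' @return A validated parameter list of class `TemplatedInsertionParams`.
#' @seealso [applyTemplatedInsertion()], [detectTemplatedInsertions()]
#' @export
TemplatedInsertionParams <- function(templateStart, templateLen,
                                     insertionPos, siteDeletionLen,
                                     inverted = TRUE,
                                     bounds = templatedInsertionBounds()) {
  p <- list(templateStart = templateStart, templateLen = templateLen,
            insertionPos = insertionPos, siteDeletionLen = siteDeletionLen,
            inverted = isTRUE(inverted))
  if (templateLen < bounds$templateLen[1L] ||
      templateLen > bounds$templateLen[2L])
    stop(sprintf("templateLen must lie in [%g, %g] bp",
                 bounds$templateLen[1L], bounds$templateLen[2L]))
  if (siteDeletionLen < bounds$siteDeletionLen[1L] ||
      siteDeletionLen > bounds$siteDeletionLen[2L])
    stop(sprintf("siteDeletionLen must lie in [%g, %g] bp",
                 bounds$siteDeletionLen[1L], bounds$siteDeletionLen[2L]))
  mid <- templateStart + templateLen / 2
  d <- abs(insertionPos - mid)
  if (d < bounds$distance[1L] || d > bounds$distance[2L])
    stop(sprintf("insertion distance %g bp outside [%g, %g]",
                 d, bounds$distance[1L], bounds$distance[2L]))
  tEnd <- templateStart + templateLen
  sEnd <- insertionPos + siteDeletionLen
  if (insertionPos < tEnd && sEnd > templateStart)
    stop("template and insertion site must not overlap")
  class(p) <- "TemplatedInsertionParams"
  p
}

#' Default bounds for templated-insertion parameters
#'
#' @return List with elements `templateLen` (`c(2e3, 1e5)` bp), `distance`
#'   (`c(1e4, 5e6)` bp, template midpoint to insertion point) and
#'   `siteDeletionLen` (`c(6, 1000)` bp).
#' @export
templatedInsertionBounds <- function() {
  list(templateLen = c(2e3, 1e5), distance = c(1e4, 5e6),
       siteDeletionLen = c(6, 1000))
}

#' Apply a templated duplication with distant intra-chromosomal insertion
#'
#' A copy of the template `[templateStart, templateStart + templateLen)` is
#' inserted at `insertionPos`, replacing `siteDeletionLen` bp there, in
#' reverse orientation when `inverted`.  The net length change is
#' `templateLen - siteDeletionLen`; copy number gains 1 over the template
#' and loses 1 over the replaced site; exactly two new junctions link the
#' insertion-site flanks to the two template boundaries.
#'
#' @param dc A [DerivativeChromosome-class].
#' @param params A [TemplatedInsertionParams()] list.
#' @return The modified [DerivativeChromosome-class].
#' @export
applyTemplatedInsertion <- function(dc, params) {
  stopifnot(inherits(params, "TemplatedInsertionParams"))
  t0 <- params$templateStart
  t1 <- t0 + params$templateLen
  ip <- params$insertionPos
  sEnd <- ip + params$siteDeletionLen
  .checkInterval(c(t0, t1), dc@genome@length)
  .checkInterval(c(ip, sEnd), dc@genome@length)
  # template must be present forward (it is the copied source)
  .findForwardSegment(dc, t0, t1)
  i <- .findForwardSegment(dc, ip, sEnd)
  s <- dc@segments[i, ]
  .spliceSegments(dc, i, rbind(
    .seg(s$start, ip, "+"),
    .seg(t0, t1, if (params$inverted) "-" else "+"),
    .seg(sEnd, s$end, "+")))
}

#' Apply breakage-fusion-bridge cycles
#'
#' Models the classic cycle that follows telomere loss: per cycle, a break
#' position is drawn uniformly within a window (default the distal 10% of
#' the current derivative) from the unstable right end, sequence distal to
#' the break is discarded, and the retained molecule is fused to its own
#' reverse complement (sister-chromatid fusion).  Each completed cycle
#' contributes one fold-back junction (`R/R` or `L/L` with near-identical
#' breakend positions) and doubles the copy number of the retained
#' portion; sequence distal to the first break is lost from this
#' haplotype.
#'
#' @param dc A [DerivativeChromosome-class].
#' @param nCycles Number of cycles (>= 1).
#' @param windowFrac Fraction of the current derivative length, measured
#'   from the unstable end, within which each break is drawn.
#' @param seed Optional integer seed for reproducibility.
#' @return The modified [DerivativeChromosome-class].
#' @export
applyBfbCycles <- function(dc, nCycles, windowFrac = 0.1, seed = NULL) {
  if (length(nCycles) != 1L || !is.finite(nCycles) || nCycles < 1)
    stop("nCycles must be an integer >= 1")
  if (!is.null(seed)) set.seed(seed)
  for (cyc in seq_len(nCycles)) {
    ld <- derivativeLength(dc)
    b <- floor(runif(1L, max(1, (1 - windowFrac) * ld), ld))
    dc <- .truncateDerivative(dc, b)
    rev <- dc@segments[rev(seq_len(nrow(dc@segments))), , drop = FALSE]
    rev$strand <- ifelse(rev$strand == "+", "-", "+")
    seg <- rbind(dc@segments, rev)
    rownames(seg) <- NULL
    dc <- new("DerivativeChromosome", genome = dc@genome, segments = seg)
  }
  dc
}

# keep the first `len` bp of the derivative (derivative coordinates)
.truncateDerivative <- function(dc, len) {
  seg <- dc@segments
  widths <- seg$end - seg$start
  ends <- cumsum(widths)
  keep <- which(ends <= len)
  cut <- if (length(keep)) max(keep) else 0L
  out <- seg[seq_len(cut), , drop = FALSE]
  used <- if (cut > 0L) ends[cut] else 0
  rem <- len - used
  if (rem > 0) {
    s <- seg[cut + 1L, ]
    piece <- if (s$strand == "+") .seg(s$start, s$start + rem, "+")
             else .seg(s$end - rem, s$end, "-")
    out <- rbind(out, piece)
  }
  rownames(out) <- NULL
  new("DerivativeChromosome", genome = dc@genome, segments = out)
}

#' Apply a chromothripsis (shattering) event
#'
#' The region is cut at `nFragments - 1` uniformly drawn internal
#' positions; each fragment is retained independently with probability
#' `retainProb`; retained fragments are shuffled in random order and
#' orientation and re-ligated in place.  Copy number of lost fragments
#' drops by 1, so the profile inside the region oscillates between two
#' states, and junction breakend sides are approximately uniform over the
#' four type categories.
#'
#' @param dc A [DerivativeChromosome-class].
#' @param region `c(start, end)` reference interval to shatter, inside a
#'   forward-retained region.
#' @param nFragments Number of fragments (>= 2).
#' @param retainProb Per-fragment retention probability.
#' @param seed Optional integer seed.
#' @return The modified [DerivativeChromosome-class].
#' @export
applyChromothripsis <- function(dc, region, nFragments, retainProb = 0.5,
                                seed = NULL) {
  iv <- .checkInterval(region, dc@genome@length)
  if (nFragments < 2)
    stop("nFragments must be >= 2")
  if (retainProb < 0 || retainProb > 1)
    stop("retainProb must lie in [0, 1]")
  if (iv[2L] - iv[1L] < nFragments)
    stop("region too small for the requested number of fragments")
  if (!is.null(seed)) set.seed(seed)
  i <- .findForwardSegment(dc, iv[1L], iv[2L])
  s <- dc@segments[i, ]
  cuts <- sort(iv[1L] + sample.int(iv[2L] - iv[1L] - 1L, nFragments - 1L))
  bounds <- c(iv[1L], cuts, iv[2L])
  frags <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
  retained <- runif(nFragments) < retainProb
  kept <- frags[retained, , drop = FALSE]
  if (nrow(kept) > 0L) {
    kept <- kept[sample.int(nrow(kept)), , drop = FALSE]
    kept$strand <- ifelse(runif(nrow(kept)) < 0.5, "+", "-")
  } else {
    kept <- .seg(numeric(0), numeric(0), character(0))
  }
  .spliceSegments(dc, i, rbind(.seg(s$start, iv[1L], "+"),
                               kept,
                               .seg(iv[2L], s$end, "+")))
}
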