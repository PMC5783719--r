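# Deriving WGS-level observables (breakpoint junctions, copy number) from a
# derivative chromosome.

.emptyJunctionFrame <- function() {
  data.frame(chromA = character(0), posA = numeric(0), sideA = character(0),
             chromB = character(0), posB = numeric(0), sideB = character(0),
             insertLen = numeric(0), stringsAsFactors = FALSE)
}

#' Construct a junction set
#'
#' Junctions are canonicalized (breakend `a` before `b` by
#' `(chrom, pos, side)`), sorted, and exact duplicates removed.
#'
#' @param junctions `data.frame` with columns `chromA`, `posA`, `sideA`,
#'   `chromB`, `posB`, `sideB` and optionally `insertLen` (default 0).
#' @return A [JunctionSet-class].
#' @export
JunctionSet <- function(junctions = .emptyJunctionFrame()) {
  if (!"insertLen" %in% names(junctions))
    junctions$insertLen <- if (nrow(junctions)) 0 else numeric(0)
  junctions <- .canonicalizeJunctions(junctions)
  new("JunctionSet", junctions = junctions)
}

.canonicalizeJunctions <- function(j) {
  j <- j[, .junctionCols, drop = FALSE]
  if (nrow(j)) {
    swap <- (j$chromA > j$chromB) |
      (j$chromA == j$chromB & j$posA > j$posB) |
      (j$chromA == j$chromB & j$posA == j$posB & j$sideA > j$sideB)
    if (any(swap)) {
      a <- j[swap, c("chromA", "posA", "sideA")]
      j[swap, c("chromA", "posA", "sideA")] <-
        j[swap, c("chromB", "posB", "sideB")]
      j[swap, c("chromB", "posB", "sideB")] <- a
    }
    j <- unique(j)
    j <- j[order(j$chromA, j$posA, j$chromB, j$posB, j$sideA, j$sideB), ,
           drop = FALSE]
    rownames(j) <- NULL
  }
  j
}

#' Derive breakpoint junctions from a derivative chromosome
#'
#' Scans adjacent segment pairs of the derivative and emits one junction
#' per pair whose reference coordinates are not contiguous in reference
#' orientation.  The result is deterministic: canonically ordered and
#' deduplicated, so a junction present in several copies of a fused arm is
#' reported once, as a sequencing pipeline would.
#'
#' @param dc A [DerivativeChromosome-class].
#' @return A [JunctionSet-class].
#' @examples
#' deriveJunctions(applyDeletion(newGenome(1e3), c(100, 200)))
#' @export
deriveJunctions <- function(dc) {
  stopifnot(is(dc, "DerivativeChromosome"))
  seg <- dc@segments
  n <- nrow(seg)
  if (n < 2L) return(JunctionSet())
  li <- seq_len(n - 1L)
  ri <- li + 1L
  lStrand <- seg$strand[li]; rStrand <- seg$strand[ri]
  contiguous <- (lStrand == "+" & rStrand == "+" &
                   seg$end[li] == seg$start[ri]) |
                (lStrand == "-" & rStrand == "-" &
                   seg$start[li] == seg$end[ri])
  keep <- which(!contiguous)
  if (!length(keep)) return(JunctionSet())
  posA <- ifelse(lStrand[keep] == "+", seg$end[li][keep] - 1,
                 seg$start[li][keep])
  sideA <- ifelse(lStrand[keep] == "+", "R", "L")
  posB <- ifelse(rStrand[keep] == "+", seg$start[ri][keep],
                 seg$end[ri][keep] - 1)
  sideB <- ifelse(rStrand[keep] == "+", "L", "R")
  JunctionSet(data.frame(
    chromA = dc@genome@chrom, posA = posA, sideA = sideA,
    chromB = dc@genome@chrom, posB = posB, sideB = sideB,
    insertLen = 0, stringsAsFactors = FALSE))
}

#' Derive an integer copy-number profile
#'
#' Computes per-base coverage of the reference by the derivative segments,
#' adds the `baselineCN - 1` intact homolog copies, averages per bin of
#' `binSize` bp, rounds to integer, and merges equal-CN neighbours into
#' segments tiling the whole chromosome.
#'
#' @param dc A [DerivativeChromosome-class].
#' @param binSize Bin width in bp (>= 1); 1 reports exact per-base
#'   segments.
#' @return A [CNProfile-class].
#' @examples
#' deriveCopyNumber(applyTandemDuplication(newGenome(1e3), c(100, 200)))
#' @export
deriveCopyNumber <- function(dc, binSize = 1L) {
  stopifnot(is(dc, "DerivativeChromosome"))
  if (binSize < 1) stop("binSize must be >= 1")
  L <- dc@genome@length
  seg <- dc@segments
  cov <- IRanges::coverage(IRanges::IRanges(seg$start + 1, seg$end),
                           width = L)
  cov <- cov + (dc@genome@baselineCN - 1L)
  if (binSize > 1) {
    starts <- seq(1, L, by = binSize)
    ends <- pmin(starts + binSize - 1, L)
    v <- IRanges::Views(cov, start = starts, end = ends)
    cn <- as.integer(round(IRanges::viewMeans(v)))
    rl <- S4Vectors::Rle(cn)
    width <- (ends - starts + 1)
    runStarts <- starts[cumsum(c(0L, S4Vectors::runLength(rl)))[
      seq_along(S4Vectors::runValue(rl))] + 1L] - 1
    runEnds <- ends[cumsum(S4Vectors::runLength(rl))]
    segs <- data.frame(start = runStarts, end = runEnds,
                       cn = S4Vectors::runValue(rl))
  } else {
    rl <- cov
    runLen <- S4Vectors::runLength(rl)
    ends <- cumsum(as.numeric(runLen))
    segs <- data.frame(start = c(0, ends[-length(ends)]), end = ends,
                       cn = as.integer(S4Vectors::runValue(rl)))
  }
  new("CNProfile", chrom = dc@genome@chrom, length = L, segments = segs)
}

#' Construct a copy-number profile directly
#'
#' @param segments `data.frame` with columns `start`, `end`, `cn` tiling
#'   `[0, length)`.
#' @param length Chromosome length in bp.
#' @param chrom Chromosome name.
#' @return A [CNProfile-class]; adjacent equal-CN segments are merged.
#' @export
CNProfile <- function(segments, length = max(segments$end),
                      chrom = "chr1") {
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 1L) {
    same <- c(FALSE, segments$cn[-1L] == segments$cn[-nrow(segments)] &
                segments$start[-1L] == segments$end[-nrow(segments)])
    grp <- cumsum(!same)
    segments <- data.frame(
      start = tapply(segments$start, grp, min),
      end = tapply(segments$end, grp, max),
      cn = tapply(segments$cn, grp, function(x) x[1L]))
  }
  rownames(segments) <- NULL
  new("CNProfile", chrom = chrom, length = as.numeric(length),
      segments = segments)
}

# copy number at a single reference position
.cnAt <- function(cn, pos) {
  seg <- cn@segments
  i <- findInterval(pos, seg$start)
  seg$cn[pmax(i, 1L)]
}
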