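#' Construct a genome model
#'
#' @param length Chromosome length in bp (> 0).
#' @param baselineCN Baseline total copy number across homologs (>= 1).
#' @param chrom Chromosome name.
#' @return A [GenomeModel-class].
#' @examples
#' GenomeModel(1e6)
#' @export
GenomeModel <- function(length, baselineCN = 2L, chrom = "chr1") {
  if (length(length) != 1L || !is.finite(length) || length <= 0)
    stop("genome 'length' must be a single positive number of bp")
  new("GenomeModel", chrom = chrom, length = as.numeric(length),
      baselineCN = as.integer(baselineCN))
}

#' Create an unrearranged derivative chromosome
#'
#' Returns the identity derivative: a single forward segment covering the
#' whole reference.  [deriveJunctions()] on the result is empty and
#' [deriveCopyNumber()] is uniform at the baseline copy number.
#'
#' @param length Chromosome length in bp, or a [GenomeModel-class].
#' @param baselineCN Baseline total copy number (ignored when a
#'   `GenomeModel` is supplied).
#' @param chrom Chromosome name (ignored when a `GenomeModel` is supplied).
#' @return A [DerivativeChromosome-class].
#' @examples
#' dc <- newGenome(1e6)
#' length(deriveJunctions(dc))
#' @export
newGenome <- function(length, baselineCN = 2L, chrom = "chr1") {
  gm <- if (is(length, "GenomeModel")) length
        else GenomeModel(length, baselineCN, chrom)
  new("DerivativeChromosome", genome = gm,
      segments = data.frame(start = 0, end = gm@length, strand = "+",
                            stringsAsFactors = FALSE))
}

#' @describeIn GenomeModel-class chromosome name
#' @param x object
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname GenomeModel-class
#' @export
setMethod("chromName", "GenomeModel", function(x) x@chrom)
#' @rdname DerivativeChromosome-class
#' @param x object
#' @export
setMethod("chromName", "DerivativeChromosome", function(x) x@genome@chrom)
#' @rdname CNProfile-class
#' @param x object
#' @export
setMethod("chromName", "CNProfile", function(x) x@chrom)

#' @describeIn GenomeModel-class reference length in bp
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname GenomeModel-class
#' @export
setMethod("genomeLength", "GenomeModel", function(x) x@length)
#' @rdname DerivativeChromosome-class
#' @export
setMethod("genomeLength", "DerivativeChromosome", function(x) x@genome@length)
#' @rdname CNProfile-class
#' @export
setMethod("genomeLength", "CNProfile", function(x) x@length)

#' @describeIn GenomeModel-class baseline total copy number
#' @export
setGeneric("baselineCN", function(x) standardGeneric("baselineCN"))
#' @rdname GenomeModel-class
#' @export
setMethod("baselineCN", "GenomeModel", function(x) x@baselineCN)
#' @rdname DerivativeChromosome-class
#' @export
setMethod("baselineCN", "DerivativeChromosome", function(x) x@genome@baselineCN)

#' Segment table of a derivative chromosome or copy-number profile
#'
#' @param x A [DerivativeChromosome-class] or [CNProfile-class].
#' @return The `data.frame` of segments.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))
#' @rdname segments
#' @export
setMethod("segments", "DerivativeChromosome", function(x) x@segments)
#' @rdname segments
#' @export
setMethod("segments", "CNProfile", function(x) x@segments)

#' Total length of the derivative molecule
#'
#' @param dc A [DerivativeChromosome-class].
#' @return Sum of segment lengths in bp.
#' @export
derivativeLength <- function(dc) {
  stopifnot(is(dc, "DerivativeChromosome"))
  sum(dc@segments$end - dc@segments$start)
}

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %s, %s bp, baseline CN %d\n",
              object@chrom, format(object@length, big.mark = ","),
              object@baselineCN))
})

setMethod("show", "DerivativeChromosome", function(object) {
  cat(sprintf("DerivativeChromosome on %s (%s bp reference)\n",
              object@genome@chrom,
              format(object@genome@length, big.mark = ",")))
  cat(sprintf("  %d segment(s), derivative length %s bp\n",
              nrow(object@segments),
              format(derivativeLength(object), big.mark = ",")))
})

setMethod("show", "CNProfile", function(object) {
  cat(sprintf("CNProfile on %s: %d segment(s), CN states {%s}\n",
              object@chrom, nrow(object@segments),
              paste(sort(unique(object@segments$cn)), collapse = ", ")))
})

#' @rdname JunctionSet-class
#' @param x a `JunctionSet`
#' @export
setMethod("length", "JunctionSet", function(x) nrow(x@junctions))

#' @rdname JunctionSet-class
#' @param row.names,optional,... passed on conventions of base
#'   `as.data.frame`; ignored.
#' @export
setMethod("as.data.frame", "JunctionSet",
  function(x, row.names = NULL, optional = FALSE, ...) x@junctions)

#' @rdname CNProfile-class
#' @param row.names,optional,... ignored.
#' @export
setMethod("as.data.frame", "CNProfile",
  function(x, row.names = NULL, optional = FALSE, ...) {
    cbind(chrom = x@chrom, x@segments)
  })

setMethod("show", "JunctionSet", function(object) {
  cat(sprintf("JunctionSet with %d junction(s)\n", length(object)))
  if (length(object) > 0)
    print(utils::head(object@junctions, 8L), row.names = FALSE)
  if (length(object) > 8L) cat("  ...\n")
})
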