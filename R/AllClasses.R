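#' @import methods
#' @importFrom stats chisq.test fisher.test wilcox.test binom.test runif
#'   rmultinom setNames
#' @importFrom utils read.table write.table head tail packageVersion
NULL

#' Reference frame for a single simulated chromosome
#'
#' A `GenomeModel` fixes the coordinate system in which derivative
#' chromosomes, junctions and copy-number profiles are expressed: one named
#' chromosome of a given length, present at a baseline total copy number
#' (across all homologs) of `baselineCN`.  Rearrangement events are applied
#' to one haplotype; the remaining `baselineCN - 1` homologs stay intact and
#' contribute uniformly to derived copy number.
#'
#' All coordinates in the package are 0-based, half-open.
#'
#' @slot chrom Chromosome name.
#' @slot length Chromosome length in bp.
#' @slot baselineCN Baseline total copy number (default 2).
#' @export
setClass("GenomeModel",
  representation(chrom = "character", length = "numeric",
                 baselineCN = "integer"),
  prototype(chrom = "chr1", length = 1e8, baselineCN = 2L))

setValidity("GenomeModel", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty name")
  if (length(object@length) != 1L || is.na(object@length) || object@length <= 0)
    msg <- c(msg, "'length' must be a single positive number of bp")
  if (length(object@baselineCN) != 1L || is.na(object@baselineCN) ||
      object@baselineCN < 1L)
    msg <- c(msg, "'baselineCN' must be an integer >= 1")
  if (length(msg)) msg else TRUE
})

#' One rearranged haplotype as an ordered list of oriented segments
#'
#' A `DerivativeChromosome` represents a rearranged haplotype as the ordered
#' list of oriented reference segments that would be read along the
#' derivative molecule.  Each segment is a half-open reference interval
#' `[start, end)` traversed forward (`"+"`) or reverse (`"-"`).  The
#' identity chromosome is a single forward segment covering the whole
#' reference.
#'
#' @slot genome A [GenomeModel-class].
#' @slot segments `data.frame` with columns `start`, `end` (0-based,
#'   half-open) and `strand` (`"+"` or `"-"`), in derivative order.
#' @seealso [newGenome()], [deriveJunctions()], [deriveCopyNumber()]
#' @export
setClass("DerivativeChromosome",
  representation(genome = "GenomeModel", segments = "data.frame"))

setValidity("DerivativeChromosome", function(object) {
  seg <- object@segments
  msg <- character()
  if (!all(c("start", "end", "strand") %in% names(seg)))
    return("'segments' needs columns start, end, strand")
  if (nrow(seg) == 0L)
    msg <- c(msg, "segment list must be non-empty")
  if (any(seg$start < 0) || any(seg$end > object@genome@length) ||
      any(seg$start >= seg$end))
    msg <- c(msg, "every segment must satisfy 0 <= start < end <= genome length")
  if (!all(seg$strand %in% c("+", "-")))
    msg <- c(msg, "segment strand must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' A set of breakpoint junctions
#'
#' A junction joins two oriented breakends.  A breakend is a chromosome,
#' a 0-based position (the retained terminal base adjacent to the join) and
#' a side: `"R"` means retained sequence lies at coordinates `<= pos`,
#' `"L"` means retained sequence lies at coordinates `>= pos`.  Junctions
#' are stored canonically ordered (breakend `a` before `b` by
#' `(chrom, pos)`) and deduplicated, with an optional untemplated
#' `insertLen` at the join.
#'
#' The side encoding maps 1:1 onto BEDPE strands: `R` to `"+"`, `L` to
#' `"-"` (see [writeBedpe()]).
#'
#' @slot junctions `data.frame` with columns `chromA`, `posA`, `sideA`,
#'   `chromB`, `posB`, `sideB`, `insertLen`.
#' @seealso [classifyJunctions()], [readBedpe()]
#' @export
setClass("JunctionSet", representation(junctions = "data.frame"))

.junctionCols <- c("chromA", "posA", "sideA", "chromB", "posB", "sideB",
                   "insertLen")

setValidity("JunctionSet", function(object) {
  j <- object@junctions
  if (!all(.junctionCols %in% names(j)))
    return(paste("'junctions' needs columns:",
                 paste(.junctionCols, collapse = ", ")))
  msg <- character()
  if (!all(j$sideA %in% c("R", "L")) || !all(j$sideB %in% c("R", "L")))
    msg <- c(msg, "breakend sides must be 'R' or 'L'")
  if (any(j$posA < 0) || any(j$posB < 0))
    msg <- c(msg, "breakend positions must be >= 0")
  if (any(j$insertLen < 0))
    msg <- c(msg, "insertLen must be >= 0")
  bad <- j$chromA == j$chromB &
    (j$posA > j$posB | (j$posA == j$posB & j$sideA > j$sideB))
  if (any(bad))
    msg <- c(msg, "junctions must be canonically ordered (a <= b)")
  if (length(msg)) msg else TRUE
})

#' Integer copy number over a contiguous tiling of the reference
#'
#' Ordered `(start, end, cn)` segments tiling `[0, length)` of one
#' chromosome without gaps or overlaps, with adjacent equal-CN segments
#' merged.
#'
#' @slot chrom Chromosome name.
#' @slot length Chromosome length in bp.
#' @slot segments `data.frame` with columns `start`, `end`, `cn`.
#' @seealso [deriveCopyNumber()], [readCnBed()]
#' @export
setClass("CNProfile",
  representation(chrom = "character", length = "numeric",
                 segments = "data.frame"))

setValidity("CNProfile", function(object) {
  seg <- object@segments
  if (!all(c("start", "end", "cn") %in% names(seg)))
    return("'segments' needs columns start, end, cn")
  msg <- character()
  if (nrow(seg) == 0L)
    msg <- c(msg, "profile must have at least one segment")
  else {
    if (seg$start[1L] != 0 || seg$end[nrow(seg)] != object@length)
      msg <- c(msg, "profile must tile [0, length)")
    if (nrow(seg) > 1L && any(seg$start[-1L] != seg$end[-nrow(seg)]))
      msg <- c(msg, "profile segments must be contiguous (no gaps/overlaps)")
    if (any(seg$cn < 0))
      msg <- c(msg, "cn must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample structural-variant classification report
#'
#' Produced by [classifySample()].  Every junction of the input is assigned
#' to exactly one complex event (chromothripsis, breakage-fusion-bridge,
#' templated insertion) or one simple junction class, so class counts
#' partition the junction set.
#'
#' @slot junctions The classified [JunctionSet-class].
#' @slot cn The [CNProfile-class] used as evidence.
#' @slot assignment Character vector, one entry per junction: a simple
#'   junction class or an event id of the form `"<class>#<k>"`.
#' @slot events List of classified complex events; each element is a list
#'   with at least `eventClass`, `junctions` (row indices) and class
#'   specific attributes.
#' @export
setClass("SampleReport",
  representation(junctions = "JunctionSet", cn = "CNProfile",
                 assignment = "character", events = "list"))

setValidity("SampleReport", function(object) {
  if (length(object@assignment) != nrow(object@junctions@junctions))
    return("one assignment per junction required")
  TRUE
})

#' Balancer marker-exchange cross design
#'
#' Encodes a self-fertilizing hermaphrodite heterozygous for a normal
#' chromosome and a balancer (crossover-suppressing) homolog, each carrying
#' visible markers on either side of the balanced interval.  A single
#' crossover within the interval (probability `r` per meiosis) produces the
#' two reciprocal recombinant haplotypes; the design enumerates all ten
#' diploid genotypes of the self progeny, maps them to phenotype classes and
#' flags which phenotype classes are unambiguously recombinant.
#'
#' Semi-dominant markers are modelled dosage-aware (heterozygous and
#' homozygous carriers are phenotypically distinguishable); recessive
#' markers require two copies.  A phenotype class is flagged recombinant
#' only if no non-recombinant genotype maps to it: the reciprocal
#' double-heterozygote (both recombinant haplotypes) is phenotypically
#' identical to the parental heterozygote and therefore never scored.
#'
#' @slot markers `data.frame` with columns `name`, `dominance`
#'   (`"recessive"` or `"semi_dominant"`), `haplotype` (`"normal"` or
#'   `"balancer"`) and `side` (`"left"` or `"right"` of the crossover
#'   interval).
#' @slot haplotypes Named list of character vectors: the marker content of
#'   `normal`, `balancer`, `rec1` (normal-left + balancer-right) and `rec2`
#'   (balancer-left + normal-right).
#' @slot genotypes `data.frame` enumerating the ten unordered haplotype
#'   pairs with their phenotype label and recombinant flag.
#' @slot phenotypes `data.frame` of distinct phenotype classes with a
#'   class-level recombinant flag.
#' @slot viability Named numeric in `[0, 1]`, one entry per genotype.
#' @seealso [defaultCross()], [expectedProgeny()], [estimateFrequency()]
#' @export
setClass("CrossDesign",
  representation(markers = "data.frame", haplotypes = "list",
                 genotypes = "data.frame", phenotypes = "data.frame",
                 viability = "numeric"))

setValidity("CrossDesign", function(object) {
  msg <- character()
  if (!all(c("name", "dominance", "haplotype", "side") %in%
           names(object@markers)))
    msg <- c(msg, "'markers' needs columns name, dominance, haplotype, side")
  if (!all(object@markers$dominance %in% c("recessive", "semi_dominant")))
    msg <- c(msg, "marker dominance must be 'recessive' or 'semi_dominant'")
  if (!all(names(object@viability) == object@genotypes$genotype))
    msg <- c(msg, "viability must be named by genotype, in genotype order")
  if (any(object@viability < 0 | object@viability > 1))
    msg <- c(msg, "viabilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Recombinant-frequency estimate
#'
#' @slot nRecombinant Number of progeny in recombinant phenotype classes.
#' @slot nTotal Total progeny scored.
#' @slot frequencyPct Frequency as a percentage, rounded to 2 decimals.
#' @slot ci95 Exact (Clopper-Pearson) 95% confidence interval, in percent.
#' @seealso [estimateFrequency()]
#' @export
setClass("HtRecEstimate",
  representation(nRecombinant = "numeric", nTotal = "numeric",
                 frequencyPct = "numeric", ci95 = "numeric"))

setValidity("HtRecEstimate", function(object) {
  msg <- character()
  if (object@frequencyPct < 0 || object@frequencyPct > 100)
    msg <- c(msg, "frequencyPct must lie in [0, 100]")
  if (length(object@ci95) != 2L)
    msg <- c(msg, "ci95 must be length 2")
  if (length(msg)) msg else TRUE
})

#' Two-marker genetic map distance estimate
#'
#' @slot interval Label of the marker interval.
#' @slot estimator `"direct"` or `"self_cross_corrected"`.
#' @slot nRecombinantClasses Progeny counted in the two visible recombinant
#'   phenotype classes.
#' @slot nTotal Total progeny scored.
#' @slot distanceCM Map distance in centimorgans.
#' @slot ci95CM 95% confidence interval in centimorgans (exact binomial CI
#'   on the recombinant count, propagated through the estimator).
#' @seealso [mapDistance()]
#' @export
setClass("MapDistanceEstimate",
  representation(interval = "character", estimator = "character",
                 nRecombinantClasses = "numeric", nTotal = "numeric",
                 distanceCM = "numeric", ci95CM = "numeric"))

setValidity("MapDistanceEstimate", function(object) {
  if (object@distanceCM < 0) "distance must be >= 0" else TRUE
})
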