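# Balancer marker-exchange cross designs and the segregation model.

# phenotype token for one marker given its copy number in a genotype
.markerToken <- function(name, dominance, dose) {
  if (dose == 0L) return(NA_character_)
  if (dominance == "recessive") {
    if (dose == 2L) name else NA_character_
  } else {
    # semi-dominant: heterozygous and homozygous carriers distinguishable
    paste0(name, ":", if (dose == 2L) "hom" else "het")
  }
}

.phenotypeLabel <- function(markers, hap1, hap2, haplotypes) {
  content <- c(haplotypes[[hap1]], haplotypes[[hap2]])
  toks <- vapply(seq_len(nrow(markers)), function(i) {
    .markerToken(markers$name[i], markers$dominance[i],
                 sum(content == markers$name[i]))
  }, character(1))
  toks <- toks[!is.na(toks)]
  if (!length(toks)) "wild_type_appearance" else paste(toks, collapse = " ")
}

#' Construct a balancer marker-exchange cross design
#'
#' Builds the full genotype and phenotype tables for a self-fertilizing
#' heterozygote carrying one normal chromosome and one balancer homolog.
#' The two recombinant haplotypes are derived from the marker sides:
#' `rec1` carries the normal left arm and the balancer right arm, `rec2`
#' the converse.  Ten unordered diploid genotypes are enumerated and
#' collapsed to phenotype classes; a class is flagged recombinant when
#' every genotype producing it carries a recombinant haplotype.
#'
#' @param markers `data.frame` with columns `name`, `dominance`
#'   (`"recessive"`/`"semi_dominant"`), `haplotype`
#'   (`"normal"`/`"balancer"`) and `side` (`"left"`/`"right"` of the
#'   crossover interval).
#' @param viability Optional named numeric in `[0, 1]` of per-genotype
#'   viabilities (genotype names like `"normal/balancer"`); unnamed
#'   genotypes default to 1.
#' @return A [CrossDesign-class].
#' @seealso [defaultCross()]
#' @export
CrossDesign <- function(markers, viability = NULL) {
  stopifnot(all(c("name", "dominance", "haplotype", "side") %in%
                  names(markers)))
  hapOf <- function(hap, side)
    markers$name[markers$haplotype == hap & markers$side == side]
  haplotypes <- list(
    normal = markers$name[markers$haplotype == "normal"],
    balancer = markers$name[markers$haplotype == "balancer"],
    rec1 = c(hapOf("normal", "left"), hapOf("balancer", "right")),
    rec2 = c(hapOf("balancer", "left"), hapOf("normal", "right")))
  hapNames <- names(haplotypes)
  pairs <- which(upper.tri(matrix(0, 4, 4), diag = TRUE), arr.ind = TRUE)
  geno <- data.frame(
    hap1 = hapNames[pairs[, "row"]],
    hap2 = hapNames[pairs[, "col"]],
    stringsAsFactors = FALSE)
  geno$genotype <- paste(geno$hap1, geno$hap2, sep = "/")
  geno$recombinant <- geno$hap1 %in% c("rec1", "rec2") |
    geno$hap2 %in% c("rec1", "rec2")
  geno$phenotype <- vapply(seq_len(nrow(geno)), function(i)
    .phenotypeLabel(markers, geno$hap1[i], geno$hap2[i], haplotypes),
    character(1))
  phen <- data.frame(phenotype = unique(geno$phenotype),
                     stringsAsFactors = FALSE)
  phen$recombinant <- vapply(phen$phenotype, function(p)
    all(geno$recombinant[geno$phenotype == p]), logical(1))
  v <- setNames(rep(1, nrow(geno)), geno$genotype)
  if (!is.null(viability)) {
    unknown <- setdiff(names(viability), names(v))
    if (length(unknown))
      stop("unknown genotype(s) in viability: ",
           paste(unknown, collapse = ", "))
    v[names(viability)] <- viability
  }
  new("CrossDesign", markers = markers, haplotypes = haplotypes,
      genotypes = geno, phenotypes = phen, viability = v)
}

#' The default balancer cross
#'
#' The main scoring system: the normal chromosome II carries the
#' semi-dominant `dpy-25` mutation (left of the balanced interval); the
#' balancer homolog (`mIn1` inversion) carries the recessive `rol-1`
#' mutation (left) and the semi-dominant GFP insertion `mIs14` (right).
#' With no recombination the self progeny segregate 50% heterozygous,
#' 25% normal-homozygous, 25% balancer-homozygous.
#'
#' @param viability Optional per-genotype viabilities, see [CrossDesign()].
#' @return A [CrossDesign-class].
#' @examples
#' expectedProgeny(defaultCross(), r = 0)
#' @export
defaultCross <- function(viability = NULL) {
  CrossDesign(data.frame(
    name = c("dpy-25", "rol-1", "mIs14"),
    dominance = c("semi_dominant", "recessive", "semi_dominant"),
    haplotype = c("normal", "balancer", "balancer"),
    side = c("left", "left", "right"),
    stringsAsFactors = FALSE), viability = viability)
}

setMethod("show", "CrossDesign", function(object) {
  cat(sprintf("CrossDesign: %d marker(s), %d genotype(s), %d phenotype class(es)\n",
              nrow(object@markers), nrow(object@genotypes),
              nrow(object@phenotypes)))
  rec <- object@phenotypes$phenotype[object@phenotypes$recombinant]
  cat("  recombinant classes:",
      if (length(rec)) paste(rec, collapse = "; ") else "(none)", "\n")
})

#' Phenotype classes of a cross design
#'
#' @param cross A [CrossDesign-class].
#' @return `data.frame` with columns `phenotype` and `recombinant`.
#' @export
phenotypeClasses <- function(cross) {
  stopifnot(is(cross, "CrossDesign"))
  cross@phenotypes
}

#' Genotype table of a cross design
#'
#' @param cross A [CrossDesign-class].
#' @return `data.frame` with one row per unordered diploid genotype:
#'   `hap1`, `hap2`, `genotype`, `recombinant`, `phenotype`.
#' @export
genotypeTable <- function(cross) {
  stopifnot(is(cross, "CrossDesign"))
  cross@genotypes
}

#' Expected progeny phenotype distribution under the segregation model
#'
#' Each parental meiosis yields a recombinant gamete pair with probability
#' `r` (one crossover within the balanced interval; reciprocal products
#' equally likely), so gametes are `normal` and `balancer` with
#' probability `(1 - r) / 2` each and `rec1`, `rec2` with probability
#' `r / 2` each.  Self progeny arise from random union of two independent
#' gametes, are weighted by per-genotype viability, renormalized over
#' viable classes and collapsed to phenotype classes.  With `r = 0` and
#' unit viability the default cross returns the Mendelian 50/25/25 split
#' and all recombinant classes have probability exactly 0.
#'
#' @param cross A [CrossDesign-class].
#' @param r Crossover probability per meiosis within the balanced
#'   interval, in `[0, 0.5]`.
#' @param viability Optional named per-genotype viabilities overriding the
#'   design's.
#' @return `data.frame` with columns `phenotype`, `probability`,
#'   `recombinant`, ordered by decreasing probability.
#' @export
expectedProgeny <- function(cross, r = 0, viability = NULL) {
  stopifnot(is(cross, "CrossDesign"))
  if (length(r) != 1L || !is.finite(r) || r < 0 || r > 0.5)
    stop("r must lie in [0, 0.5]")
  gam <- c(normal = (1 - r) / 2, balancer = (1 - r) / 2,
           rec1 = r / 2, rec2 = r / 2)
  v <- cross@viability
  if (!is.null(viability)) {
    unknown <- setdiff(names(viability), names(v))
    if (length(unknown))
      stop("unknown genotype(s) in viability: ",
           paste(unknown, collapse = ", "))
    v[names(viability)] <- viability
  }
  geno <- cross@genotypes
  pGeno <- gam[geno$hap1] * gam[geno$hap2] *
    ifelse(geno$hap1 == geno$hap2, 1, 2)
  w <- pGeno * v[geno$genotype]
  if (sum(w) <= 0) stop("no viable progeny under the supplied viabilities")
  w <- w / sum(w)
  probs <- tapply(w, geno$phenotype, sum)
  out <- data.frame(phenotype = names(probs),
                    probability = as.numeric(probs),
                    stringsAsFactors = FALSE)
  out <- merge(out, cross@phenotypes, by = "phenotype", sort = FALSE)
  out <- out[order(-out$probability), ]
  rownames(out) <- NULL
  out
}

#' Simulate a scored brood
#'
#' Multinomial draw of `n` progeny from the [expectedProgeny()]
#' distribution.
#'
#' @inheritParams expectedProgeny
#' @param n Number of progeny scored (>= 1).
#' @param seed Optional integer seed.
#' @return Named integer vector of counts per phenotype class (a progeny
#'   tally).
#' @export
simulateProgeny <- function(cross, r, n, viability = NULL, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ep <- expectedProgeny(cross, r, viability)
  counts <- as.integer(rmultinom(1L, size = n, prob = ep$probability))
  setNames(counts, ep$phenotype)
}
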