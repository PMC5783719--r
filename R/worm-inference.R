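# Frequency inference, group tests, fold changes and two-marker map
# distances for the balancer scoring system.

#' Estimate the recombinant (marker-exchange) frequency
#'
#' The frequency is `100 * nRecombinant / nTotal`, reported rounded to two
#' decimals, with an exact Clopper-Pearson 95% confidence interval.
#' Supply either a progeny tally plus the cross design that defines which
#' phenotype classes are recombinant, or the two counts directly.
#'
#' @param tally Named integer vector of phenotype-class counts (as
#'   returned by [simulateProgeny()] or [readProgenyTsv()]), or the
#'   recombinant count when `nTotal` is given.
#' @param cross A [CrossDesign-class] (ignored when counts are supplied
#'   directly).
#' @param nTotal Total progeny scored, when supplying counts directly.
#' @return An [HtRecEstimate-class].
#' @examples
#' estimateFrequency(2, nTotal = 3175)    # 0.06%
#' estimateFrequency(43, nTotal = 2625)   # 1.64%
#' @export
estimateFrequency <- function(tally, cross = NULL, nTotal = NULL) {
  if (!is.null(nTotal)) {
    k <- as.numeric(tally)
    n <- as.numeric(nTotal)
  } else {
    if (is.null(cross))
      stop("a CrossDesign is required to score a phenotype tally")
    if (any(tally < 0)) stop("tally counts must be non-negative")
    rec <- cross@phenotypes$phenotype[cross@phenotypes$recombinant]
    unknown <- setdiff(names(tally), cross@phenotypes$phenotype)
    if (length(unknown))
      stop("tally classes not in the cross design: ",
           paste(unknown, collapse = ", "))
    k <- sum(tally[names(tally) %in% rec])
    n <- sum(tally)
  }
  if (is.na(n) || n <= 0) stop("total progeny count must be positive")
  if (k < 0 || k > n) stop("recombinant count must lie in [0, nTotal]")
  ci <- as.numeric(binom.test(round(k), round(n))$conf.int) * 100
  new("HtRecEstimate", nRecombinant = k, nTotal = n,
      frequencyPct = round(100 * k / n, 2), ci95 = ci)
}

setMethod("show", "HtRecEstimate", function(object) {
  cat(sprintf("Ht-REC frequency: %.2f%% (%g / %g; 95%% CI %.2f-%.2f%%)\n",
              object@frequencyPct, object@nRecombinant, object@nTotal,
              object@ci95[1L], object@ci95[2L]))
})

#' @describeIn HtRecEstimate-class recombinant frequency in percent
#' @param x object
#' @export
setGeneric("frequencyPct", function(x) standardGeneric("frequencyPct"))
#' @rdname HtRecEstimate-class
#' @export
setMethod("frequencyPct", "HtRecEstimate", function(x) x@frequencyPct)

.asCounts <- function(x, cross = NULL) {
  if (is(x, "HtRecEstimate")) return(c(x@nRecombinant, x@nTotal))
  if (is.numeric(x) && length(x) == 2L && is.null(names(x)))
    return(x)
  est <- estimateFrequency(x, cross = cross)
  c(est@nRecombinant, est@nTotal)
}

#' Compare two recombinant frequencies
#'
#' Builds the 2x2 table (recombinant vs not, per group).  Fisher's exact
#' test is used when either group total is at most 1000; otherwise a
#' chi-squared test without continuity correction.  The rule is a pure
#' function of the group totals.
#'
#' @param tallyA,tallyB [HtRecEstimate-class] objects, `c(k, n)` count
#'   pairs, or named phenotype tallies (then `cross` is required).
#' @param cross Optional [CrossDesign-class] for scoring named tallies.
#' @return List with `test` (`"fisher"` or `"chisq"`), `p.value` and
#'   `table`.
#' @examples
#' compareFrequencies(c(2, 3175), c(43, 2625))
#' @export
compareFrequencies <- function(tallyA, tallyB, cross = NULL) {
  a <- .asCounts(tallyA, cross); b <- .asCounts(tallyB, cross)
  if (a[2L] <= 0 || b[2L] <= 0) stop("both group totals must be positive")
  tab <- rbind(A = c(rec = a[1L], non = a[2L] - a[1L]),
               B = c(rec = b[1L], non = b[2L] - b[1L]))
  if (all(tab == 0)) stop("degenerate table: all counts are zero")
  if (a[2L] <= 1000 || b[2L] <= 1000) {
    list(test = "fisher", p.value = fisher.test(tab)$p.value, table = tab)
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    list(test = "chisq", p.value = p, table = tab)
  }
}

#' Fold change between two recombinant frequencies
#'
#' The ratio of the two 2-decimal rounded percentage frequencies, reported
#' to the nearest integer fold under both conventions (round and
#' truncate), with a flag when they differ.
#'
#' @param estA,estB [HtRecEstimate-class] objects (numerator,
#'   denominator).
#' @return List with `ratio`, `foldRound`, `foldTrunc` and
#'   `conventionsDiffer`; `foldRound`/`foldTrunc` are `NA` with an
#'   explanatory `note` when the denominator frequency is 0.
#' @examples
#' foldChange(estimateFrequency(43, nTotal = 2625),
#'            estimateFrequency(2, nTotal = 3175))  # 27-fold
#' @export
foldChange <- function(estA, estB) {
  stopifnot(is(estA, "HtRecEstimate"), is(estB, "HtRecEstimate"))
  if (estB@frequencyPct == 0)
    return(list(ratio = NA_real_, foldRound = NA_real_,
                foldTrunc = NA_real_, conventionsDiffer = NA,
                note = "not defined (denominator 0)"))
  ratio <- estA@frequencyPct / estB@frequencyPct
  fr <- round(ratio); ft <- trunc(ratio)
  list(ratio = ratio, foldRound = fr, foldTrunc = ft,
       conventionsDiffer = fr != ft)
}

#' Two-marker interval design for map-distance estimation
#'
#' A cis double heterozygote for two linked recessive markers,
#' self-fertilized.  The visible recombinant phenotype classes are the two
#' single-marker classes (`"<A> only"` and `"<B> only"`); with crossover
#' probability `p` per meiosis their summed expected frequency is
#' `R = p - p^2 / 2`, which the corrected estimator inverts exactly.
#'
#' @param markerA,markerB Marker names flanking the interval.
#' @param detectability Factor by which the raw recombinant-class fraction
#'   is divided under the `direct` estimator (default 1).
#' @return List of class `IntervalDesign`.
#' @seealso [mapDistance()], [simulateTwoMarkerProgeny()]
#' @export
twoMarkerCross <- function(markerA, markerB, detectability = 1) {
  structure(list(markerA = markerA, markerB = markerB,
                 detectability = detectability,
                 interval = paste(markerA, markerB, sep = "-"),
                 classes = c("wild_type_appearance",
                             paste(markerA, "only"),
                             paste(markerB, "only"),
                             paste(markerA, markerB, sep = " "))),
            class = "IntervalDesign")
}

#' Expected phenotype-class probabilities for a two-marker self cross
#'
#' Gametes of the cis double heterozygote are parental (`AB`, `++`, each
#' `(1 - p) / 2`) or recombinant (`A+`, `+B`, each `p / 2`); progeny
#' phenotypes follow from random gamete union with both markers recessive.
#'
#' @param p Crossover probability per meiosis in `[0, 0.5]`.
#' @param design An interval design from [twoMarkerCross()].
#' @return Named numeric probabilities over the four phenotype classes.
#' @export
expectedTwoMarkerClasses <- function(p, design) {
  if (p < 0 || p > 0.5) stop("p must lie in [0, 0.5]")
  gAB <- (1 - p) / 2; gRec <- p / 2
  pA <- gAB + gRec          # gametes carrying marker A
  pBoth <- gAB^2            # both gametes AB -> double homozygote
  pAonly <- pA^2 - pBoth
  pBonly <- pAonly
  probs <- c(1 - pAonly - pBonly - pBoth, pAonly, pBonly, pBoth)
  setNames(probs, design$classes)
}

#' Simulate a two-marker mapping brood
#'
#' @inheritParams expectedTwoMarkerClasses
#' @param n Progeny scored.
#' @param seed Optional integer seed.
#' @return Named integer tally over the four phenotype classes.
#' @export
simulateTwoMarkerProgeny <- function(p, n, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- expectedTwoMarkerClasses(p, design)
  setNames(as.integer(rmultinom(1L, n, probs)), names(probs))
}

#' Genetic map distance from a two-marker self cross
#'
#' Two estimators of the crossover probability `p` from the fraction `R`
#' of progeny in the two visible recombinant classes:
#' `direct` reports `100 * R / detectability` cM; `self_cross_corrected`
#' inverts the self-cross expectation `R = p - p^2 / 2` exactly via
#' `p = 1 - sqrt(1 - 2R)` and reports `100 * p` cM.  The 95% CI is the
#' exact binomial CI on the recombinant-class count propagated through the
#' chosen estimator.
#'
#' @param tally Named tally over the design's phenotype classes, or
#'   `c(nRecombinant, nTotal)`.
#' @param design An interval design from [twoMarkerCross()].
#' @param estimator `"self_cross_corrected"` (default) or `"direct"`.
#' @return A [MapDistanceEstimate-class].
#' @examples
#' d <- twoMarkerCross("dpy-17", "unc-36")
#' mapDistance(c(95, 1000), d)   # R = 0.095 -> 10 cM corrected
#' @export
mapDistance <- function(tally, design,
                        estimator = c("self_cross_corrected", "direct")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(design, "IntervalDesign"))
  if (is.null(names(tally)) && length(tally) == 2L) {
    k <- tally[1L]; n <- tally[2L]
  } else {
    recClasses <- design$classes[2:3]
    missing <- setdiff(recClasses, names(tally))
    if (length(missing))
      stop("tally lacks recombinant class(es): ",
           paste(missing, collapse = ", "))
    k <- sum(tally[recClasses]); n <- sum(tally)
  }
  if (n <= 0) stop("total progeny count must be positive")
  R <- k / n
  transform <- function(R) {
    if (estimator == "direct") return(100 * R / design$detectability)
    if (R > 0.5)
      stop("recombinant fraction ", signif(R, 3),
           " exceeds 0.5; the corrected estimator is undefined")
    100 * (1 - sqrt(1 - 2 * R))
  }
  d <- transform(R)
  ciR <- as.numeric(binom.test(round(k), round(n))$conf.int)
  ci <- vapply(pmin(ciR, if (estimator == "direct") Inf else 0.5),
               transform, numeric(1))
  new("MapDistanceEstimate", interval = design$interval,
      estimator = estimator, nRecombinantClasses = as.numeric(k),
      nTotal = as.numeric(n), distanceCM = d, ci95CM = ci)
}

setMethod("show", "MapDistanceEstimate", function(object) {
  cat(sprintf("Map distance (%s, %s): %.2f cM (95%% CI %.2f-%.2f; %g/%g)\n",
              object@interval, object@estimator, object@distanceCM,
              object@ci95CM[1L], object@ci95CM[2L],
              object@nRecombinantClasses, object@nTotal))
})
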