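# Templated duplication with distant intra-chromosomal insertion:
# application, observables and round-trip detection.

test_that("parameter bounds are validated", {
  expect_error(TemplatedInsertionParams(5e4, 1e3, 3e5, 100),
               "templateLen")
  expect_error(TemplatedInsertionParams(5e4, 2e5, 3e5, 100),
               "templateLen")
  expect_error(TemplatedInsertionParams(5e4, 2e4, 3e5, 3),
               "siteDeletionLen")
  expect_error(TemplatedInsertionParams(5e4, 2e4, 3e5, 2000),
               "siteDeletionLen")
  expect_error(TemplatedInsertionParams(5e4, 2e4, 62e3, 100),
               "distance")
  expect_error(TemplatedInsertionParams(5e4, 2e4, 49950, 100),
               "overlap")
})

test_that("an inverted insertion changes CN and adds two junctions", {
  p <- TemplatedInsertionParams(5e4, 2e4, 3e5, 100, inverted = TRUE)
  dc <- applyTemplatedInsertion(newGenome(1e6), p)
  expect_equal(derivativeLength(dc), 1e6 + 2e4 - 100)
  cn <- deriveCopyNumber(dc)
  pb <- cnPerBase(cn)
  expect_equal(pb[6e4], 3L)           # template amplified
  expect_equal(pb[3e5 + 50], 1L)      # site deletion
  expect_equal(pb[1e5], 2L)
  j <- as.data.frame(deriveJunctions(dc))
  expect_equal(nrow(j), 2L)
  # each junction pairs one breakend near a template boundary with one
  # within the site deletion span of the insertion point
  pos <- c(j$posA, j$posB)
  nearTemplate <- abs(pos - 5e4) <= 1 | abs(pos - 7e4) <= 1
  nearSite <- abs(pos - 3e5) <= 100
  expect_equal(sum(nearTemplate), 2L)
  expect_equal(sum(nearSite), 2L)
  # sequence-level oracle
  v <- seqTemplated(seqNew(1e6), p)
  expect_equal(j, as.data.frame(seqJunctions(v)))
  expect_equal(pb, seqCN(v, 1e6))
})

test_that("direct (non-inverted) insertions are representable too", {
  p <- TemplatedInsertionParams(5e4, 2e4, 3e5, 500, inverted = FALSE)
  dc <- applyTemplatedInsertion(newGenome(1e6), p)
  v <- seqTemplated(seqNew(1e6), p)
  expect_equal(as.data.frame(deriveJunctions(dc)),
               as.data.frame(seqJunctions(v)))
  expect_equal(cnPerBase(deriveCopyNumber(dc)), seqCN(v, 1e6))
})

test_that("detection round-trips the generating parameters", {
  for (inverted in c(TRUE, FALSE)) {
    p <- TemplatedInsertionParams(5e4, 2e4, 3e5, 100, inverted = inverted)
    dc <- applyTemplatedInsertion(newGenome(1e6), p)
    ev <- detectTemplatedInsertions(deriveJunctions(dc),
                                    deriveCopyNumber(dc, 1000))
    expect_length(ev, 1L)
    expect_equal(ev[[1L]]$template, c(5e4, 7e4))
    expect_equal(ev[[1L]]$siteDeletionLen, 100)
    expect_equal(ev[[1L]]$insertionPos, 3e5)
    expect_equal(ev[[1L]]$inverted, inverted)
  }
})

test_that("an isolated tandem duplication is not called an insertion", {
  dc <- applyTandemDuplication(newGenome(1e6), c(4e5, 43e4))
  ev <- detectTemplatedInsertions(deriveJunctions(dc),
                                  deriveCopyNumber(dc, 1000))
  expect_length(ev, 0L)
})

test_that("overlapping candidate pairings keep the smallest site deletion", {
  # two inverted insertions with nearby sites and nearby templates: a
  # spurious cross-pairing of their junctions also satisfies the raw
  # geometry, so the detector must resolve the ambiguity
  p1 <- TemplatedInsertionParams(8e4, 2e4, 3e5, 50, inverted = TRUE)
  p2 <- TemplatedInsertionParams(5e4, 2e4, 300200, 500, inverted = TRUE)
  dc <- applyTemplatedInsertion(newGenome(1e6), p1)
  dc <- applyTemplatedInsertion(dc, p2)
  js <- deriveJunctions(dc)
  cn <- deriveCopyNumber(dc, 1000)
  j <- as.data.frame(js)
  # brute force over all junction pairings: the geometry alone admits
  # more candidates than there are true events
  allCand <- list()
  for (a in seq_len(nrow(j) - 1L)) for (b in seq(a + 1L, nrow(j))) {
    hit <- htrec:::.tiPairGeometry(
      c(j$posA[a], j$posB[a]), c(j$sideA[a], j$sideB[a]),
      c(j$posA[b], j$posB[b]), c(j$sideA[b], j$sideB[b]),
      templatedInsertionBounds())
    if (!is.null(hit))
      allCand[[length(allCand) + 1L]] <- c(hit, list(pair = c(a, b)))
  }
  expect_gte(length(allCand), 3L)
  ev <- detectTemplatedInsertions(js, cn)
  expect_length(ev, 2L)
  expect_setequal(vapply(ev, function(e) e$siteDeletionLen, numeric(1)),
                  c(50, 500))
  templates <- lapply(ev, function(e) e$template)
  hasTemplate <- function(t) any(vapply(templates, function(x)
    isTRUE(all(x == t)), logical(1)))
  expect_true(hasTemplate(c(8e4, 1e5)))
  expect_true(hasTemplate(c(5e4, 7e4)))
})
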