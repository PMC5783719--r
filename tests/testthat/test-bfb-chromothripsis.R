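# Breakage-fusion-bridge cycles and chromothripsis: event mechanics and
# round-trip detection.

test_that("one BFB cycle yields a tight fold-back and duplicates the arm", {
  dc <- applyBfbCycles(newGenome(1e6), 1, seed = 11)
  j <- as.data.frame(deriveJunctions(dc))
  expect_equal(nrow(j), 1L)
  expect_lte(j$posB - j$posA, 1e4)
  expect_equal(classifyJunctions(deriveJunctions(dc)), "fold_back")
  pb <- cnPerBase(deriveCopyNumber(dc))
  expect_equal(pb[1], 3L)                       # retained arm + homolog
  expect_equal(pb[length(pb)], 1L)              # distal loss
  # sequence-level oracle for a fixed break
  v <- seqBfb1(seqNew(1e5), 95000)
  dc2 <- htrec:::.truncateDerivative(newGenome(1e5), 95000)
  seg <- rbind(segments(dc2),
               data.frame(start = 0, end = 95000, strand = "-"))
  dc2 <- new("DerivativeChromosome", genome = dc2@genome, segments = seg)
  expect_equal(as.data.frame(deriveJunctions(dc2)),
               as.data.frame(seqJunctions(v)))
  expect_equal(cnPerBase(deriveCopyNumber(dc2)), seqCN(v, 1e5))
})

test_that("n cycles give n distinct fold-backs with stepwise CN", {
  dc <- applyBfbCycles(newGenome(1e6), 3, seed = 5)
  js <- deriveJunctions(dc)
  expect_equal(length(js), 3L)
  expect_true(all(classifyJunctions(js) == "fold_back"))
  # CN steps rise monotonically toward the fused (distal) end and crash
  # to loss beyond the outermost fold-back
  cn <- segments(deriveCopyNumber(dc, 1))
  outer <- max(as.data.frame(js)$posB)
  steps <- cn$cn[cn$end <= outer + 1]
  expect_true(all(diff(steps) >= 0))
  expect_lt(cn$cn[nrow(cn)], cn$cn[1L])
  expect_error(applyBfbCycles(newGenome(1e6), 0), "nCycles")
})

test_that("BFB detection round-trips and needs the CN signature", {
  dc <- applyBfbCycles(newGenome(1e7), 3, seed = 9)
  ev <- detectBfb(deriveJunctions(dc), deriveCopyNumber(dc, 1000))
  expect_length(ev, 1L)
  expect_equal(ev[[1L]]$cycleEstimate, 3L)
  # a fold-back-like junction with flat CN is not a BFB
  js <- JunctionSet(data.frame(chromA = "chr1", posA = 5e6, sideA = "R",
                               chromB = "chr1", posB = 5e6 + 50,
                               sideB = "R", insertLen = 0))
  flat <- CNProfile(data.frame(start = 0, end = 1e7, cn = 2))
  expect_length(detectBfb(js, flat), 0L)
  # a deletion-only sample has no fold-backs at all
  del <- applyDeletion(newGenome(1e7), c(1e6, 2e6))
  expect_length(detectBfb(deriveJunctions(del),
                          deriveCopyNumber(del, 1000)), 0L)
})

test_that("chromothripsis with full retention changes nothing but order", {
  dc <- applyChromothripsis(newGenome(1e6), c(2e5, 8e5), nFragments = 10,
                            retainProb = 1, seed = 21)
  expect_equal(derivativeLength(dc), 1e6)
  expect_equal(nrow(segments(deriveCopyNumber(dc))), 1L)
})

test_that("partial retention leaves exactly two CN states in the region", {
  dc <- applyChromothripsis(newGenome(1e6), c(2e5, 8e5), nFragments = 20,
                            retainProb = 0.5, seed = 33)
  cn <- segments(deriveCopyNumber(dc, 1))
  inside <- cn[cn$start >= 2e5 & cn$end <= 8e5, ]
  expect_setequal(unique(inside$cn), c(2L, 1L))
  expect_error(applyChromothripsis(newGenome(1e6), c(2e5, 8e5), 1),
               "nFragments")
})

test_that("junction side categories are near-uniform over seeds", {
  counts <- c(RL = 0, LR = 0, RR = 0, LL = 0)
  for (s in 1:40) {
    dc <- applyChromothripsis(newGenome(1e6), c(2e5, 8e5),
                              nFragments = 20, retainProb = 0.5, seed = s)
    j <- as.data.frame(deriveJunctions(dc))
    ss <- paste0(j$sideA, j$sideB)
    for (k in names(counts)) counts[k] <- counts[k] + sum(ss == k)
  }
  frac <- counts / sum(counts)
  expect_true(all(abs(frac - 0.25) < 0.06))
})

test_that("chromothripsis detection round-trips and rejects lookalikes", {
  dc <- applyChromothripsis(newGenome(1e8), c(4e7, 4.15e7),
                            nFragments = 20, retainProb = 0.5, seed = 13)
  ev <- detectChromothripsis(deriveJunctions(dc),
                             deriveCopyNumber(dc, 1000))
  expect_length(ev, 1L)
  expect_lte(ev[[1L]]$region[1L], 4e7 + 1e6)
  expect_gte(ev[[1L]]$region[2L], 4.15e7 - 1e6)
  # a run of independent deletions is not chromothripsis even when their
  # breakends cluster: the junction spans do not interleave and the
  # orientations are all of one category
  dc2 <- newGenome(1e8)
  starts <- seq(2e6, 2e6 + 19 * 2e5, by = 2e5)
  for (s in starts) dc2 <- applyDeletion(dc2, c(s, s + 5e4))
  expect_length(detectChromothripsis(deriveJunctions(dc2),
                                     deriveCopyNumber(dc2, 1000),
                                     classifierConfig(),
                                     minBreakpoints = 4L), 0L)
  # empty junction list
  expect_length(detectChromothripsis(JunctionSet(),
                                     deriveCopyNumber(dc2, 1000)), 0L)
})

test_that("raising the breakpoint threshold never adds calls", {
  cl <- simulateClone("rtel1_null", seed = 14)
  nCalls <- vapply(c(4L, 8L, 16L, 40L), function(mb)
    length(detectChromothripsis(cl$junctions, cl$cn, classifierConfig(),
                                minBreakpoints = mb)), integer(1))
  expect_true(all(diff(nCalls) <= 0))
})
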