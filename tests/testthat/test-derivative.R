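# Derivative-chromosome construction and the simple event operations,
# checked against the sequence-level oracle.

test_that("identity derivative has no junctions and flat copy number", {
  dc <- newGenome(1e6)
  expect_equal(derivativeLength(dc), 1e6)
  expect_equal(length(deriveJunctions(dc)), 0L)
  cn <- segments(deriveCopyNumber(dc))
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$cn, 2L)
  expect_error(newGenome(0), "positive")
  expect_error(newGenome(-5), "positive")
})

test_that("deletion shortens the derivative and leaves one RL junction", {
  dc <- applyDeletion(newGenome(1e3), c(100, 200))
  expect_equal(derivativeLength(dc), 900)
  j <- as.data.frame(deriveJunctions(dc))
  expect_equal(nrow(j), 1L)
  expect_equal(j$posA, 99)
  expect_equal(j$sideA, "R")
  expect_equal(j$posB, 200)
  expect_equal(j$sideB, "L")
  cn <- deriveCopyNumber(dc)
  expect_equal(cnPerBase(cn)[150], 1L)
  expect_equal(cnPerBase(cn)[50], 2L)
  # oracle agreement
  v <- seqDelete(seqNew(1e3), c(100, 200))
  expect_equal(as.data.frame(deriveJunctions(dc)),
               as.data.frame(seqJunctions(v)))
  expect_equal(cnPerBase(cn), seqCN(v, 1e3))
})

test_that("tandem duplication lengthens the derivative and gains CN", {
  dc <- applyTandemDuplication(newGenome(1e3), c(100, 200))
  expect_equal(derivativeLength(dc), 1100)
  j <- deriveJunctions(dc)
  expect_equal(classifyJunctions(j), "duplication_type")
  jd <- as.data.frame(j)
  expect_equal(jd$posA, 100); expect_equal(jd$sideA, "L")
  expect_equal(jd$posB, 199); expect_equal(jd$sideB, "R")
  expect_equal(cnPerBase(deriveCopyNumber(dc))[150], 3L)
  v <- seqTandem(seqNew(1e3), c(100, 200))
  expect_equal(jd, as.data.frame(seqJunctions(v)))
  expect_equal(cnPerBase(deriveCopyNumber(dc)), seqCN(v, 1e3))
})

test_that("inversion keeps length and CN and yields an HH/TT pair", {
  dc <- applyInversion(newGenome(1e3), c(100, 200))
  expect_equal(derivativeLength(dc), 1000)
  j <- as.data.frame(deriveJunctions(dc))
  expect_equal(nrow(j), 2L)
  expect_setequal(paste0(j$sideA, j$sideB), c("RR", "LL"))
  expect_equal(nrow(segments(deriveCopyNumber(dc))), 1L)
  v <- seqInvert(seqNew(1e3), c(100, 200))
  expect_equal(j, as.data.frame(seqJunctions(v)))
  # whole-chromosome inversion: both joins at ends, no junctions
  expect_equal(length(deriveJunctions(applyInversion(newGenome(1e3),
                                                     c(0, 1e3)))), 0L)
})

test_that("events are rejected outside forward-retained sequence", {
  dc <- applyDeletion(newGenome(1e3), c(100, 200))
  expect_error(applyDeletion(dc, c(120, 180)), "forward-retained")
  expect_error(applyDeletion(dc, c(50, 150)), "forward-retained")
  expect_error(applyDeletion(dc, c(900, 1100)), "out of bounds")
  inv <- applyInversion(newGenome(1e3), c(100, 200))
  expect_error(applyTandemDuplication(inv, c(120, 180)),
               "forward-retained")
})

test_that("length conservation holds across random event sequences", {
  set.seed(42)
  for (rep in 1:5) {
    L <- 1e5
    dc <- newGenome(L)
    v <- seqNew(L)
    expected <- L
    starts <- sort(sample(seq(0, L - 5000, by = 5000), 6))
    for (k in seq_along(starts)) {
      iv <- c(starts[k] + 1, starts[k] + sample(100:2000, 1))
      cls <- sample(c("del", "dup", "inv"), 1)
      if (cls == "del") {
        dc <- applyDeletion(dc, iv); v <- seqDelete(v, iv)
        expected <- expected - diff(iv)
      } else if (cls == "dup") {
        dc <- applyTandemDuplication(dc, iv); v <- seqTandem(v, iv)
        expected <- expected + diff(iv)
      } else {
        dc <- applyInversion(dc, iv); v <- seqInvert(v, iv)
      }
    }
    expect_equal(derivativeLength(dc), expected)
    expect_equal(derivativeLength(dc), length(v))
    expect_equal(as.data.frame(deriveJunctions(dc)),
                 as.data.frame(seqJunctions(v)))
    expect_equal(cnPerBase(deriveCopyNumber(dc)), seqCN(v, L))
  }
})

test_that("junction sets are canonical and deduplicated", {
  df <- data.frame(chromA = "chr1", posA = 500, sideA = "L",
                   chromB = "chr1", posB = 100, sideB = "R",
                   insertLen = 0)
  js <- JunctionSet(rbind(df, df))
  expect_equal(length(js), 1L)
  j <- as.data.frame(js)
  expect_true(j$posA <= j$posB)
  # row order of the input does not matter
  df2 <- data.frame(chromA = "chr1", posA = c(900, 100),
                    sideA = c("R", "R"), chromB = "chr1",
                    posB = c(950, 200), sideB = c("L", "L"),
                    insertLen = 0)
  expect_equal(as.data.frame(JunctionSet(df2)),
               as.data.frame(JunctionSet(df2[2:1, ])))
})
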