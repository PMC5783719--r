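# Junction typing and whole-sample classification.

test_that("junction geometry maps to the five intra-chromosomal types", {
  mk <- function(posA, sideA, posB, sideB, chromB = "chr1")
    JunctionSet(data.frame(chromA = "chr1", posA = posA, sideA = sideA,
                           chromB = chromB, posB = posB, sideB = sideB,
                           insertLen = 0))
  expect_equal(classifyJunctions(mk(99, "R", 200, "L")), "deletion_type")
  expect_equal(classifyJunctions(mk(100, "L", 199, "R")),
               "duplication_type")
  expect_equal(classifyJunctions(mk(1e5, "R", 2e5, "R")), "inversion_HH")
  expect_equal(classifyJunctions(mk(1e5, "L", 2e5, "L")), "inversion_TT")
  expect_equal(classifyJunctions(mk(1e5, "R", 1e5 + 50, "R")),
               "fold_back")
  expect_equal(classifyJunctions(mk(1e5, "L", 1e5 + 50, "L"),
                                 foldBackGap = 10), "inversion_TT")
  expect_equal(classifyJunctions(mk(1e5, "R", 2e5, "R", chromB = "chr2")),
               "interchromosomal")
})

test_that("wild-type clones classify into simple classes only", {
  for (s in c(2, 5, 8)) {
    cl <- simulateClone("wild_type", seed = s)
    rep <- classifySample(cl$junctions, cl$cn)
    expect_true(all(names(classCounts(rep)) %in%
                      c("deletion_type", "duplication_type", "inversion")))
    expect_length(rep@events, 0L)
  }
})

test_that("rtel1-null clones contain complex classes", {
  hits <- 0L
  for (s in 1:5) {
    cl <- simulateClone("rtel1_null", seed = s)
    rep <- classifySample(cl$junctions, cl$cn)
    if (any(names(classCounts(rep)) %in%
              c("bfb", "chromothripsis", "templated_insertion")))
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("every junction is assigned to exactly one class (partition)", {
  for (s in c(3, 4)) {
    cl <- simulateClone("rtel1_null", seed = s)
    rep <- classifySample(cl$junctions, cl$cn)
    expect_false(any(is.na(rep@assignment)))
    expect_equal(sum(classCounts(rep)), length(cl$junctions))
    # junctions supporting complex events are disjoint across events
    evj <- unlist(lapply(rep@events, function(e) e$junctions))
    expect_false(any(duplicated(evj)))
  }
})

test_that("classification is deterministic and counts are additive", {
  cl <- simulateClone("rtel1_null", seed = 6)
  r1 <- classifySample(cl$junctions, cl$cn)
  r2 <- classifySample(cl$junctions, cl$cn)
  expect_identical(r1@assignment, r2@assignment)
  # simple-class counts over a disjoint union of two samples add up
  a <- simulateClone("wild_type", seed = 10)
  b <- simulateClone("wild_type", seed = 20)
  ca <- classCounts(classifySample(a$junctions, a$cn))
  cb <- classCounts(classifySample(b$junctions, b$cn))
  merged <- JunctionSet(rbind(as.data.frame(a$junctions),
                              as.data.frame(b$junctions)))
  # same CN baseline for both wild-type clones; use a flat profile
  flat <- CNProfile(data.frame(start = 0, end = 1e8, cn = 2))
  cm <- classCounts(classifySample(merged, flat))
  for (k in union(names(ca), names(cb))) {
    expect_equal(unname(cm[k]),
                 sum(ca[names(ca) == k], cb[names(cb) == k]))
  }
})

test_that("seeded clone simulation is reproducible and honors profiles", {
  a <- simulateClone("rtel1_null", seed = 123)
  b <- simulateClone("rtel1_null", seed = 123)
  expect_identical(as.data.frame(a$junctions), as.data.frame(b$junctions))
  expect_identical(segments(a$cn), segments(b$cn))
  for (s in 1:5) {
    wt <- simulateClone("wild_type", seed = s)
    nEvents <- length(wt$events)
    expect_gte(nEvents, 8L); expect_lte(nEvents, 12L)
    expect_false(any(vapply(wt$events, function(e) e$eventClass, "")
                     %in% c("bfb", "chromothripsis",
                            "templated_insertion")))
    mt <- simulateClone("rtel1_null", seed = s)
    expect_gte(length(mt$events), 15L)
  }
})
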