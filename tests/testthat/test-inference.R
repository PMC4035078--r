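test_that("descents are located by linear scan", {
  expect_identical(descents(slatusBlockRanks()), 11L)
  expect_identical(descents(slatusBlockRanks(withTrnP = TRUE)), 11L)
  expect_identical(descents(1:10), integer(0))
  expect_identical(descents(c(3, 2, 1)), c(1L, 2L))
  expect_identical(descents(numeric(0)), integer(0))
})

test_that("two-increasing splits match the brute-force split oracle", {
  # frozen against bruteSplits(): [2,1,3,2] admits no split, [1,2,3] all four
  expect_identical(twoIncreasingSplit(c(2, 1, 3, 2)), integer(0))
  expect_identical(twoIncreasingSplit(1:3), 0:3)
  expect_identical(twoIncreasingSplit(slatusBlockRanks(withTrnP = TRUE)), 11L)
  set.seed(99)
  for (i in 1:50) {
    seq <- sample(20, sample(6, 1) + 1)
    expect_identical(as.integer(twoIncreasingSplit(seq)),
                     as.integer(unlist(bruteSplits(seq))))
  }
})

test_that("the stage-E order has a unique remnant-supported DRRL explanation", {
  co <- canonicalVertebrateOrder()
  ex <- explainDrrl(co, stageEOrder(), requireRemnants = TRUE)
  expect_length(ex, 1L)
  x <- ex[[1]]
  expect_identical(x@event@insertionEdge, c("trnQ", "trnM"))
  expect_identical(x@event@block, geneVocabulary()$label[9:37])
  expect_identical(x@splitPosition, 11L)
  expect_setequal(x@copy1, geneVocabulary()$label[slatusCopy1Idx])
  expect_true(x@remnantSupport)
  # without the remnant requirement the same explanation is still found
  exAll <- explainDrrl(co, stageEOrder())
  expect_true(explanationKeys(list(x)) %in% explanationKeys(exAll))
})

test_that("the identity order is trivially derivable at every edge", {
  co <- canonicalVertebrateOrder()
  ex <- explainDrrl(co, co)
  expect_true(length(ex) > 38L)
  edges <- unique(vapply(ex, function(x)
    paste(x@event@insertionEdge, collapse = ">"), character(1)))
  expect_length(edges, 38L)
  expect_false(any(vapply(ex, slot, TRUE, "remnantSupport")))
})

test_that("strand inversions are flagged, never silently explained", {
  co <- canonicalVertebrateOrder()
  el <- orderElements(co)
  el$strand[el$label == "trnW"] <- "L"
  flipped <- new("GeneOrder", elements = el, circular = TRUE)
  expect_warning(ex <- explainDrrl(co, flipped), "inversion.*trnW")
  expect_length(ex, 0L)
  expect_identical(attr(ex, "inversion"), "trnW")
  expect_warning(exT <- explainTdrl(co, flipped), "inversion")
  expect_length(exT, 0L)
})

test_that("gene-content mismatches are reported with the offending labels", {
  co <- canonicalVertebrateOrder()
  short <- geneElements(samariscusLatusOrder())
  el <- orderElements(short)
  short2 <- new("GeneOrder", elements = el[el$label != "trnD", ],
                circular = TRUE)
  expect_error(explainDrrl(co, short2), "missing.*trnD")
})

test_that("TDRL explanations exist for loss-resolved tandem arrays", {
  toy <- parseGeneOrder("g1 g2 g3 g4 g5 g6")
  obs <- parseGeneOrder("g1 g3 g5 g2 g4 g6")
  ex <- explainTdrl(toy, obs)
  expect_true(length(ex) >= 1L)
  full <- Filter(function(x) length(x@event@block) == 6L, ex)
  expect_true(any(vapply(full, function(x)
    setequal(x@copy1, c("g1", "g3", "g5")), TRUE)))
  # the stage-E gene arrangement is TDRL-explainable too, but with no
  # remnant support: TDRL cannot highlight the CR-separated clusters
  exE <- explainTdrl(canonicalVertebrateOrder(), stageEOrder())
  expect_true(length(exE) >= 1L)
  expect_false(any(vapply(exE, slot, TRUE, "remnantSupport")))
  # a full reversal is beyond one step
  expect_length(explainTdrl(parseGeneOrder("g1 g2 g3 g4"),
                            parseGeneOrder("g4 g3 g2 g1")), 0L)
})

test_that("recent duplications are reduced in both directions", {
  red <- reduceRecentDuplications(samariscusLatusOrder())
  expect_length(red, 2L)
  expect_identical(red[[1]]$segment, c("CR1", "trnC", "trnY"))
  expect_setequal(vapply(red, `[[`, "", "removed"), c("first", "second"))
  sizes <- vapply(red, function(r) length(r$order), integer(1))
  expect_identical(sizes, c(39L, 39L))
  # no repeats, no reductions
  expect_length(reduceRecentDuplications(canonicalVertebrateOrder()), 0L)
})

test_that("exactly one reduction of the observed order is one-step derivable", {
  co <- canonicalVertebrateOrder()
  red <- reduceRecentDuplications(samariscusLatusOrder())
  ex <- lapply(red, function(r) explainDrrl(co, r$order))
  derivable <- vapply(ex, length, integer(1)) > 0L
  expect_identical(sum(derivable), 1L)
  hit <- ex[derivable][[1]]
  expect_length(hit, 1L)
  expect_identical(hit[[1]]@event@insertionEdge, c("trnQ", "trnM"))
  # cluster sizes: 11 raw copy-1 survivors; copy 2 carries 17 + trnP
  expect_length(hit[[1]]@copy1, 11L)
  expect_length(hit[[1]]@copy2, 18L)
  expect_identical(hit[[1]]@copy2[18L], "trnP")
  # the derivable reduction is the one that removed the translocated copy
  expect_identical(red[[which(derivable)]]$removed, "second")
})

test_that("the brute-force oracle replays and recovers known events", {
  toy <- toyOrder(4)
  assign <- setNames(c("copy2", "copy1", "copy1"), c("g2", "g3", "g4"))
  res <- simulateDrrl(toy, c("g1", "g2"), assign)
  bf <- bruteForceExplanations(toy, res$order, maxBlock = 4)
  key <- paste("g1>g2", paste(sort(c("g3", "g4")), collapse = ","), sep = "|")
  expect_true(key %in% explanationKeys(bf))
  # an arrangement with three descents in every candidate block is
  # unreachable in one step
  unreachable <- parseGeneOrder("g1 g4 g2 g5 g3 CR")
  expect_length(bruteForceExplanations(toyOrder(5), unreachable, maxBlock = 5),
                0L)
  expect_length(explainDrrl(toyOrder(5), unreachable), 0L)
  expect_error(bruteForceExplanations(toy, res$order, maxBlock = 3),
               "exceeds maxBlock")
})

test_that("descent-based inference agrees with the brute-force oracle", {
  for (s in 1:40) {
    n <- 2 + (s %% 7)
    cs <- randomDrrlCase(n, 1000 + s)
    expect_identical(explanationKeys(explainDrrl(cs@ancestral, cs@derived)),
                     explanationKeys(bruteForceExplanations(cs@ancestral,
                                                            cs@derived,
                                                            maxBlock = n)))
  }
})

test_that("the six-stage reconstruction reaches the observed order", {
  st <- reconstructSlatus()
  expect_named(st, c("A", "B", "C", "D", "E", "F"))
  expect_true(orderIdentical(st$A, canonicalVertebrateOrder()))
  expect_length(st$B, 39L)
  expect_true(orderIdentical(st$C, st$B))
  expect_identical(length(attr(st, "event")@block), 29L)
  expect_identical(sum(orderElements(st$D)$class == "CR"), 3L)
  expect_true(orderIdentical(st$E, stageEOrder()))
  expect_true(orderIdentical(st$F, samariscusLatusOrder()))
})

test_that("reconstruction scars sit where the annotation shows residues", {
  scars <- slatusScars()
  look <- function(up, dn) scars[scars$upstream == up & scars$downstream == dn, ]
  expect_true(look("trnT", "trnM")$scarred)     # degenerated CRII, 86 bp
  expect_identical(look("trnT", "trnM")$nDeleted, 2L)
  expect_true(look("CR1", "trnC")$scarred)      # trnM..trnN copies lost
  expect_identical(look("CR1", "trnC")$nDeleted, 5L)
  expect_true(look("trnY'", "trnP")$scarred)    # inherited from trnL2|trnP
  expect_false(look("trnC", "trnY")$scarred)    # contiguous survivors
  expect_identical(look("trnC", "trnY")$nDeleted, 0L)
})
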