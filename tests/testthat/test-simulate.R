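test_that("segment duplication and translocation inserts a tagged copy", {
  co <- canonicalVertebrateOrder()
  b <- duplicateTranslocate(co, "CR", c("trnQ", "trnM"))
  tok <- orderTokens(b)
  expect_length(b, 39L)
  at <- match("trnQ", tok)
  expect_identical(tok[at + 1:2], c("CR'", "trnM"))
  expect_identical(tok[39], "CR")  # original untouched
  # multi-element segment
  e <- stageEOrder()
  f0 <- duplicateTranslocate(e, c("CR", "trnC", "trnY"), c("trnL2", "trnP"))
  tok2 <- orderTokens(f0)
  at2 <- match("trnL2", tok2)
  expect_identical(tok2[at2 + 1:3], c("CR'", "trnC'", "trnY'"))
  # degenerate placement right after the segment = tandem duplication
  toy <- toyOrder(4)
  td <- duplicateTranslocate(toy, c("g2", "g3"), c("g3", "g4"))
  expect_identical(orderTokens(td), c("g1", "g2", "g3", "g2'", "g3'", "g4", "CR"))
  # errors
  expect_error(duplicateTranslocate(toy, c("g2", "g3"), c("g2", "g3")),
               "inside the segment")
  expect_error(duplicateTranslocate(toy, "g2", c("g1", "g3")), "not adjacent")
  expect_error(duplicateTranslocate(toy, c("g2", "g4"), c("g1", "g2")),
               "not contiguous")
})

test_that("double replication duplicates the genes between the two origins", {
  co <- canonicalVertebrateOrder()
  b <- duplicateTranslocate(co, "CR", c("trnQ", "trnM"))
  st <- doubleReplication(b)
  expect_s4_class(st, "DuplicatedState")
  expect_identical(length(st@blockLabels), 29L)  # trnM .. trnP
  expect_identical(st@blockLabels[1], "trnM")
  expect_identical(st@blockLabels[29], "trnP")
  el <- orderElements(st)
  expect_identical(sum(el$class == "CR"), 3L)
  expect_length(st, 8L + 3L + 2L * 29L)
  # both copies keep the replication-order arrangement
  expect_identical(el$label[el$copy == "1"], st@blockLabels)
  expect_identical(el$label[el$copy == "2"], st@blockLabels)
  # upstream genes stay single-copy
  expect_identical(el$label[1:8], orderElements(co)$label[1:8])
})

test_that("double replication handles toy and degenerate configurations", {
  # hand-simulated 5-gene toy: origins after g2 -> block g3 g4 g5
  toy <- toyOrder(5)
  b <- duplicateTranslocate(toy, "CR", c("g2", "g3"))
  st <- doubleReplication(b)
  expect_identical(st@blockLabels, c("g3", "g4", "g5"))
  expect_identical(orderTokens(st),
                   c("g1", "g2", "CRI", "g31", "g41", "g51", "CRII",
                     "g32", "g42", "g52", "CRIII"))
  # empty block: CR copy inserted immediately before the original CR
  b0 <- duplicateTranslocate(toy, "CR", c("g5", "CR"))
  st0 <- doubleReplication(b0)
  expect_identical(length(st0@blockLabels), 0L)
  expect_identical(sum(orderElements(st0)$class == "CR"), 3L)
  # wrong CR multiplicity
  expect_error(doubleReplication(toy), "exactly 2 CRs")
  expect_error(doubleReplication(st), "exactly 2 CRs")
})

test_that("random loss resolves the S. latus assignment to the stage-E order", {
  co <- canonicalVertebrateOrder()
  st <- doubleReplication(duplicateTranslocate(co, "CR", c("trnQ", "trnM")))
  blockTok <- st@blockLabels
  v <- geneVocabulary()
  idx <- v$index[match(blockTok, v$label)]
  assign <- setNames(ifelse(idx %in% slatusCopy1Idx, "copy1", "copy2"),
                     blockTok)
  res <- randomLoss(st, assign)
  expect_true(orderIdentical(res$order, stageEOrder()))
  expect_identical(res$event@insertionEdge, c("trnQ", "trnM"))
  expect_identical(sum(res$event@lossAssignment == "copy1"), 11L)
})

test_that("identity losses undo the duplication", {
  toy <- toyOrder(5)
  b <- duplicateTranslocate(toy, "CR", c("g2", "g3"))
  st <- doubleReplication(b)
  all1 <- setNames(rep("copy1", 3), c("g3", "g4", "g5"))
  # keeping copy 1 plus a functional CRII (CRIII lost) restores the
  # two-CR configuration that preceded the replication
  back <- randomLoss(st, all1, crFates = c(CRI = "functional",
                                           CRII = "functional",
                                           CRIII = "lost"))$order
  expect_true(orderIdentical(back, b, ignoreCopy = TRUE))
  # keeping copy 2 with only CRIII surviving restores the single-CR order
  all2 <- setNames(rep("copy2", 3), c("g3", "g4", "g5"))
  back2 <- randomLoss(st, all2, crFates = c(CRI = "lost", CRII = "lost",
                                            CRIII = "functional"))$order
  expect_true(orderIdentical(back2, toy, ignoreCopy = TRUE))
})

test_that("random loss draws are seed-reproducible and validated", {
  toy <- toyOrder(6)
  st <- doubleReplication(duplicateTranslocate(toy, "CR", c("g2", "g3")))
  a <- randomLoss(st, seed = 42)
  b <- randomLoss(st, seed = 42)
  expect_true(orderIdentical(a$order, b$order))
  expect_identical(a$event@lossAssignment, b$event@lossAssignment)
  expect_error(randomLoss(st), "seed")
  expect_error(randomLoss(st, setNames("copy1", "g3")), "cover exactly")
  expect_error(randomLoss(st, setNames(rep("copy1", 4), c("g3", "g4", "g5", "g6")),
                          crFates = c(CRI = "remnant", CRII = "remnant",
                                      CRIII = "lost")),
               "functional")
})

test_that("a full DRRL event composes the three steps", {
  co <- canonicalVertebrateOrder()
  v <- geneVocabulary()
  blockLab <- v$label[9:37]
  assign <- setNames(ifelse(v$index[9:37] %in% slatusCopy1Idx,
                            "copy1", "copy2"), blockLab)
  res <- simulateDrrl(co, c("trnQ", "trnM"), assign)
  expect_true(orderIdentical(res$order, stageEOrder()))
  # all-copy-2 keeps the canonical gene arrangement, with both degenerated
  # CRs flanking the empty copy-1 slot
  all2 <- setNames(rep("copy2", 29), blockLab)
  res2 <- simulateDrrl(co, c("trnQ", "trnM"), all2)
  expect_true(orderIdentical(geneElements(res2$order), geneElements(co)))
  tok <- orderTokens(res2$order)
  at <- match("trnQ", tok)
  expect_identical(tok[at + 1:3], c("CR", "CRII-remnant", "trnM"))
  expect_identical(tok[length(tok)], "CRIII-remnant")
  expect_error(simulateDrrl(samariscusLatusOrder(), c("trnQ", "trnM"), all2),
               "exactly one CR")
})

test_that("DRRL output preserves gene content, strands and cluster structure", {
  v <- geneVocabulary()
  for (s in 1:25) {
    n <- 3 + (s %% 8)
    cs <- randomDrrlCase(n, s)
    anc <- orderElements(cs@ancestral)
    der <- orderElements(cs@derived)
    ancG <- anc[anc$class != "CR", ]
    derG <- der[der$class %in% c("tRNA", "rRNA", "CDS"), ]
    # content conservation: each ancestral gene exactly once
    expect_setequal(derG$label, ancG$label)
    expect_identical(nrow(derG), nrow(ancG))
    # strand preservation
    expect_identical(setNames(derG$strand, derG$label)[ancG$label],
                     setNames(ancG$strand, ancG$label))
    # cluster structure: block genes form two runs, each increasing in
    # ancestral rank, with the CRII remnant between them
    ev <- cs@event
    tok <- orderTokens(cs@derived)
    surv1 <- names(ev@lossAssignment)[ev@lossAssignment == "copy1"]
    surv2 <- names(ev@lossAssignment)[ev@lossAssignment == "copy2"]
    rank1 <- match(surv1, ev@block)
    rank2 <- match(surv2, ev@block)
    expect_true(all(diff(rank1) > 0) && all(diff(rank2) > 0))
    pos <- match(c(surv1, "CRII-remnant", surv2, "CRIII-remnant"), tok)
    expect_false(anyNA(pos))
    expect_identical(pos, sort(pos))  # copy1 run, remnant, copy2 run, remnant
  }
})

test_that("TDRL resolves a tandem array by the loss assignment", {
  toy <- parseGeneOrder("g1 g2 g3 g4 g5 g6")
  keep <- setNames(c("copy1", "copy2", "copy1", "copy2", "copy1", "copy2"),
                   paste0("g", 1:6))
  res <- simulateTdrl(toy, paste0("g", 1:6), keep)
  expect_identical(orderTokens(canonicalRotation(res$order)),
                   c("g1", "g3", "g5", "g2", "g4", "g6"))
  # all copy-1 is the identity
  all1 <- setNames(rep("copy1", 6), paste0("g", 1:6))
  expect_true(orderIdentical(simulateTdrl(toy, paste0("g", 1:6), all1)$order,
                             toy))
  # a single-element block is the identity for either choice
  for (w in c("copy1", "copy2")) {
    one <- simulateTdrl(toy, "g3", setNames(w, "g3"))$order
    expect_true(orderIdentical(one, toy))
  }
  expect_error(simulateTdrl(toy, paste0("g", 1:6), all1[1:3]), "cover exactly")
  expect_error(simulateTdrl(toy, c("g1", "g3"), NULL, seed = 1),
               "not contiguous")
  # strand preservation on a mixed-strand block
  q <- parseGeneOrder("trnI trnQ trnM ND2")
  res2 <- simulateTdrl(q, c("trnI", "trnQ", "trnM"),
                       setNames(c("copy2", "copy1", "copy2"),
                                c("trnI", "trnQ", "trnM")))
  el <- orderElements(res2$order)
  expect_identical(el$strand[el$label == "trnQ"], "L")
})
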