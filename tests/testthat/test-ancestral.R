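test_that("a star tree of identical tips needs zero events", {
  tr <- ape::read.tree(text = "(A,B,C,D);")
  tips <- setNames(notoGeneOrders(rep("Noto1GO", 4)), c("A", "B", "C", "D"))
  rec <- reconstructAncestral(tr, tips)
  expect_identical(rec@totalCost, 0)
  expect_identical(totalEventCount(rec)$total, 0L)
  expect_identical(nrow(detectHomoplasy(rec)), 0L)
})

test_that("Sankoff total cost equals exhaustive assignment enumeration", {
  trees <- c("((A,B),(C,D));", "(((A,B),C),(D,E));",
             "((A,(B,C)),((D,E),F));")
  tipSets <- list(
    c(A = "VertGO", B = "Noto1GO", C = "Noto2GO", D = "VertGO"),
    c(A = "Noto1GO", B = "DissoGO", C = "VertGO", D = "Noto2GO",
      E = "Noto3GO"),
    c(A = "VertGO", B = "Noto1GO", C = "Noto1GO", D = "Noto3GO",
      E = "Noto2GO", F = "VertGO"))
  for (k in seq_along(trees)) {
    tr <- ape::read.tree(text = trees[k])
    tips <- setNames(notoGeneOrders(unname(tipSets[[k]])),
                     names(tipSets[[k]]))
    rec <- reconstructAncestral(tr, tips)
    oracle <- bruteMinCost(tr, tipSets[[k]], rec@distances)
    expect_identical(rec@totalCost, oracle)
  }
})

test_that("a deeper candidate pool never increases the minimal cost", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tips <- setNames(notoGeneOrders(c("VertGO", "Noto1GO", "DissoGO",
                                    "VertGO")), c("A", "B", "C", "D"))
  r1 <- reconstructAncestral(tr, tips, poolDepth = 1L)
  r2 <- reconstructAncestral(tr, tips, poolDepth = 2L)
  expect_lte(r2@totalCost, r1@totalCost)
})

test_that("homoplasy detection flags planted convergent origins only", {
  tr <- ape::read.tree(text = "(((A,B),(C,D)),E);")
  tips <- setNames(notoGeneOrders(c("Noto1GO", "VertGO", "Noto1GO",
                                    "VertGO", "VertGO")),
                   c("A", "B", "C", "D", "E"))
  rec <- reconstructAncestral(tr, tips)
  hp <- detectHomoplasy(rec)
  expect_true("Noto1GO" %in% hp$state)
  expect_gte(hp$nOrigins[hp$state == "Noto1GO"], 2L)
  ## single origin: the same derived order on one clade only
  tips2 <- setNames(notoGeneOrders(c("Noto1GO", "Noto1GO", "VertGO",
                                     "VertGO", "VertGO")),
                    c("A", "B", "C", "D", "E"))
  rec2 <- reconstructAncestral(tr, tips2)
  expect_identical(nrow(detectHomoplasy(rec2)), 0L)
})

test_that("tip placement can change the reconstruction, and is detected", {
  tips <- setNames(notoGeneOrders(c("Noto1GO", "Noto1GO", "VertGO",
                                    "VertGO", "VertGO")),
                   c("X", "Y", "Z", "W", "O"))
  together <- ape::read.tree(text = "(((X,Y),(Z,W)),O);")
  apart <- ape::read.tree(text = "(((X,Z),(Y,W)),O);")
  cmp <- compareTopologies(together, apart, tips)
  expect_false(cmp$identicalPathways)
  expect_lt(cmp$assignmentA@totalCost, cmp$assignmentB@totalCost)
  ## identical trees give identical assignments
  cmpSame <- compareTopologies(together, together, tips)
  expect_true(cmpSame$identicalPathways)
})

test_that("the alternative basal placement leaves the pathways unchanged", {
  cmp <- compareTopologies(notoReferenceTree(),
                           notoReferenceTree(alternative = TRUE),
                           notoTipOrders(),
                           extraStates = notoGeneOrders("TremaIntGO"))
  expect_true(cmp$identicalPathways)
})

test_that("missing tip assignments are reported by name", {
  tr <- ape::read.tree(text = "((A,B),C);")
  tips <- setNames(notoGeneOrders(c("VertGO", "VertGO")), c("A", "B"))
  expect_error(reconstructAncestral(tr, tips), "C")
})
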