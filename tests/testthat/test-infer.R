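test_that("identical orders yield one empty path of cost zero", {
  v <- notoGeneOrders("VertGO")[[1]]
  p <- inferEvents(v, v)
  expect_length(p, 1L)
  expect_identical(p[[1]]@cost, 0)
  expect_length(p[[1]]@events, 0L)
  expect_identical(eventDistance(v, v), 0L)
})

test_that("every returned path replays to the target", {
  go <- notoGeneOrders()
  prs <- list(c("VertGO", "Noto1GO"), c("Noto1GO", "DissoGO"),
              c("Noto3GO", "Noto2GO"), c("TremaIntGO", "TremaGO"))
  for (pr in prs) {
    paths <- inferEvents(go[[pr[1]]], go[[pr[2]]], maxDepth = 2)
    expect_gt(length(paths), 0)
    for (p in paths) {
      cur <- go[[pr[1]]]
      for (ev in p@events) cur <- applyEvent(cur, ev)
      expect_true(ordersEqual(cur, go[[pr[2]]]))
    }
  }
  ## replay validation is enforced on construction
  expect_error(newEventPath(go$VertGO, go$Noto1GO, list()), "replay")
})

test_that("search cost matches brute-force enumeration on toy orders", {
  ## restricted model shared with the oracle: inversions, transpositions,
  ## prl, tdrl with duplicated blocks of <= 3 elements
  model <- eventModel(kinds = c("inversion", "transposition", "prl",
                                "tdrl"), maxDup = 3L)
  set.seed(31)
  nAgree <- 0L
  for (r in 1:12) {
    src <- randomToyOrder(5)
    ## scramble with 1-2 random oracle moves so distances are small
    labs <- orderLabels(src); signs <- orderSigns(src)
    mv <- oracleMoves(labs, signs, maxDup = 3L)
    for (k in seq_len(sample(2, 1))) {
      m <- mv[[sample(length(mv), 1)]]
      r2 <- m(labs, signs); labs <- r2$l; signs <- r2$s
    }
    tgt <- geneOrder(labs, signs)
    dOracle <- oracleDistance(src, tgt, maxDepth = 2L, maxDup = 3L)
    dExh <- eventDistance(src, tgt, model, maxDepth = 2L,
                          mode = "exhaustive", region = NULL)
    dGui <- eventDistance(src, tgt, model, maxDepth = 2L,
                          mode = "auto", region = NULL)
    expect_identical(dExh, dOracle)
    expect_identical(dGui, dOracle)
    nAgree <- nAgree + 1L
  }
  expect_identical(nAgree, 12L)
})

test_that("distance is symmetric under the invertible-event model", {
  model <- eventModel(kinds = c("inversion", "transposition",
                                "inverse_transposition"))
  set.seed(41)
  for (r in 1:6) {
    a <- randomToyOrder(6)
    b <- randomToyOrder(6)
    dab <- eventDistance(a, b, model, maxDepth = 2L, region = NULL)
    dba <- eventDistance(b, a, model, maxDepth = 2L, region = NULL)
    expect_identical(dab, dba)
  }
})

test_that("unreachable targets return NA and tiny caps raise a truncation error", {
  go <- notoGeneOrders()
  expect_true(is.na(eventDistance(go$VertGO, go$TremaGO, maxDepth = 1L)))
  expect_error(
    inferEvents(go$VertGO, go$Noto1GO, maxDepth = 1L,
                mode = "exhaustive", searchCap = 10L),
    "cap exceeded")
})

test_that("co-minimal paths are ordered deterministically", {
  go <- notoGeneOrders()
  p1 <- inferEvents(go$Noto1GO, go$Noto3GO)
  p2 <- inferEvents(go$Noto1GO, go$Noto3GO)
  expect_identical(lapply(p1, function(p) lapply(p@events, function(e)
    list(e@kind, e@seg, e@drop))),
    lapply(p2, function(p) lapply(p@events, function(e)
      list(e@kind, e@seg, e@drop))))
})

test_that("region restriction confines the search to the hot spot", {
  go <- notoGeneOrders()
  p <- inferEvents(go$VertGO, go$Noto1GO, region = c("nad5", "F"))
  expect_gt(length(p), 0)
  expect_identical(p[[1]]@cost, 1)
  ## the Trematominae inversion crosses trnF into the IQM region and is
  ## invisible to a search confined between nad5 and F
  pTrema <- inferEvents(go$TremaIntGO, go$TremaGO, maxDepth = 1L,
                        region = c("nad5", "F"))
  expect_length(pTrema, 0L)
  pWide <- inferEvents(go$TremaIntGO, go$TremaGO, maxDepth = 1L,
                       region = c("nad5", "M"))
  expect_gt(length(pWide), 0)
})
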