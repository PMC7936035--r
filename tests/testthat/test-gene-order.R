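test_that("canonicalization is a normal form over rotations and readings", {
  go <- notoGeneOrders()
  v <- go$VertGO
  n <- length(orderLabels(v))
  set.seed(11)
  for (r in 1:6) {
    k <- sample(n, 1)
    rot <- geneOrder(c(orderLabels(v)[k:n], orderLabels(v)[seq_len(k - 1)]),
                     c(orderSigns(v)[k:n], orderSigns(v)[seq_len(k - 1)]))
    expect_true(ordersEqual(rot, v))
    mir <- geneOrder(rev(c(orderLabels(v)[k:n],
                           orderLabels(v)[seq_len(k - 1)])),
                     -rev(c(orderSigns(v)[k:n],
                            orderSigns(v)[seq_len(k - 1)])))
    expect_true(ordersEqual(mir, v))
  }
  ## idempotence
  expect_identical(formatGeneOrder(canonicalizeOrder(v)),
                   formatGeneOrder(v))
  ## property over random toy orders: all 2n readings agree
  for (rep in 1:10) {
    o <- randomToyOrder(6)
    key <- formatGeneOrder(o)
    labs <- orderLabels(o); signs <- orderSigns(o)
    for (k in seq_along(labs)) {
      rl <- c(labs[k:6], labs[seq_len(k - 1)])
      rs <- c(signs[k:6], signs[seq_len(k - 1)])
      expect_identical(formatGeneOrder(geneOrder(rl, rs)), key)
      expect_identical(formatGeneOrder(geneOrder(rev(rl), -rev(rs))), key)
    }
  }
})

test_that("missing cox1 errors unless a fallback start is configured", {
  expect_error(geneOrder(c("nad1", "rrnS"), c(1, 1)), "cox1")
  o <- geneOrder(c("nad1", "rrnS"), c(1, 1), fallbackStart = "rrnS")
  expect_identical(orderLabels(o)[1], "rrnS")
  expect_true(isTRUE(o@meta$partial))
})

test_that("copy tags follow traversal order: letters for genes, numbers for CoRe", {
  n1 <- notoGeneOrders("Noto1GO")[[1]]
  tg <- copyTags(n1)
  labs <- orderLabels(n1)
  expect_identical(tg[labs == "T"], c("a", "b"))
  expect_identical(tg[labs == "CoRe"], c("1", "2"))
  expect_true(all(tg[labs == "cox1"] == ""))
  ## notation round trip keeps tags
  s <- formatGeneOrder(n1)
  expect_match(s, "T\\(a\\)")
  expect_true(ordersEqual(geneOrder(s), n1))
})

test_that("order equality ignores rotation and input copy tags", {
  go <- notoGeneOrders()
  expect_false(ordersEqual(go$Noto2GO, go$Noto3GO))  # CoRe1 presence
  ## tags in the input notation are reassigned, not trusted
  a <- geneOrder("cox1,T(b),-P,T(a),nad5")
  b <- geneOrder("cox1,T,-P,T,nad5")
  expect_true(ordersEqual(a, b))
})

test_that("distinct order census finds the eight Nototheniidae arrangements", {
  go <- notoGeneOrders()
  tips <- notoTipOrders()
  fam <- notoFamilyTips()
  census <- distinctOrders(setNames(go[tips[fam]], fam))
  expect_identical(census$count, 8L)
  ## n copies of one order -> 1 class
  expect_identical(distinctOrders(rep(go["VertGO"], 5))$count, 1L)
  ## randomized toy orders, distinct by construction
  set.seed(5)
  toys <- list()
  keys <- character()
  while (length(toys) < 6) {
    o <- randomToyOrder(6)
    k <- formatGeneOrder(o)
    if (!k %in% keys) { keys <- c(keys, k); toys[[length(toys) + 1]] <- o }
  }
  expect_identical(distinctOrders(toys)$count, 6L)
})

test_that("fixture gene orders are mutually distinct", {
  go <- notoGeneOrders()
  census <- distinctOrders(go)
  expect_identical(census$count, length(go))
})

test_that("region slices reproduce the hot-spot layouts", {
  go <- notoGeneOrders()
  sV <- regionSlice(go$VertGO, "nad5", "F")
  expect_identical(formatGeneOrder(sV, tags = FALSE),
                   "nad5,-nad6,-E,cob,T,-P,CoRe,F")
  s1 <- regionSlice(go$Noto1GO, "nad5", "F")
  expect_identical(
    formatGeneOrder(s1),
    "nad5,T(a),-P(a),CoRe(1),-nad6,-E,cob,T(b),-P(b),CoRe(2),F")
  ## single-element slice
  sx <- regionSlice(go$VertGO, "cob", "cob")
  expect_identical(orderLabels(sx), "cob")
  expect_error(regionSlice(go$VertGO, "nad5", "nope"), "absent")
  ## slices of the named orders are mutually distinct
  slices <- lapply(go[c("VertGO", "Noto1GO", "Noto2GO", "Noto3GO",
                        "DissoGO", "TremaIntGO")],
                   function(o) formatGeneOrder(regionSlice(o, "nad5", "F")))
  expect_identical(anyDuplicated(unlist(slices)), 0L)
})

test_that("gene orders are extracted from annotated genomes", {
  cfg <- simConfig(3, geneScale = 0.2)
  anc <- simulateAncestor(cfg)
  g <- assembleGenome(anc)
  expect_true(ordersEqual(extractGeneOrder(g),
                          notoGeneOrders("VertGO")[[1]]))
  ## planted inversion is recovered from the annotation
  v <- simGeneOrder(anc)
  ev <- rearrangementEvent("inversion", segment = c("CoRe", "CoRe"),
                           order = v)
  sim2 <- mitoRearr:::.applySimEvent(anc, ev)
  o2 <- extractGeneOrder(assembleGenome(sim2))
  expect_true(ordersEqual(o2, applyEvent(v, ev)))
  ## partial genome missing cox1 uses the fallback start
  f <- genomeFeatures(g)
  f2 <- f[f$label != "cox1", ]
  f2$start <- f2$start - min(f2$start)
  g2 <- annotatedGenome("partial", genomeSequence(g), f2,
                        completeness = "partial",
                        checkTranslation = FALSE)
  o3 <- extractGeneOrder(g2, fallbackStart = "rrnS")
  expect_true(isTRUE(o3@meta$partial))
})
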