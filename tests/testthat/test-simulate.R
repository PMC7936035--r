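test_that("the simulated ancestor is a valid VertGO genome", {
  cfg <- simConfig(101, geneScale = 0.25)
  anc <- simulateAncestor(cfg)
  g <- assembleGenome(anc)
  expect_identical(nrow(genomeFeatures(g)), 39L)
  expect_true(ordersEqual(extractGeneOrder(g),
                          notoGeneOrders("VertGO")[[1]]))
  ## protein-coding genes translate without internal stops
  f <- genomeFeatures(g)
  for (r in which(f$type == "PCG")) {
    aa <- mitoRearr:::.translate2(featureSequence(g, r))
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  ## seeded determinism
  g2 <- assembleGenome(simulateAncestor(cfg))
  expect_identical(genomeSequence(g2), genomeSequence(g))
  ## at full scale the genome is in the typical mitogenome size range
  gf <- assembleGenome(simulateAncestor(simConfig(101)))
  expect_gt(genomeLength(gf), 15000)
  expect_lt(genomeLength(gf), 18500)
})

test_that("zero-length branches leave tips identical to the ancestor", {
  cfg <- simConfig(102, geneScale = 0.15)
  anc <- simulateAncestor(cfg)
  tr <- ape::read.tree(text = "(A:0,B:0);")
  res <- evolveOnTree(anc, tr, config = cfg)
  expect_identical(genomeSequence(res$genomes$A),
                   genomeSequence(assembleGenome(anc)))
  expect_identical(genomeSequence(res$genomes$B),
                   genomeSequence(res$genomes$A))
})

test_that("the scripted pathway to the Trematominae arrangement replays", {
  cfg <- simConfig(103, geneScale = 0.2)
  anc <- simulateAncestor(cfg)
  v <- simGeneOrder(anc)
  tdprl <- rearrangementEvent("tdrl", segment = c("nad6", "CoRe"),
      order = v,
      keep = rbind(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), rep(TRUE, 6)))
  noto1 <- applyEvent(v, tdprl)
  prl <- rearrangementEvent("prl", drop = c("CoRe(1)", "T(b)", "P(b)"),
                            order = noto1)
  intermediate <- applyEvent(noto1, prl)
  inv <- rearrangementEvent("inversion", segment = c("CoRe", "I"),
                            order = intermediate)
  tr <- ape::read.tree(text = "((A:0.02,B:0.02):0.02,C:0.04);")
  stem <- paste0("node", ape::getMRCA(tr, c("A", "B")))
  res <- evolveOnTree(anc, tr,
      events = setNames(list(list(tdprl), list(prl, inv)),
                        c(stem, "A")), config = cfg)
  expect_true(ordersEqual(extractGeneOrder(res$genomes$A),
                          notoGeneOrders("TremaGO")[[1]]))
  expect_true(ordersEqual(extractGeneOrder(res$genomes$B),
                          notoGeneOrders("Noto1GO")[[1]]))
  expect_true(ordersEqual(extractGeneOrder(res$genomes$C),
                          notoGeneOrders("VertGO")[[1]]))
  ## truth-log replay: every emitted genome equals its logged order
  for (nm in names(res$genomes))
    expect_true(ordersEqual(extractGeneOrder(res$genomes[[nm]]),
                            res$truth$nodeOrders[[nm]]))
  ## scripts on absent branches are rejected
  expect_error(evolveOnTree(anc, tr, events = list(nope = list(prl)),
                            config = cfg), "absent branch")
})

test_that("undecayed remnants align to their source gene at full identity", {
  cfg <- simConfig(104, geneScale = 0.3, remnantDecay = 0,
                   remnantDeletion = 0)
  anc <- simulateAncestor(cfg)
  v <- simGeneOrder(anc)
  tdprl <- rearrangementEvent("tdrl", segment = c("nad6", "CoRe"),
      order = v,
      keep = rbind(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), rep(TRUE, 6)))
  tr <- ape::read.tree(text = "(A:0,B:0);")
  res <- evolveOnTree(anc, tr, events = list(A = list(tdprl)),
                      config = cfg)
  cls <- classifySpacers(res$genomes["A"])
  gr <- cls[cls$class == "GR_ISP", ]
  expect_gt(nrow(gr), 0)
  expect_true(all(gr$identity == 100))
})

test_that("null spacers are reproducible with the requested composition", {
  expect_identical(makeNullSpacers(0, 50), character())
  s1 <- makeNullSpacers(20, 100, seed = 9)
  s2 <- makeNullSpacers(20, 100, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(nchar(s1) == 100L))
  gc <- mean(vapply(strsplit(paste(s1, collapse = ""), "")[[1]],
                    function(b) b %in% c("G", "C"), logical(1)))
  expect_lt(abs(gc - 0.5), 0.05)  # binomial tolerance at n = 2000
})

test_that("sampled planted events stay inside the hot spot and change the order", {
  v <- notoGeneOrders("VertGO")[[1]]
  set.seed(31)
  for (r in 1:20) {
    ev <- samplePlantedEvent(v)
    out <- applyEvent(v, ev)
    expect_false(ordersEqual(out, v))
    ## the arrangement outside nad5..M is untouched
    pre <- regionSlice(out, "cox1", "nad5")
    expect_identical(orderLabels(pre)[1:16],
                     orderLabels(regionSlice(v, "cox1", "nad5"))[1:16])
  }
})
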