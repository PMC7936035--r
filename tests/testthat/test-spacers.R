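## deterministic toy: a genome with controllable gaps between features
gapGenome <- function(gaps, seed = 7) {
  set.seed(seed)
  mkseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  labs <- c("cox1", "S2", "D", "cox2")
  lens <- c(90L, 60L, 60L, 90L)
  pos <- 0L; rows <- list(); parts <- character()
  for (i in seq_along(labs)) {
    rows[[i]] <- data.frame(label = labs[i], strand = "H", start = pos,
                            end = pos + lens[i], type = "tRNA",
                            stringsAsFactors = FALSE)
    parts <- c(parts, mkseq(lens[i]))
    pos <- pos + lens[i]
    if (gaps[i] > 0L) { parts <- c(parts, mkseq(gaps[i])); pos <- pos + gaps[i] }
  }
  annotatedGenome("gap", paste(parts, collapse = ""),
                  do.call(rbind, rows), checkTranslation = FALSE)
}

test_that("contiguous annotations yield no spacers; gaps are found with flanks", {
  g0 <- gapGenome(c(0L, 0L, 0L, 0L))
  expect_identical(nrow(extractSpacers(g0)), 0L)
  g1 <- gapGenome(c(0L, 60L, 0L, 0L))
  sp <- extractSpacers(g1)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$flank_upstream, "S2")
  expect_identical(sp$flank_downstream, "D")
  expect_identical(sp$length, 60L)
  expect_identical(nchar(sp$sequence), 60L)
  ## sub-threshold gaps are ignored
  g2 <- gapGenome(c(0L, 5L, 0L, 0L))
  expect_identical(nrow(extractSpacers(g2)), 0L)
})

test_that("a spacer spanning the origin is extracted with wrapped coordinates", {
  g <- gapGenome(c(0L, 0L, 0L, 50L))  # gap after the last feature wraps
  sp <- extractSpacers(g)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$flank_upstream, "cox2")
  expect_identical(sp$flank_downstream, "cox1")
  expect_identical(sp$length, 50L)
  expect_identical(nchar(sp$sequence), 50L)
})

test_that("planted gene remnants are detected, including on the opposite strand", {
  cfg <- simConfig(11, geneScale = 0.3)
  anc <- simulateAncestor(cfg)
  g <- assembleGenome(anc)
  lib <- spacerGeneLibrary(g)
  cob <- lib[["cob"]]
  rem <- substr(cob, nchar(cob) - 33L, nchar(cob))  # 34 nt of the 3' end
  hits <- scanSpacer(paste0(makeNullSpacers(1, 30, seed = 2), rem,
                            makeNullSpacers(1, 30, seed = 3)), lib)
  expect_gt(nrow(hits), 0)
  top <- hits[1, ]
  expect_identical(top$target, "cob")
  expect_identical(top$strand, "H")
  expect_identical(top$identity, 100)
  expect_gte(top$alignLength, 34L)
  expect_identical(top$targetRegion, "3prime")
  ## reverse-complement remnant -> strand L
  hitsL <- scanSpacer(paste0(makeNullSpacers(1, 30, seed = 4),
                             mitoRearr:::.revcomp(rem)), lib)
  expect_identical(hitsL$target[1], "cob")
  expect_identical(hitsL$strand[1], "L")
  expect_error(scanSpacer("ACGT", character()), "empty")
})

test_that("the translated remnant matches the protein C-terminus in frame", {
  cfg <- simConfig(12, geneScale = 0.3)
  g <- assembleGenome(simulateAncestor(cfg))
  lib <- spacerGeneLibrary(g)
  cob <- lib[["cob"]]
  ## 34 nt ending 3 nt before the stop: remnant of the coding 3' end
  rem <- substr(cob, nchar(cob) - 36L, nchar(cob) - 3L)
  spacer <- paste0(makeNullSpacers(1, 25, seed = 5), rem)
  hits <- scanSpacer(spacer, lib)
  top <- as.list(hits[hits$target == "cob", ][1, ])
  pc <- peptideCheck(spacer, top, cob)
  expect_identical(pc$identicalRun, nchar(pc$peptideRemnant))
  expect_gte(pc$identicalRun, 34L %/% 3L - 1L)
  expect_identical(pc$peptideRemnant, pc$peptideGene)
  ## one nonsynonymous change splits the identical run
  rem2 <- rem
  substr(rem2, 17, 17) <- if (substr(rem2, 17, 17) == "C") "G" else "C"
  spacer2 <- paste0(makeNullSpacers(1, 25, seed = 6), rem2)
  hits2 <- scanSpacer(spacer2, lib)
  if (nrow(hits2) && any(hits2$target == "cob")) {
    top2 <- as.list(hits2[hits2$target == "cob", ][1, ])
    pc2 <- peptideCheck(spacer2, top2, cob)
    expect_lte(pc2$identicalRun, pc$identicalRun)
  }
})

test_that("spacers classify as GR-ISP with pathway corroboration or STD-ISP", {
  cfg <- simConfig(13, geneScale = 0.3)
  anc <- simulateAncestor(cfg)
  v <- simGeneOrder(anc)
  tdprl <- rearrangementEvent("tdrl", segment = c("nad6", "CoRe"),
      order = v,
      keep = rbind(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE), rep(TRUE, 6)))
  tr <- ape::read.tree(text = "(A:0.02,B:0.02);")
  res <- evolveOnTree(anc, tr, events = list(A = list(tdprl)),
                      config = cfg)
  paths <- list(newEventPath(notoGeneOrders("VertGO")[[1]],
                             notoGeneOrders("Noto1GO")[[1]],
                             list(tdprl), 1))
  cls <- classifySpacers(res$genomes["A"], paths = paths)
  gr <- cls[cls$class == "GR_ISP", ]
  expect_gt(nrow(gr), 0)
  expect_true(any(gr$target == "cob"))
  expect_true(any(grepl("VertGO->Noto1GO",
                        gr$corroborates[gr$target == "cob"])))
  ## a random spacer stays STD-ISP
  g2 <- gapGenome(c(0L, 80L, 0L, 0L), seed = 29)
  cls2 <- classifySpacers(list(g2), minGeneLength = 50L)
  expect_true(all(cls2$class == "STD_ISP"))
})

test_that("self-alignment of a gene region is the top-scoring library hit", {
  g <- assembleGenome(simulateAncestor(simConfig(14, geneScale = 0.3)))
  lib <- spacerGeneLibrary(g)
  frag <- substr(lib[["nad4"]], 50, 120)
  hits <- scanSpacer(frag, lib)
  expect_identical(hits$target[1], "nad4")
})
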