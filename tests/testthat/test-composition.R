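test_that("skew formulas and complement antisymmetry hold", {
  expect_identical(skewReport("TTAA")$AT_skew, 0)
  expect_identical(skewReport("AAAT")$AT_skew, 0.5)
  expect_true(skewReport("NNNN")$undefined)
  set.seed(13)
  for (r in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(skewReport(rc)$AT_skew, -skewReport(s)$AT_skew)
    expect_equal(skewReport(rc)$GC_skew, -skewReport(s)$GC_skew)
    expect_true(abs(skewReport(s)$AT_skew) <= 1)
    expect_true(abs(skewReport(s)$GC_skew) <= 1)
  }
})

test_that("codon position partitions sum to the full gene counts", {
  g <- assembleGenome(simulateAncestor(simConfig(4, geneScale = 0.15)))
  tab <- perGeneSkewTable(list(g))
  full <- tab[tab$partition == "full" & tab$unit == "cox1", ]
  pos <- tab[tab$partition %in% c("pos1", "pos2", "pos3") &
             tab$unit == "cox1", ]
  for (b in c("nA", "nC", "nG", "nT"))
    expect_identical(sum(pos[[b]]), full[[b]])
  ## one row per genome x unit x partition; no rows for absent genes
  expect_false("nad99" %in% tab$unit)
  expect_identical(sum(tab$unit == "cox1"), 4L)  # full + 3 positions
})

test_that("degeneracy classification matches an independent code-table oracle", {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  got <- classifyCodonDegeneracy(all64)
  want <- vapply(all64, oracleDegeneracy, character(1))
  expect_identical(got, unname(want))
  ## spot checks from the code table
  expect_identical(classifyCodonDegeneracy("CTC"), "NNN4")  # Leu CTN
  expect_identical(classifyCodonDegeneracy("AAA"), "NNR2")  # Lys AAR
  expect_identical(classifyCodonDegeneracy("TGA"), "NNR2")  # Trp TGR
  expect_identical(classifyCodonDegeneracy("AGA"), "other") # stop
  expect_identical(classifyCodonDegeneracy("AXA"), "other") # ambiguous
})

test_that("degenerate-site pools match a hand count and honor exclusions", {
  ## toy gene CTA,CTG,AAA: NNN4 third positions {A,G}; 2-fold pool {A}
  seq <- "CTACTGAAA"
  f <- data.frame(label = "nad2", strand = "H", start = 0L, end = 9L,
                  type = "PCG", stringsAsFactors = FALSE)
  g <- annotatedGenome("toy", seq, f, checkTranslation = FALSE)
  ds <- extractDegenerateSets(g, exclude = character())
  expect_identical(ds$NNN4, c(A = 1L, C = 0L, G = 1L, T = 0L))
  expect_identical(ds$NNR2_NNY2, c(A = 1L, C = 0L, G = 0L, T = 0L))
  ## excluding the gene removes exactly its codons
  ds2 <- extractDegenerateSets(g, exclude = "nad2")
  expect_identical(sum(ds2$NNN4) + sum(ds2$NNR2_NNY2), 0L)
  expect_warning(extractDegenerateSets(g, exclude = "nad4"), "absent")
  ## automatic exclusion drops strand-translocated genes
  f3 <- f; f3$strand <- "L"
  g3 <- annotatedGenome("flip", seq, f3, checkTranslation = FALSE)
  ds3 <- extractDegenerateSets(g3)
  expect_identical(ds3$excluded, "nad2")
})

test_that("strand symmetry z-test behaves at the extremes and at the null", {
  r <- strandSymmetryTest(c(A = 500L, C = 10L, G = 10L, T = 500L))
  expect_identical(r$statistic[r$comparison == "A_vs_T"], 0)
  expect_identical(r$p_value[r$comparison == "A_vs_T"], 1)
  r2 <- strandSymmetryTest(c(A = 100L, C = 50L, G = 50L, T = 0L))
  expect_equal(r2$statistic[r2$comparison == "A_vs_T"], 10)
  expect_true(r2$rejected_at_0.05[r2$comparison == "A_vs_T"])
  expect_true(strandSymmetryTest(c(A = 3L, C = 2L, G = 1L,
                                   T = 2L))$low_power[1])
})

test_that("group skew comparison is Student's t on absolute values", {
  a <- c(0.5, 0.52, 0.48); b <- c(-0.5, -0.52, -0.48)
  r <- compareSkewGroups(a, b)
  expect_equal(r$p_value, 1)       # equal |skew|
  expect_equal(r$statistic, 0)
  set.seed(17)
  x <- rnorm(8, 0.4, 0.05); y <- rnorm(9, 0.2, 0.05)
  r2 <- compareSkewGroups(x, y)
  tt <- t.test(abs(x), abs(y), var.equal = TRUE)
  expect_equal(r2$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(r2$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_error(compareSkewGroups(1, c(1, 2)), "n >= 2")
})

test_that("reversal decisions separate the three simulated scenarios", {
  r <- simulateReversalScenario("none", seed = 5)
  expect_identical(r$decision$decision, "none")
  r <- simulateReversalScenario("partial", seed = 5)
  expect_identical(r$decision$decision, "partial")
  ## Trematominae-like pattern: AT skews flipped, GC skews not
  ev <- r$decision$evidence
  expect_true(all(ev$opposite[ev$skew == "AT"]))
  expect_false(any(ev$opposite[ev$class == "NNN4" & ev$skew == "GC"]))
  r <- simulateReversalScenario("full", seed = 5)
  expect_identical(r$decision$decision, "full")
  expect_true(all(r$decision$evidence$opposite))
  expect_true(all(r$decision$evidence$rejected))
})
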