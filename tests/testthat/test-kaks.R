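test_that("identical sequences give zero distances and no ratio", {
  r <- pairwiseKaKs("TTACGATGA", "TTACGATGA")
  expect_identical(r$Ka, 0); expect_identical(r$Ks, 0)
  expect_true(is.na(r$ratio))
})

test_that("a single synonymous difference yields Ka = 0, Ks > 0", {
  ## Leu TTA -> TTG in a context of conserved codons
  a <- "TTACGACGACGACGA"; b <- "TTGCGACGACGACGA"
  r <- pairwiseKaKs(a, b)
  expect_identical(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_identical(r$Nd, 0)
  expect_equal(r$Sd, 1)
})

test_that("Ka/Ks matches the independent path-enumeration oracle", {
  set.seed(23)
  code <- oracleMitoCode()
  cods <- names(code)[code != "*"]
  for (rep in 1:6) {
    a <- paste(sample(cods, 30, TRUE), collapse = "")
    ## derive b by mutating a few positions
    b <- mutateSequence(a, 0.08, seed = rep)
    r <- pairwiseKaKs(a, b)
    o <- oracleNG86(a, b)
    expect_equal(r$S, o$S, tolerance = 1e-9)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
    if (!is.na(o$Ks)) expect_equal(r$Ks, o$Ks, tolerance = 1e-9)
    if (!is.na(o$Ka)) expect_equal(r$Ka, o$Ka, tolerance = 1e-9)
    ## symmetry
    r2 <- pairwiseKaKs(b, a)
    expect_equal(r$Ka, r2$Ka, tolerance = 1e-12)
    expect_equal(r$Ks, r2$Ks, tolerance = 1e-12)
  }
})

test_that("saturation and malformed input are flagged", {
  expect_error(pairwiseKaKs("TTA", "TTAA"), "equal length")
  expect_error(pairwiseKaKs("TTAA", "TTAC"), "multiple of 3")
  ## a wildly divergent pair saturates
  r <- pairwiseKaKs("TTA", "GGC")
  expect_true(r$saturated)
})

test_that("codons with gaps or ambiguity are dropped pairwise", {
  r <- pairwiseKaKs("TTANNNCGA", "TTGAAACGA")
  expect_identical(r$nCodons, 2L)   # middle codon dropped
})

test_that("distribution summaries follow the box-plot conventions", {
  aln <- list(cox1 = c(a = "TTACGACTT", b = "TTGCGACTT",
                       c = "TTACGGCTT"))
  d <- kaksDistribution(aln)
  expect_identical(d$complex, "IV")
  ## one defined pair -> median = mean = that value
  one <- list(atp8 = c(x = "TTAAAACGA", y = "TTACAACGA"))
  d1 <- kaksDistribution(one)
  expect_equal(d1$median, d1$mean)
  ## all-identical genomes -> empty distribution, undefined count reported
  same <- list(cob = c(x = "TTACGA", y = "TTACGA", z = "TTACGA"))
  d2 <- kaksDistribution(same)
  expect_identical(d2$n, 0L)
  expect_identical(d2$nUndefined, 3L)
  ## ordering by OXPHOS complex
  multi <- list(atp8 = one$atp8, cob = c(x = "TTACGA", y = "CTACGA"),
                nad2 = c(x = "TTACGA", y = "TTACGG"))
  dm <- kaksDistribution(multi)
  expect_identical(dm$complex, c("I", "III", "V"))
})
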