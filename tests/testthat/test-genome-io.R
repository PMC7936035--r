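## build a small annotated toy genome in code
toyGenome <- function(id = "toy") {
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE,
                      prob = c(.3, .3, .2, .2)), collapse = "")
  f <- data.frame(
    label = c("cox1", "S2", "D", "rrnS"),
    strand = c("H", "L", "H", "H"),
    start = c(0L, 120L, 200L, 300L),
    end = c(120L, 190L, 290L, 380L),
    type = c("PCG", "tRNA", "tRNA", "rRNA"),
    stringsAsFactors = FALSE)
  annotatedGenome(id, seq, f, checkTranslation = FALSE)
}

test_that("TSV feature tables round-trip bit-exactly", {
  g <- toyGenome()
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fa")
  writeFeatureTable(g, tsv, fa)
  g2 <- suppressWarnings(
    readFeatureTable(tsv, "tsv", fasta = fa, identifier = "toy"))
  expect_identical(genomeFeatures(g2), genomeFeatures(g))
  expect_identical(genomeSequence(g2), genomeSequence(g))
  ## and a full simulated genome round-trips too
  sim <- assembleGenome(simulateAncestor(simConfig(2, geneScale = 0.15)))
  writeFeatureTable(sim, tsv, fa)
  back <- readFeatureTable(tsv, "tsv", fasta = fa,
                           identifier = sim@identifier)
  expect_identical(genomeFeatures(back), genomeFeatures(sim))
  expect_true(ordersEqual(extractGeneOrder(back), extractGeneOrder(sim)))
})

test_that("heterogeneous labels are normalized through the synonym map", {
  out <- suppressWarnings(normalizeLabels(
    c("ND6", "CYTB", "D-loop", "tRNA-Leu(UUR)", "COIII", "12S rRNA",
      "tRNA-Ser(AGY)", "mystery")))
  expect_identical(out[1:7],
                   c("nad6", "cob", "CoRe", "L2", "cox3", "rrnS", "S1"))
  expect_identical(out[8], "mystery")
  expect_warning(normalizeLabels("mystery"), "unknown")
  expect_true(attr(suppressWarnings(normalizeLabels("mystery")),
                   "unknown"))
})

test_that("origin-spanning features wrap modulo the genome length", {
  seq <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")  # 100 bp
  f <- data.frame(label = c("cox1", "CoRe"), strand = c("H", "H"),
                  start = c(10L, 80L), end = c(60L, 110L),
                  type = c("PCG", "control_region"),
                  stringsAsFactors = FALSE)
  g <- annotatedGenome("wrap", seq, f, checkTranslation = FALSE)
  s <- featureSequence(g, "CoRe")
  expect_identical(nchar(s), 30L)  # wrapped length = end - start
  expect_identical(s, paste0(substr(seq, 81, 100), substr(seq, 1, 10)))
})

test_that("malformed coordinates and duplicate features are rejected", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("label\tstrand\tstart\tend\ttype",
               "cox1\tH\t0\tnot_a_number\tPCG"), tsv)
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(c(x = "ACGT")), fa)
  expect_error(suppressWarnings(readFeatureTable(tsv, "tsv", fasta = fa)),
               "coordinates")
  f <- data.frame(label = c("cox1", "cox1"), strand = c("H", "H"),
                  start = c(0L, 0L), end = c(9L, 9L),
                  type = c("PCG", "PCG"), stringsAsFactors = FALSE)
  expect_error(annotatedGenome("dup", "ACGTACGTAC", f,
                               checkTranslation = FALSE), "duplicate")
})

test_that("a minimal GenBank flat file parses with normalized labels", {
  gb <- c(
    "LOCUS       TOY01 120 bp DNA circular",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..30",
    "                     /gene=\"ND6\"",
    "     tRNA            complement(31..60)",
    "                     /product=\"tRNA-Glu\"",
    "     D-loop          61..100",
    "     rRNA            101..120",
    "                     /product=\"12S ribosomal RNA\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac",
    "       51 gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "      101 acgtacgtac gtacgtacgt",
    "//")
  path <- tempfile(fileext = ".gb")
  writeLines(gb, path)
  g <- suppressWarnings(readFeatureTable(path, "genbank_flat"))
  f <- genomeFeatures(g)
  expect_identical(g@identifier, "TOY01")
  expect_identical(nchar(genomeSequence(g)), 120L)
  expect_identical(f$label, c("nad6", "E", "CoRe", "rrnS"))
  expect_identical(f$strand, c("H", "L", "H", "H"))
  ## 1-based closed -> 0-based half-open is lossless
  expect_identical(f$start, c(0L, 30L, 60L, 100L))
  expect_identical(f$end, c(30L, 60L, 100L, 120L))
  expect_identical(f$type,
                   c("PCG", "tRNA", "control_region", "rRNA"))
})

test_that("newick reading validates tips, rooting and duplicates", {
  tr <- readNewickTree("((A,B),C);")
  expect_identical(ape::Ntip(tr), 3L)
  expect_true(ape::is.rooted(tr))
  ## round trip preserves topology
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  tr2 <- readNewickTree(path)
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr))
  expect_error(readNewickTree("((A,B),C);", genomeIds = c("A", "B")),
               "C")
  expect_error(readNewickTree("(A,B,C);"), "unrooted")
  tru <- readNewickTree("(A,B,C);", outgroup = "C")
  expect_true(ape::is.rooted(tru))
})

test_that("report serialization is loss-free, headers included for empty tables", {
  tab <- data.frame(gene = c("cox1", "cob"), value = c(1.5, -2),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  writeReport(tab, path, "tsv")
  back <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_identical(back, tab)
  empty <- tab[0, ]
  writeReport(empty, path, "tsv")
  expect_identical(readLines(path), "gene\tvalue")
  ## nested event path -> JSON with an event list
  go <- notoGeneOrders()
  p <- inferEvents(go$Noto1GO, go$DissoGO)[[1]]
  jf <- tempfile(fileext = ".json")
  writeReport(eventPathRecord(p), jf, "json")
  parsed <- jsonlite::read_json(jf)
  expect_identical(parsed$cost, 1L)
  expect_identical(parsed$events[[1]]$kind, "PRL")
})
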