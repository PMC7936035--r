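## package-level memoization cache
.mitoCache <- new.env(parent = emptyenv())
.mitoCache$tdrl <- list()

## reverse complement for plain character DNA
.revcomp <- function(x) {
    chartr("ACGTN", "TGCAN",
           vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""), character(1),
                  USE.NAMES = FALSE))
}

## split a DNA string into codons (drops an incomplete trailing codon)
.codons <- function(seq) {
    n <- nchar(seq) %/% 3L
    if (n == 0L) return(character())
    substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

## vertebrate mitochondrial genetic code (translation table 2),
## as a named character vector codon -> amino acid ('*' = stop)
.mitoCode <- function() {
    code <- .mitoCache$mitoCode
    if (is.null(code)) {
        gc <- Biostrings::getGeneticCode("2")
        code <- setNames(as.character(gc), names(gc))
        .mitoCache$mitoCode <- code
    }
    code
}

## translate an in-frame character DNA string under table 2
.translate2 <- function(seq) {
    cods <- .codons(seq)
    aa <- .mitoCode()[cods]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}
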