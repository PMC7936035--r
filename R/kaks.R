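## Pairwise Ka/Ks by the Nei-Gojobori (1986) method under the vertebrate
## mitochondrial code, with Jukes-Cantor correction, plus distribution
## summaries grouped by OXPHOS complex.

## per-codon synonymous site counts under code table 2; mutations to
## stop codons count as nonsynonymous sites
.ngSites <- function() {
    S <- .mitoCache$ngSites
    if (!is.null(S)) return(S)
    code <- .mitoCode()
    bases <- c("A", "C", "G", "T")
    S <- setNames(numeric(64L), names(code))
    for (cod in names(code)) {
        if (code[[cod]] == "*") { S[[cod]] <- NA_real_; next }
        s <- 0
        for (p in 1:3) {
            ref <- substr(cod, p, p)
            for (b in setdiff(bases, ref)) {
                alt <- cod
                substr(alt, p, p) <- b
                if (code[[alt]] != "*" && code[[alt]] == code[[cod]])
                    s <- s + 1 / 3
            }
        }
        S[[cod]] <- s
    }
    .mitoCache$ngSites <- S
    S
}

## synonymous/nonsynonymous difference counts between two codons,
## averaged over all substitution paths that avoid stop codons (all
## paths if every path passes through a stop); memoized
.ngDiffs <- function(codA, codB) {
    key <- paste0(codA, codB)
    hit <- .mitoCache$ngDiffs[[key]]
    if (!is.null(hit)) return(hit)
    code <- .mitoCode()
    pos <- which(strsplit(codA, "")[[1]] != strsplit(codB, "")[[1]])
    perms <- if (length(pos) <= 1L) list(pos) else {
        pm <- list()
        permute <- function(v, acc) {
            if (!length(v)) { pm[[length(pm) + 1L]] <<- acc; return() }
            for (i in seq_along(v)) permute(v[-i], c(acc, v[i]))
        }
        permute(pos, integer())
        pm
    }
    walk <- function(ord) {
        cur <- codA; sd <- 0; nd <- 0; okStop <- TRUE
        for (p in ord) {
            nxt <- cur
            substr(nxt, p, p) <- substr(codB, p, p)
            if (code[[nxt]] == "*") okStop <- FALSE
            if (code[[cur]] != "*" && code[[nxt]] != "*" &&
                code[[cur]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
            cur <- nxt
        }
        c(sd = sd, nd = nd, ok = as.numeric(okStop))
    }
    res <- vapply(perms, walk, numeric(3))
    use <- res["ok", ] == 1
    if (!any(use)) use <- rep(TRUE, ncol(res))
    out <- c(sd = mean(res["sd", use]), nd = mean(res["nd", use]))
    if (is.null(.mitoCache$ngDiffs)) .mitoCache$ngDiffs <- list()
    .mitoCache$ngDiffs[[key]] <- out
    out
}

#' Pairwise Ka/Ks (Nei-Gojobori 1986, Jukes-Cantor corrected)
#'
#' Counts synonymous and nonsynonymous sites and differences per codon
#' under the vertebrate mitochondrial code, averaging multiple-hit
#' codons over all minimal substitution paths (paths through stop codons
#' are excluded when avoidable), then applies the Jukes-Cantor
#' correction d = -3/4 log(1 - 4p/3) to the proportions. Codons
#' containing gaps, ambiguity characters or stop codons in either
#' sequence are dropped pairwise.
#'
#' @param seqA,seqB in-frame codon sequences of equal length.
#' @param gene optional gene label carried into the result.
#' @param ids optional length-2 identifier vector.
#' @return list (class \code{KaKsResult}) with Ka, Ks, ratio (NA when
#'   Ks = 0), pS, pN, sites and counts, and a \code{saturated} flag
#'   (proportion >= 0.75, distance undefined).
#' @export
#' @examples
#' pairwiseKaKs("TTACGA", "TTGCGA")$Ks > 0  # one synonymous change
pairwiseKaKs <- function(seqA, seqB, gene = NA_character_,
                         ids = c(NA_character_, NA_character_)) {
    a <- toupper(seqA); b <- toupper(seqB)
    if (nchar(a) != nchar(b)) stop("sequences must have equal length")
    if (nchar(a) %% 3L != 0L) stop("length must be a multiple of 3")
    ca <- .codons(a); cb <- .codons(b)
    code <- .mitoCode()
    ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
    ok <- ok & code[ca] != "*" & code[cb] != "*"
    ok[is.na(ok)] <- FALSE
    ca <- ca[ok]; cb <- cb[ok]
    sites <- .ngSites()
    S <- sum((sites[ca] + sites[cb]) / 2)
    N <- 3 * length(ca) - S
    Sd <- 0; Nd <- 0
    diffIdx <- which(ca != cb)
    for (i in diffIdx) {
        d <- .ngDiffs(ca[i], cb[i])
        Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    }
    pS <- if (S > 0) Sd / S else NA_real_
    pN <- if (N > 0) Nd / N else NA_real_
    jc <- function(p) {
        if (is.na(p)) return(NA_real_)
        if (p >= 0.75) return(NA_real_)
        -3 / 4 * log(1 - 4 * p / 3)
    }
    Ks <- jc(pS); Ka <- jc(pN)
    saturated <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
    ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
    structure(list(gene = gene, ids = ids, Ka = Ka, Ks = Ks,
                   ratio = ratio, pS = pS, pN = pN, S = S, N = N,
                   Sd = Sd, Nd = Nd, nCodons = length(ca),
                   saturated = saturated),
              class = "KaKsResult")
}

#' All-pairs Ka/Ks table for a gene alignment
#'
#' @param seqs named character vector of equal-length in-frame sequences
#'   (a codon alignment).
#' @param gene gene label.
#' @return data.frame with one row per unordered pair.
#' @export
kaksPairTable <- function(seqs, gene = NA_character_) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- as.character(seq_along(seqs))
    if (length(seqs) < 2L) stop("need >= 2 sequences")
    prs <- combn(seq_along(seqs), 2)
    rows <- lapply(seq_len(ncol(prs)), function(k) {
        i <- prs[1, k]; j <- prs[2, k]
        r <- pairwiseKaKs(seqs[[i]], seqs[[j]], gene, c(ids[i], ids[j]))
        data.frame(gene = gene, idA = ids[i], idB = ids[j], Ka = r$Ka,
                   Ks = r$Ks, ratio = r$ratio, saturated = r$saturated,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Distribution summary of pairwise Ka/Ks ratios per gene
#'
#' Box-plot style summary (median, mean, quartiles, whiskers at 1.5x the
#' interquartile range, outliers beyond them) of all pairwise ratios per
#' gene, ordered by OXPHOS complex. Pairs with undefined ratio (Ks = 0
#' or saturated) are excluded and counted.
#'
#' @param geneAlignments named list (gene -> named character vector of
#'   aligned sequences).
#' @return data.frame ordered by complex then gene.
#' @export
kaksDistribution <- function(geneAlignments) {
    cmap <- oxphosComplexMap()
    rows <- list()
    for (gene in names(geneAlignments)) {
        tab <- kaksPairTable(geneAlignments[[gene]], gene)
        v <- tab$ratio[!is.na(tab$ratio)]
        nUndef <- sum(is.na(tab$ratio))
        if (length(v)) {
            q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
            iqr <- q[3] - q[1]
            lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
            rows[[gene]] <- data.frame(
                gene = gene, complex = unname(cmap[gene]),
                n = length(v), nUndefined = nUndef,
                median = q[2], mean = mean(v), q1 = q[1], q3 = q[3],
                whiskerLow = min(v[v >= lo]), whiskerHigh = max(v[v <= hi]),
                nOutliers = sum(v < lo | v > hi),
                stringsAsFactors = FALSE)
        } else {
            rows[[gene]] <- data.frame(
                gene = gene, complex = unname(cmap[gene]),
                n = 0L, nUndefined = nUndef, median = NA_real_,
                mean = NA_real_, q1 = NA_real_, q3 = NA_real_,
                whiskerLow = NA_real_, whiskerHigh = NA_real_,
                nOutliers = 0L, stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out <- out[order(factor(out$complex, levels = c("I", "III", "IV", "V")),
                     out$gene), ]
    rownames(out) <- NULL
    out
}
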