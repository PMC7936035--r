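## Intergenic spacer extraction and gene-remnant scanning: local
## (Smith-Waterman) alignment of each spacer against the genome's own
## gene library, STD-ISP vs GR-ISP classification, and the translated
## peptide check for protein-coding remnants.

#' Default spacer-scan thresholds
#'
#' A hit supports a rearrangement-derived spacer (GR-ISP) when the local
#' alignment spans >= \code{minLen} nt at >= \code{minIdentity} percent
#' identity AND reaches a raw score of >= \code{minScore} (match +2,
#' mismatch -3), OR contains an exact match of >= \code{minExact} nt.
#' The score term carries the statistical weight: identity/length alone
#' admit the short 70-80 percent-identity stretches that optimal local
#' alignment finds between any two random sequences. The defaults are
#' calibrated on simulated random-composition null spacers scanned
#' against a full mitogenome gene library so that the false-positive
#' rate stays at or below 1 percent, while every remnant of >= 20 nt
#' with <= 10 percent divergence is detected (such a remnant always
#' attains score >= 30 or an 18 nt exact run). Strongly biased spacer
#' composition inflates the null tail; raise \code{minScore} when
#' scanning extreme-composition material.
#'
#' @param minLen minimum alignment length (nt).
#' @param minIdentity minimum percent identity.
#' @param minScore minimum raw alignment score.
#' @param minExact minimum exact-run length (nt).
#' @return list of thresholds.
#' @export
spacerThresholds <- function(minLen = 15L, minIdentity = 70,
                             minScore = 30, minExact = 18L) {
    list(minLen = as.integer(minLen), minIdentity = minIdentity,
         minScore = minScore, minExact = as.integer(minExact))
}

#' Extract intergenic spacers from an annotated genome
#'
#' All gaps between consecutive features (circular: including the wrap
#' gap between the last and the first feature) of at least
#' \code{minLength} nt. Overlapping features yield no spacer. Flank
#' labels carry copy tags when the flanking gene is duplicated.
#'
#' @param genome AnnotatedGenome.
#' @param minLength minimum spacer length (default 10 nt).
#' @return data.frame: genome, flank_upstream, flank_downstream, start,
#'   end (0-based half-open, circular), length, sequence.
#' @export
extractSpacers <- function(genome, minLength = 10L) {
    f <- genome@features
    L <- nchar(genome@sequence)
    n <- nrow(f)
    if (n < 2L)
        return(data.frame(genome = character(), flank_upstream = character(),
                          flank_downstream = character(), start = integer(),
                          end = integer(), length = integer(),
                          sequence = character(), stringsAsFactors = FALSE))
    tags <- .goTags(f$label)
    labT <- ifelse(nzchar(tags), paste0(f$label, "(", tags, ")"), f$label)
    rows <- list()
    ends <- pmin(f$end, L + f$start * 0)   # effective linear end
    for (i in seq_len(n)) {
        j <- if (i < n) i + 1L else 1L
        gapStart <- f$end[i]
        gapEnd <- if (i < n) f$start[j] else f$start[j] + L
        ## an origin-spanning feature's end already exceeds L
        len <- gapEnd - gapStart
        if (len < minLength) next
        s <- gapStart %% L
        e <- s + len
        seq <- if (e <= L) substr(genome@sequence, s + 1L, e)
               else paste0(substr(genome@sequence, s + 1L, L),
                           substr(genome@sequence, 1L, e - L))
        rows[[length(rows) + 1L]] <- data.frame(
            genome = genome@identifier, flank_upstream = labT[i],
            flank_downstream = labT[j], start = s, end = e,
            length = len, sequence = seq, stringsAsFactors = FALSE)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(genome = character(), flank_upstream = character(),
                   flank_downstream = character(), start = integer(),
                   end = integer(), length = integer(),
                   sequence = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Build the scannable gene library of a genome
#'
#' All annotated features as sense-strand sequences; the Control Region
#' is included (CoRe remnants are key rearrangement evidence). The
#' scanner itself searches both strands.
#'
#' @param genome AnnotatedGenome.
#' @param minGeneLength drop features shorter than this (default 40 nt,
#'   skips tRNAs whose remnants are too short to call reliably; set to 0
#'   to scan against everything).
#' @return named character vector label -> sequence.
#' @export
spacerGeneLibrary <- function(genome, minGeneLength = 40L) {
    f <- genome@features
    tags <- .goTags(f$label)
    labT <- ifelse(nzchar(tags), paste0(f$label, "(", tags, ")"), f$label)
    seqs <- vapply(seq_len(nrow(f)), function(r)
        featureSequence(genome, r), character(1))
    keep <- nchar(seqs) >= minGeneLength
    setNames(seqs[keep], labT[keep])
}

## BLASTN-like scoring: match +2, mismatch -3, gap open 5, gap extend 2
.spacerSubstMat <- function() {
    m <- .mitoCache$substMat
    if (is.null(m)) {
        bases <- c("A", "C", "G", "T")
        m <- matrix(-3, 4, 4, dimnames = list(bases, bases))
        diag(m) <- 2
        .mitoCache$substMat <- m
    }
    m
}

#' Scan one spacer against a gene library
#'
#' Smith-Waterman local alignment (match +2, mismatch -3, gap open -5,
#' gap extend -2) of the spacer against every library entry on both
#' strands; hits passing the thresholds are returned sorted by score.
#'
#' @param spacerSeq spacer sequence (character).
#' @param library named character vector from [spacerGeneLibrary()].
#' @param thresholds list from [spacerThresholds()].
#' @return data.frame: target, strand (H: gene sense / L: reverse
#'   complement), score, alignLength, identity (percent), exactRun (nt),
#'   spacerStart/spacerEnd and targetStart/targetEnd (1-based within
#'   spacer/gene sense), targetRegion ("5prime"/"internal"/"3prime").
#' @export
scanSpacer <- function(spacerSeq, library, thresholds = spacerThresholds()) {
    if (!length(library)) stop("empty gene library")
    sub <- .spacerSubstMat()
    pat <- Biostrings::DNAString(spacerSeq)
    rows <- list()
    for (strand in c("H", "L")) {
        libseq <- if (strand == "H") library else
            setNames(.revcomp(library), names(library))
        aln <- Biostrings::pairwiseAlignment(
            Biostrings::DNAStringSet(libseq), pat,
            type = "local", substitutionMatrix = sub,
            gapOpening = 5, gapExtension = 2)
        sc <- Biostrings::score(aln)
        lens <- Biostrings::nchar(aln)
        pids <- Biostrings::pid(aln)
        ## a perfect run of minExact nt scores 2*minExact: alignments
        ## below both routes cannot pass and are skipped unexamined
        cand <- which((lens >= thresholds$minLen &
                       pids >= thresholds$minIdentity &
                       sc >= thresholds$minScore) |
                      sc >= 2 * thresholds$minExact)
        for (k in cand) {
            a <- aln[k]
            alnLen <- lens[k]
            if (alnLen == 0L) next
            pid <- pids[k]
            pv <- strsplit(as.character(
                Biostrings::alignedPattern(a)[[1]]), "")[[1]]
            sv <- strsplit(as.character(
                Biostrings::alignedSubject(a)[[1]]), "")[[1]]
            rl <- rle(pv == sv & pv != "-")
            best <- if (any(rl$values)) max(rl$lengths[rl$values]) else 0L
            pass <- (alnLen >= thresholds$minLen &&
                     pid >= thresholds$minIdentity &&
                     sc[k] >= thresholds$minScore) ||
                    best >= thresholds$minExact
            if (!pass) next
            gLen <- nchar(library[[k]])
            tS <- Biostrings::start(Biostrings::pattern(a))
            tE <- Biostrings::end(Biostrings::pattern(a))
            if (strand == "L") { tmp <- tS; tS <- gLen - tE + 1L
                                 tE <- gLen - tmp + 1L }
            region <- if (tE > 2 * gLen / 3) "3prime"
                      else if (tS <= gLen / 3) "5prime" else "internal"
            rows[[length(rows) + 1L]] <- data.frame(
                target = names(libseq)[k], strand = strand,
                score = sc[k], alignLength = alnLen, identity = pid,
                exactRun = best,
                spacerStart = Biostrings::start(Biostrings::subject(a)),
                spacerEnd = Biostrings::end(Biostrings::subject(a)),
                targetStart = tS, targetEnd = tE,
                targetRegion = region, stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(target = character(), strand = character(),
                   score = numeric(), alignLength = integer(),
                   identity = numeric(), exactRun = integer(),
                   spacerStart = integer(), spacerEnd = integer(),
                   targetStart = integer(), targetEnd = integer(),
                   targetRegion = character(), stringsAsFactors = FALSE)
    out <- out[order(-out$score), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Translated-peptide check of a protein-coding remnant hit
#'
#' Translates the matched spacer segment in the frame implied by the hit
#' coordinates within the target gene (vertebrate mitochondrial code)
#' and reports the longest identical amino-acid run against the
#' corresponding protein segment. Only meaningful for PCG targets.
#'
#' @param spacerSeq spacer sequence.
#' @param hit one row of a [scanSpacer()] result (list or data.frame row).
#' @param geneSeq the target gene's sense sequence.
#' @return list with \code{peptideRemnant}, \code{peptideGene},
#'   \code{identicalRun} (aa), \code{frameOffset}; or NULL with a
#'   warning when the frame cannot be determined.
#' @export
peptideCheck <- function(spacerSeq, hit, geneSeq) {
    tS <- hit$targetStart
    if (is.na(tS)) { warning("frame undeterminable"); return(NULL) }
    frameOff <- (tS - 1L) %% 3L
    segment <- substr(spacerSeq, hit$spacerStart, hit$spacerEnd)
    if (hit$strand == "L") segment <- .revcomp(segment)
    ## trim to the first full codon of the gene's reading frame
    trim <- (3L - frameOff) %% 3L
    segment <- substr(segment, trim + 1L, nchar(segment))
    gStart <- tS + trim
    gSeg <- substr(geneSeq, gStart, gStart + nchar(segment) - 1L)
    n3 <- (nchar(segment) %/% 3L) * 3L
    if (n3 < 3L) return(list(peptideRemnant = "", peptideGene = "",
                             identicalRun = 0L, frameOffset = frameOff))
    aaR <- .translate2(substr(segment, 1L, n3))
    aaG <- .translate2(substr(gSeg, 1L, n3))
    rv <- strsplit(aaR, "")[[1]]; gv <- strsplit(aaG, "")[[1]]
    run <- 0L; best <- 0L
    for (z in seq_along(rv)) {
        if (rv[z] == gv[z]) { run <- run + 1L; if (run > best) best <- run }
        else run <- 0L
    }
    list(peptideRemnant = aaR, peptideGene = aaG, identicalRun = best,
         frameOffset = frameOff)
}

#' Classify all spacers of a genome set as STD-ISP or GR-ISP
#'
#' A spacer is GR-ISP (rearrangement-derived) iff at least one library
#' hit passes the thresholds; otherwise STD-ISP (slippage-derived).
#' When an [AncestralAssignment-class] (or a list of EventPaths) is
#' supplied, each GR-ISP is cross-referenced against the rearrangement
#' pathways: it corroborates an event path if its remnant's target gene
#' is among the elements that the path duplicates and loses.
#'
#' @param genomes list of AnnotatedGenome.
#' @param thresholds list from [spacerThresholds()].
#' @param minLength minimum spacer length.
#' @param paths optional list of [EventPath-class] for corroboration.
#' @param minGeneLength passed to [spacerGeneLibrary()].
#' @return data.frame: one row per spacer with class, top hit fields and
#'   \code{corroborates} (semicolon-joined path labels or "").
#' @export
classifySpacers <- function(genomes, thresholds = spacerThresholds(),
                            minLength = 10L, paths = NULL,
                            minGeneLength = 40L) {
    lostByPath <- list()
    if (!is.null(paths)) {
        for (p in paths) {
            lab <- paste0(if (!is.na(p@source@name)) p@source@name else "?",
                          "->", if (!is.na(p@target@name)) p@target@name
                          else "?")
            lost <- character()
            cur <- canonicalizeOrder(p@source)
            for (ev in p@events) {
                if (ev@kind %in% c("prl", "loss"))
                    lost <- c(lost, orderLabels(cur)[ev@drop])
                if (ev@kind == "tdrl") {
                    segLabs <- orderLabels(cur)[ev@seg[1]:ev@seg[2]]
                    lost <- c(lost,
                              segLabs[colSums(ev@keep) < nrow(ev@keep)])
                }
                cur <- applyEvent(cur, ev)
            }
            lostByPath[[lab]] <- unique(lost)
        }
    }
    rows <- list()
    for (g in genomes) {
        sp <- extractSpacers(g, minLength)
        if (!nrow(sp)) next
        lib <- spacerGeneLibrary(g, minGeneLength)
        for (r in seq_len(nrow(sp))) {
            hits <- scanSpacer(sp$sequence[r], lib, thresholds)
            cls <- if (nrow(hits)) "GR_ISP" else "STD_ISP"
            corr <- ""
            if (nrow(hits) && length(lostByPath)) {
                tgt <- sub("\\(.*\\)", "", hits$target[1])
                who <- names(lostByPath)[vapply(lostByPath, function(x)
                    tgt %in% x, logical(1))]
                corr <- paste(who, collapse = ";")
            }
            rows[[length(rows) + 1L]] <- data.frame(
                genome = sp$genome[r],
                flank_upstream = sp$flank_upstream[r],
                flank_downstream = sp$flank_downstream[r],
                length = sp$length[r], class = cls,
                target = if (nrow(hits)) hits$target[1] else NA_character_,
                identity = if (nrow(hits)) hits$identity[1] else NA_real_,
                alignLength = if (nrow(hits)) hits$alignLength[1]
                              else NA_integer_,
                targetRegion = if (nrow(hits)) hits$targetRegion[1]
                               else NA_character_,
                nHits = nrow(hits), corroborates = corr,
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(genome = character(), flank_upstream = character(),
                   flank_downstream = character(), length = integer(),
                   class = character(), target = character(),
                   identity = numeric(), alignLength = integer(),
                   targetRegion = character(), nHits = integer(),
                   corroborates = character(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}
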