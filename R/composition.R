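## Strand compositional-bias statistics: AT/GC skews, degenerate
## third-position pools under the vertebrate mitochondrial code,
## strand-symmetry tests, group comparisons and the full-reversal
## decision rule.

#' Base counts and AT/GC skews of a sequence
#'
#' AT-skew = (A - T)/(A + T); GC-skew = (G - C)/(G + C). Ns are ignored;
#' a zero denominator yields NA with an \code{undefined} flag.
#'
#' @param sequence character DNA string (or a vector of strings, pooled).
#' @return list with \code{counts} (named A/C/G/T), \code{AT_skew},
#'   \code{GC_skew}, \code{undefined}.
#' @export
#' @examples
#' skewReport("AAAT")$AT_skew  # 0.5
skewReport <- function(sequence) {
    s <- paste(toupper(sequence), collapse = "")
    counts <- vapply(c("A", "C", "G", "T"), function(b)
        nchar(gsub(paste0("[^", b, "]"), "", s)), numeric(1))
    at <- counts["A"] + counts["T"]; gc <- counts["G"] + counts["C"]
    list(counts = counts,
         AT_skew = if (at > 0) unname((counts["A"] - counts["T"]) / at)
                   else NA_real_,
         GC_skew = if (gc > 0) unname((counts["G"] - counts["C"]) / gc)
                   else NA_real_,
         undefined = (at == 0) || (gc == 0))
}

#' Per-gene skew table across genomes
#'
#' One row per genome x feature x partition. Partitions: \code{full} (the
#' whole feature), \code{pos1}/\code{pos2}/\code{pos3} (codon positions,
#' PCGs only, reading-frame orientation), plus \code{genome} (whole
#' deposited sequence) when requested. Features missing from a (partial)
#' genome are simply absent, not zero rows.
#'
#' @param genomes list of AnnotatedGenome.
#' @param partitions character subset of
#'   \code{c("full","pos1","pos2","pos3","genome")}.
#' @param features optional label subset (default: all PCG + rRNA).
#' @return data.frame with genome, unit, partition, counts and skews.
#' @export
perGeneSkewTable <- function(genomes,
                             partitions = c("full", "pos1", "pos2",
                                            "pos3", "genome"),
                             features = NULL) {
    rows <- list()
    addRow <- function(genome, unit, partition, sk) {
        rows[[length(rows) + 1L]] <<- data.frame(
            genome = genome, unit = unit, partition = partition,
            nA = sk$counts["A"], nC = sk$counts["C"],
            nG = sk$counts["G"], nT = sk$counts["T"],
            AT_skew = sk$AT_skew, GC_skew = sk$GC_skew,
            stringsAsFactors = FALSE)
    }
    for (g in genomes) {
        f <- g@features
        sel <- if (is.null(features)) which(f$type %in% c("PCG", "rRNA"))
               else which(f$label %in% features)
        for (r in sel) {
            seq <- featureSequence(g, r)
            if ("full" %in% partitions)
                addRow(g@identifier, f$label[r], "full", skewReport(seq))
            if (f$type[r] == "PCG" &&
                any(c("pos1", "pos2", "pos3") %in% partitions)) {
                ncod <- nchar(seq) %/% 3L
                if (ncod * 3L != nchar(seq))
                    stop("frame violation in gene ", f$label[r], " of ",
                         g@identifier)
                ch <- strsplit(seq, "")[[1]]
                for (p in 1:3) {
                    pn <- paste0("pos", p)
                    if (pn %in% partitions)
                        addRow(g@identifier, f$label[r], pn,
                               skewReport(paste(
                                   ch[seq(p, ncod * 3L, by = 3L)],
                                   collapse = "")))
                }
            }
        }
        if ("genome" %in% partitions)
            addRow(g@identifier, "genome", "genome",
                   skewReport(g@sequence))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Classify codon degeneracy under the vertebrate mitochondrial code
#'
#' \code{NNN4}: all four third-position variants synonymous;
#' \code{NNR2}/\code{NNY2}: exactly the purine/pyrimidine pair
#' synonymous; \code{other}: everything else, including stop codons
#' (AGA/AGG are stops in translation table 2, TGA is Trp, ATA is Met)
#' and codons with ambiguous bases.
#'
#' @param codons character vector of 3-letter codons.
#' @return character vector in \code{c("NNN4","NNR2","NNY2","other")}.
#' @export
#' @examples
#' classifyCodonDegeneracy(c("CTC", "AAA", "TGA", "AGA"))
classifyCodonDegeneracy <- function(codons) {
    map <- .mitoCache$degeneracy
    if (is.null(map)) {
        code <- .mitoCode()
        bases <- c("A", "C", "G", "T")
        all64 <- names(code)
        map <- setNames(rep("other", 64L), all64)
        for (cod in all64) {
            aa <- code[[cod]]
            if (aa == "*") next
            pre <- substr(cod, 1, 2)
            fam <- paste0(pre, bases)
            syn <- fam[code[fam] == aa]
            third <- substr(cod, 3, 3)
            if (length(syn) == 4L) map[[cod]] <- "NNN4"
            else if (setequal(syn, paste0(pre, c("A", "G"))) &&
                     third %in% c("A", "G")) map[[cod]] <- "NNR2"
            else if (setequal(syn, paste0(pre, c("C", "T"))) &&
                     third %in% c("C", "T")) map[[cod]] <- "NNY2"
        }
        .mitoCache$degeneracy <- map
    }
    out <- map[toupper(codons)]
    out[is.na(out)] <- "other"
    unname(out)
}

#' Pool synonymous third positions of degenerate codons
#'
#' Builds, per genome, the third-position base pools of the 4-fold
#' (NNN4) and 2-fold (NNR2 + NNY2) degenerate codons across
#' protein-coding genes, the raw material of the strand-symmetry tests.
#' Genes translocated to the opposite strand relative to the typical
#' arrangement must be excluded (their bias is mirrored); exclusions can
#' be given explicitly or derived automatically from each genome's gene
#' order by comparison with the typical vertebrate strand assignment.
#'
#' @param genome AnnotatedGenome.
#' @param exclude character vector of gene labels to drop; with
#'   \code{exclude = "auto"} genes whose strand differs from their VertGO
#'   strand are dropped (e.g. nad1 after the Trematominae inversion).
#' @return list with \code{NNN4} and \code{NNR2_NNY2} (named base count
#'   vectors), \code{excluded}, and \code{nCodons} per class.
#' @export
extractDegenerateSets <- function(genome, exclude = "auto") {
    f <- genome@features
    pcg <- which(f$type == "PCG")
    if (identical(exclude, "auto")) {
        v <- notoGeneOrders("VertGO")[[1]]
        vstrand <- setNames(ifelse(orderSigns(v) < 0, "L", "H"),
                            orderLabels(v))
        exclude <- f$label[pcg][f$strand[pcg] !=
                                   vstrand[f$label[pcg]]]
    } else {
        miss <- setdiff(exclude, f$label)
        if (length(miss))
            warning("excluded gene(s) absent from genome: ",
                    paste(miss, collapse = ", "))
    }
    pools <- list(NNN4 = c(A = 0L, C = 0L, G = 0L, T = 0L),
                  NNR2_NNY2 = c(A = 0L, C = 0L, G = 0L, T = 0L))
    nCodons <- c(NNN4 = 0L, NNR2_NNY2 = 0L)
    for (r in pcg) {
        if (f$label[r] %in% exclude) next
        cods <- .codons(featureSequence(genome, r))
        if (!length(cods)) next
        last <- .mitoCode()[cods[length(cods)]]
        if (!is.na(last) && last == "*")     # drop the stop codon
            cods <- cods[-length(cods)]
        cls <- classifyCodonDegeneracy(cods)
        third <- substr(cods, 3, 3)
        for (cl in c("NNN4", "NNR2", "NNY2")) {
            sel <- third[cls == cl]
            if (!length(sel)) next
            tgt <- if (cl == "NNN4") "NNN4" else "NNR2_NNY2"
            tb <- table(factor(sel, levels = c("A", "C", "G", "T")))
            pools[[tgt]] <- pools[[tgt]] + as.integer(tb)
            nCodons[tgt] <- nCodons[tgt] + length(sel)
        }
    }
    list(NNN4 = pools$NNN4, NNR2_NNY2 = pools$NNR2_NNY2,
         excluded = exclude, nCodons = nCodons)
}

#' Strand-symmetry test on pooled base counts
#'
#' Tests H0: P(A) = P(T) (and P(G) = P(C)) among pooled synonymous
#' sites, via the binomial normal approximation
#' z = (nA - nT)/sqrt(nA + nT), two-sided p from the standard normal.
#' Pools smaller than 10 sites are flagged low-power.
#'
#' @param counts named base count vector (A/C/G/T), e.g. one pool from
#'   [extractDegenerateSets()].
#' @return data.frame with one row per comparison (A_vs_T, G_vs_C):
#'   statistic, p_value, rejected_at_0.05, skew, low_power.
#' @export
strandSymmetryTest <- function(counts) {
    one <- function(n1, n2, label) {
        tot <- n1 + n2
        z <- if (tot > 0) (n1 - n2) / sqrt(tot) else NA_real_
        p <- if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))
        data.frame(comparison = label, statistic = z, p_value = p,
                   rejected_at_0.05 = !is.na(p) && p < 0.05,
                   skew = if (tot > 0) (n1 - n2) / tot else NA_real_,
                   low_power = tot < 10,
                   stringsAsFactors = FALSE)
    }
    rbind(one(counts[["A"]], counts[["T"]], "A_vs_T"),
          one(counts[["G"]], counts[["C"]], "G_vs_C"))
}

#' Compare absolute skews between two taxon groups (Student's t)
#'
#' Two-sample Student's t-test (pooled variance, two-tailed) on the
#' absolute values of the skews -- the comparison of inversion-affected
#' taxa against the remaining taxa.
#'
#' @param groupA,groupB numeric vectors of skew values (absolute values
#'   are taken).
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{meanA}, \code{meanB}.
#' @export
compareSkewGroups <- function(groupA, groupB) {
    a <- abs(groupA); b <- abs(groupB)
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs n >= 2")
    if (stats::var(a) + stats::var(b) == 0) {
        return(list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                    df = length(a) + length(b) - 2L,
                    p_value = if (mean(a) == mean(b)) 1 else 0,
                    meanA = mean(a), meanB = mean(b)))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, meanA = mean(a), meanB = mean(b))
}

#' Decide whether the strand compositional bias is reversed
#'
#' Applies the two-criterion rule per degenerate-site class: a genome
#' shows a FULL reversal iff, for both the 4-fold (NNN4) and 2-fold
#' (NNR2+NNY2) pools, (1) the AT- and GC-skews carry the sign opposite
#' to the expectation for unrearranged mitogenomes, and (2) strand
#' symmetry is rejected at P < 0.05 for both A-vs-T and G-vs-C. A
#' PARTIAL reversal holds when a proper, non-empty subset of the
#' sign-opposition criteria is met (the pattern of a recent Control
#' Region inversion); otherwise none.
#'
#' @param degSets output of [extractDegenerateSets()].
#' @param expectedSigns expected skew signs without reversal:
#'   \code{c(AT = 1, GC = -1)} (deposited-strand third positions are
#'   typically A-rich and C-rich).
#' @param alpha significance level.
#' @return list with \code{decision} ("none"/"partial"/"full"),
#'   \code{evidence} data.frame (per class and skew: sign opposition and
#'   rejection flags), and the test tables.
#' @export
decideReversal <- function(degSets, expectedSigns = c(AT = 1, GC = -1),
                           alpha = 0.05) {
    ev <- list(); tests <- list()
    for (cl in c("NNN4", "NNR2_NNY2")) {
        tt <- strandSymmetryTest(degSets[[cl]])
        tests[[cl]] <- tt
        sk <- skewReport(paste(rep(names(degSets[[cl]]),
                                   degSets[[cl]]), collapse = ""))
        ev[[length(ev) + 1L]] <- data.frame(
            class = cl, skew = "AT",
            value = sk$AT_skew,
            opposite = !is.na(sk$AT_skew) && sk$AT_skew != 0 &&
                sign(sk$AT_skew) == -sign(expectedSigns[["AT"]]),
            rejected = tt$p_value[tt$comparison == "A_vs_T"] < alpha,
            stringsAsFactors = FALSE)
        ev[[length(ev) + 1L]] <- data.frame(
            class = cl, skew = "GC",
            value = sk$GC_skew,
            opposite = !is.na(sk$GC_skew) && sk$GC_skew != 0 &&
                sign(sk$GC_skew) == -sign(expectedSigns[["GC"]]),
            rejected = tt$p_value[tt$comparison == "G_vs_C"] < alpha,
            stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, ev)
    decision <- if (all(ev$opposite) && all(ev$rejected)) "full"
                else if (any(ev$opposite)) "partial"
                else "none"
    list(decision = decision, evidence = ev, tests = tests)
}
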