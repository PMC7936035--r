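#' Controlled vocabulary for mitochondrial genome elements
#'
#' The 37 genes of the typical vertebrate mitogenome (13 protein-coding
#' genes, 2 rRNAs, 22 tRNAs named by one-letter amino-acid code with the
#' L1/L2 and S1/S2 isoacceptor distinction), plus the Control Region
#' (\code{CoRe}, origin of H-strand replication) and the L-strand
#' replication origin (\code{OL}).
#'
#' @return A data.frame with columns \code{label} and \code{type}
#'   (\code{PCG}, \code{rRNA}, \code{tRNA}, \code{control_region},
#'   \code{origin}).
#' @export
#' @examples
#' nrow(mitoVocabulary())  # 39 elements
mitoVocabulary <- function() {
    pcg <- c("cox1", "cox2", "cox3", "atp6", "atp8", "cob",
             "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
    rrna <- c("rrnS", "rrnL")
    trna <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
              "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y")
    data.frame(
        label = c(pcg, rrna, trna, "CoRe", "OL"),
        type = c(rep("PCG", length(pcg)), rep("rRNA", length(rrna)),
                 rep("tRNA", length(trna)), "control_region", "origin"),
        stringsAsFactors = FALSE)
}

# type lookup used internally
.elementType <- function(labels) {
    voc <- mitoVocabulary()
    voc$type[match(labels, voc$label)]
}

#' Normalize heterogeneous gene names to the controlled vocabulary
#'
#' GenBank records name mitochondrial features inconsistently ("ND6",
#' "CYTB", "D-loop", "tRNA-Leu(UUR)", "16S ribosomal RNA", ...). This maps
#' common synonyms onto the closed label set of [mitoVocabulary()].
#' Unknown labels are returned unchanged with attribute
#' \code{unknown = TRUE} positions.
#'
#' @param x character vector of raw labels.
#' @return character vector of normalized labels; attribute
#'   \code{unknown} holds a logical vector marking labels that could not
#'   be normalized.
#' @export
normalizeLabels <- function(x) {
    key <- toupper(gsub("[ _]", "", x))
    map <- .synonymMap()
    hit <- map[key]
    voc <- mitoVocabulary()$label
    direct <- match(toupper(x), toupper(voc))
    out <- unname(ifelse(!is.na(hit), hit,
                         ifelse(!is.na(direct), voc[direct], x)))
    unknown <- unname(is.na(hit) & is.na(direct))
    if (any(unknown))
        warning("unknown feature label(s) kept verbatim: ",
                paste(unique(x[unknown]), collapse = ", "))
    attr(out, "unknown") <- unknown
    out
}

.synonymMap <- function() {
    m <- c(
        "COI" = "cox1", "COXI" = "cox1", "CO1" = "cox1", "COX1" = "cox1",
        "COII" = "cox2", "COXII" = "cox2", "CO2" = "cox2", "COX2" = "cox2",
        "COIII" = "cox3", "COXIII" = "cox3", "CO3" = "cox3", "COX3" = "cox3",
        "ATP6" = "atp6", "ATPASE6" = "atp6", "ATP8" = "atp8", "ATPASE8" = "atp8",
        "CYTB" = "cob", "CYB" = "cob", "COB" = "cob", "CYTOCHROMEB" = "cob",
        "ND1" = "nad1", "ND2" = "nad2", "ND3" = "nad3", "ND4" = "nad4",
        "ND4L" = "nad4L", "ND5" = "nad5", "ND6" = "nad6",
        "NAD1" = "nad1", "NAD2" = "nad2", "NAD3" = "nad3", "NAD4" = "nad4",
        "NAD4L" = "nad4L", "NAD5" = "nad5", "NAD6" = "nad6",
        "12S" = "rrnS", "12SRRNA" = "rrnS", "RRNS" = "rrnS",
        "12SRIBOSOMALRNA" = "rrnS", "SRRNA" = "rrnS",
        "16S" = "rrnL", "16SRRNA" = "rrnL", "RRNL" = "rrnL",
        "16SRIBOSOMALRNA" = "rrnL", "LRRNA" = "rrnL",
        "D-LOOP" = "CoRe", "DLOOP" = "CoRe", "CONTROLREGION" = "CoRe",
        "CR" = "CoRe", "CORE" = "CoRe",
        "OL" = "OL", "O_L" = "OL", "ORIGINL" = "OL", "OLR" = "OL",
        "REP_ORIGIN" = "OL", "L-STRANDORIGIN" = "OL")
    aa <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe",
            G = "Gly", H = "His", I = "Ile", K = "Lys", M = "Met",
            N = "Asn", P = "Pro", Q = "Gln", R = "Arg", T = "Thr",
            V = "Val", W = "Trp", Y = "Tyr")
    trn <- c(paste0("TRNA-", toupper(aa)), paste0("TRN", names(aa)))
    names(trn) <- trn
    trn[] <- rep(names(aa), 2)
    m <- c(m, trn,
           "TRNA-LEU(UUR)" = "L2", "TRNA-LEU(TAA)" = "L2", "TRNL2" = "L2",
           "TRNA-LEU(CUN)" = "L1", "TRNA-LEU(TAG)" = "L1", "TRNL1" = "L1",
           "TRNA-LEU" = "L1",
           "TRNA-SER(UCN)" = "S2", "TRNA-SER(TGA)" = "S2", "TRNS2" = "S2",
           "TRNA-SER(AGY)" = "S1", "TRNA-SER(GCT)" = "S1", "TRNS1" = "S1",
           "TRNA-SER" = "S1")
    m
}

#' Map mitochondrial protein-coding genes to OXPHOS complexes
#'
#' Complex I: the NADH dehydrogenase subunits; complex III: apocytochrome
#' b; complex IV: the cytochrome c oxidase subunits; complex V: the ATP
#' synthase subunits. Covers the 13 PCGs exactly once.
#'
#' @return named character vector, gene -> complex label.
#' @export
oxphosComplexMap <- function() {
    c(nad1 = "I", nad2 = "I", nad3 = "I", nad4 = "I", nad4L = "I",
      nad5 = "I", nad6 = "I",
      cob = "III",
      cox1 = "IV", cox2 = "IV", cox3 = "IV",
      atp6 = "V", atp8 = "V")
}
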