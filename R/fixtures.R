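## Named notothenioid gene orders and the reference phylogeny fixtures.

.GO_STRINGS <- local({
    head17 <- "cox1,-S2,D,cox2,K,atp8,atp6,cox3,G,nad3,R,nad4L,nad4,H,S1,L1,nad5"
    tailIQM <- "F,rrnS,V,rrnL,L2,nad1,I,-Q,M"
    tailWANCY <- "nad2,W,-A,-N,OL,-C,-Y"
    mk <- function(mid, tail = paste(tailIQM, tailWANCY, sep = ","))
        paste(head17, mid, tail, sep = ",")
    list(
        VertGO   = mk("-nad6,-E,cob,T,-P,CoRe"),
        Noto1GO  = mk("T,-P,CoRe,-nad6,-E,cob,T,-P,CoRe"),
        Noto2GO  = mk("T,CoRe,-nad6,-E,cob,-P,CoRe"),
        Noto3GO  = mk("T,-nad6,-E,cob,-P,CoRe"),
        DissoGO  = mk("T,-P,CoRe,-nad6,-E,cob,CoRe"),
        TremaIntGO = mk("T,-P,-nad6,-E,cob,CoRe"),
        TremaGO  = paste(head17,
            "T,-P,-nad6,-E,cob,-I,-nad1,-L2,-rrnL,-V,-rrnS,-F,-CoRe,-Q,M",
            tailWANCY, sep = ","),
        RacoGO   = mk("T,-P,CoRe,-nad6,-E,cob,-P,CoRe"),
        GymnGO   = mk("T,-E,-nad6,-E,cob,-P,CoRe,-P"),
        ChamGO   = mk("T,-nad6,-E,cob,-P,CoRe,-nad6,-E,cob,-P,CoRe"),
        RossiiGO = mk("T,-P,CoRe,-nad6,-E,T,-P,CoRe,-nad6,-E,cob,T,-P,CoRe"))
})

#' Named notothenioid mitochondrial gene orders
#'
#' The typical vertebrate order (VertGO) and the rearranged orders found
#' in the Nototheniidae: Noto1GO-Noto3GO, DissoGO, TremaGO, RacoGO,
#' GymnGO, ChamGO, plus the unsampled pre-inversion Trematominae
#' intermediate (TremaIntGO) and the Noto1GO modification of
#' *Notothenia rossii* (RossiiGO). RacoGO's exact element list is known
#' only from published figure panels and is flagged
#' \code{figure_derived} in its metadata; GymnGO follows the textual
#' pathway description (it retains duplicated trnE and trnP).
#'
#' All rearrangements relative to VertGO lie in the nad5-trnF region,
#' except TremaGO whose inverted block (CoRe through trnI, seven genes
#' plus the Control Region moved to the opposite strand) extends into the
#' IQM region.
#'
#' @param which optional character vector of order names to return.
#' @return named list of canonical [GeneOrder-class] objects.
#' @export
#' @examples
#' notoGeneOrders(c("VertGO", "Noto1GO"))
notoGeneOrders <- function(which = NULL) {
    nm <- names(.GO_STRINGS)
    if (!is.null(which)) {
        bad <- setdiff(which, nm)
        if (length(bad)) stop("unknown gene order(s): ",
                              paste(bad, collapse = ", "))
        nm <- which
    }
    out <- lapply(nm, function(n) {
        o <- geneOrder(.GO_STRINGS[[n]], name = n)
        if (n %in% c("RacoGO", "GymnGO"))
            o@meta$figure_derived <- TRUE
        if (n == "TremaIntGO") o@meta$unsampled_intermediate <- TRUE
        o
    })
    names(out) <- nm
    out
}

## clade building blocks of the reference topology
.notoClades <- local({
    trema <- paste0("((Trematomus_bernacchii,Trematomus_borchgrevinki),",
                    "(Trematomus_hansoni,(Trematomus_newnesi,",
                    "(Trematomus_eulepidotus,Lindbergichthys_nudifrons))))")
    disso <- paste0("(Aethotaxis_mitopteryx,",
                    "(Dissostichus_eleginoides,Dissostichus_mawsoni))")
    arted <- paste0("(Artedidraco_skottsbergi,",
                    "(Pogonophryne_scotti,Histiodraco_velifer))")
    ha <- paste0("(Harpagifer_antarcticus,", arted, ")")
    chan <- paste0("(Champsocephalus_gunnari,(Chaenocephalus_aceratus,",
                   "(Pagetopsis_macropterus,(Chionodraco_hamatus,",
                   "Cryodraco_antarcticus))))")
    bgcc <- paste0("((Akarotaxis_nudiceps,Racovitzia_glacialis),",
                   "(Gymnodraco_acuticeps,(Cygnodraco_mawsoni,", chan, ")))")
    nodeb <- paste0("(", ha, ",", bgcc, ")")
    dt <- paste0("(", disso, ",", trema, ")")
    nototheniinae <- "(Notothenia_coriiceps,Notothenia_angustata)"
    list(trema = trema, disso = disso, nodeb = nodeb, dt = dt,
         nototheniinae = nototheniinae)
})

.notoTreeString <- function(alternative = FALSE) {
    cl <- .notoClades
    fam <- if (!alternative)
        paste0("(Pleuragramma_antarctica,(", cl$nototheniinae, ",(",
               cl$dt, ",", cl$nodeb, ")))")
    else
        paste0("(", cl$nototheniinae, ",((Pleuragramma_antarctica,",
               cl$dt, "),", cl$nodeb, "))")
    paste0("(Bovichtus_angustifrons,(Pseudaphritis_urvillii,",
           "(Eleginops_maclovinus,", fam, ")));")
}

#' Reference notothenioid phylogeny (28 taxa)
#'
#' A transcription of the published reference topology (maximum-likelihood
#' tree under the heterotachy model): the non-Antarctic Bovichtidae,
#' Pseudaphritidae and Eleginopsidae branch off first; within the
#' Nototheniidae, *Pleuragramma antarctica* is sister to the remaining
#' lineages; Harpagiferinae pair with Artedidraconinae, and that clade is
#' sister to the Bathydraconinae/Gymnodraconinae/Cygnodraconinae/
#' Channichthyinae lineage. Species not named in the running text are
#' plausible congeners (the structural analyses depend only on the
#' subfamily-level shape and the gene-order assignments). The
#' \code{alternative} topology differs in the placement of
#' *P. antarctica* (sister to Dissostichinae + Trematominae, as obtained
#' under the best partition scheme).
#'
#' @param alternative return the alternative topology.
#' @return rooted \code{phylo} object.
#' @export
notoReferenceTree <- function(alternative = FALSE) {
    ape::read.tree(text = .notoTreeString(alternative))
}

#' Tip gene-order assignments for the 28-taxon reference set
#'
#' Species-to-gene-order map used for ancestral reconstruction: VertGO in
#' the three non-Antarctic outgroup taxa, the eight nototheniid orders on
#' the Antarctic tips.
#'
#' @param later include the optional fixture tips of species published
#'   after the study window (*C. dewitti*, *P. albipinna*, *N. rossii*,
#'   *T. loennbergii*), which are excluded from the reference analyses.
#' @return named character vector, species -> gene-order name (keys of
#'   [notoGeneOrders()]).
#' @export
notoTipOrders <- function(later = FALSE) {
    base <- c(
        Bovichtus_angustifrons = "VertGO",
        Pseudaphritis_urvillii = "VertGO",
        Eleginops_maclovinus = "VertGO",
        Pleuragramma_antarctica = "Noto1GO",
        Notothenia_coriiceps = "Noto2GO",
        Notothenia_angustata = "Noto1GO",
        Aethotaxis_mitopteryx = "Noto1GO",
        Dissostichus_eleginoides = "DissoGO",
        Dissostichus_mawsoni = "DissoGO",
        Trematomus_bernacchii = "TremaGO",
        Trematomus_borchgrevinki = "TremaGO",
        Trematomus_hansoni = "TremaGO",
        Trematomus_newnesi = "TremaGO",
        Trematomus_eulepidotus = "TremaGO",
        Lindbergichthys_nudifrons = "TremaGO",
        Harpagifer_antarcticus = "Noto2GO",
        Artedidraco_skottsbergi = "Noto3GO",
        Pogonophryne_scotti = "Noto3GO",
        Histiodraco_velifer = "Noto3GO",
        Akarotaxis_nudiceps = "Noto3GO",
        Racovitzia_glacialis = "RacoGO",
        Gymnodraco_acuticeps = "GymnGO",
        Cygnodraco_mawsoni = "Noto3GO",
        Champsocephalus_gunnari = "ChamGO",
        Chaenocephalus_aceratus = "Noto3GO",
        Pagetopsis_macropterus = "Noto3GO",
        Chionodraco_hamatus = "Noto3GO",
        Cryodraco_antarcticus = "Noto3GO")
    if (later)
        base <- c(base,
                  Chionobathyscus_dewitti = "Noto3GO",
                  Pogonophryne_albipinna = "Noto3GO",
                  Notothenia_rossii = "RossiiGO",
                  Trematomus_loennbergii = "TremaGO")
    base
}

#' Nototheniidae membership of the reference tip set
#'
#' @return character vector of the Antarctic-family tips (everything but
#'   the three non-Antarctic outgroups).
#' @export
notoFamilyTips <- function() {
    t <- notoTipOrders()
    setdiff(names(t), c("Bovichtus_angustifrons", "Pseudaphritis_urvillii",
                        "Eleginops_maclovinus"))
}
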