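#' @import methods
#' @importFrom stats median pnorm pt quantile rbinom runif setNames reorder
#' @importFrom utils combn head read.table write.table
#' @importFrom ape read.tree is.rooted root getMRCA
NULL

#' GeneOrder: a signed circular mitochondrial gene order
#'
#' The unit every structural analysis operates on: the circular arrangement
#' of labeled mitochondrial elements (genes, Control Region(s), O_L) with
#' their strand assignment. Orders are stored in canonical linearized form:
#' starting from \code{cox1} on the plus (H) strand; a circular molecule
#' read from either strand is the same molecule, so the mirror complement
#' is identified during canonicalization.
#'
#' @slot name character, a display name (e.g. \code{"VertGO"}).
#' @slot labels character vector of element labels.
#' @slot signs integer vector: \code{+1} for H-strand, \code{-1} for
#'   L-strand, \code{0} for unsigned positional elements (O_L).
#' @slot meta list of free-form metadata (e.g. \code{figure_derived},
#'   \code{partial}).
#' @export
setClass("GeneOrder",
    representation(name = "character", labels = "character",
                   signs = "integer", meta = "list"),
    prototype(name = NA_character_, meta = list()))

setValidity("GeneOrder", function(object) {
    msg <- character()
    if (length(object@labels) == 0L)
        msg <- c(msg, "gene order must contain at least one element")
    if (length(object@labels) != length(object@signs))
        msg <- c(msg, "labels and signs must have equal length")
    if (sum(object@labels == "cox1") > 1L)
        msg <- c(msg, "at most one cox1 allowed")
    if (!all(object@signs %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "signs must be -1, 0 or +1")
    if (length(msg)) msg else TRUE
})

#' RearrangementEvent: one mitochondrial rearrangement mechanism
#'
#' An executable rearrangement operator. Kinds follow the classical
#' mechanism taxonomy: \code{"inversion"} (I), \code{"transposition"} (t),
#' \code{"inverse_transposition"} (it), \code{"tdrl"} (tandem duplication
#' of a block followed by random loss; covers completed TDRL, TD-PRL and
#' the single-gene tdrl), \code{"td"} (tandem duplication, nothing lost),
#' \code{"trid"} (tandem triplication, nothing lost), \code{"prl"}
#' (partial random loss of redundant copies), \code{"loss"} (deletion of a
#' contiguous segment, even if it removes the last copy of an element).
#'
#' Positions refer to the canonical linearization of the order the event
#' is applied to.
#'
#' @slot kind character, one of the kinds above.
#' @slot seg integer length-2: first and last position of the contiguous
#'   segment (for segment-based kinds).
#' @slot at integer: for (inverse) transpositions, the position after
#'   which the segment is re-inserted (0 = in front of the first element).
#' @slot copies integer: number of tandem copies for \code{tdrl} (2).
#' @slot keep logical matrix (copies x segment length) for \code{tdrl}:
#'   which elements each copy retains. Every column must keep >= 1 copy
#'   and every row >= min(2, k) elements.
#' @slot drop integer vector of positions removed by \code{prl}.
#' @export
setClass("RearrangementEvent",
    representation(kind = "character", seg = "integer", at = "integer",
                   copies = "integer", keep = "matrix", drop = "integer"),
    prototype(seg = integer(), at = NA_integer_, copies = NA_integer_,
              keep = matrix(logical(), 0, 0), drop = integer()))

setValidity("RearrangementEvent", function(object) {
    kinds <- c("inversion", "transposition", "inverse_transposition",
               "tdrl", "td", "trid", "prl", "loss")
    if (!object@kind %in% kinds)
        return(paste("unknown event kind:", object@kind))
    if (object@kind %in% c("inversion", "transposition",
                           "inverse_transposition", "tdrl", "td", "trid",
                           "loss")) {
        if (length(object@seg) != 2L || object@seg[1] > object@seg[2])
            return("seg must be c(first, last) with first <= last")
    }
    if (object@kind == "tdrl") {
        k <- object@seg[2] - object@seg[1] + 1L
        if (ncol(object@keep) != k)
            return("keep matrix must have one column per segment element")
        if (any(colSums(object@keep) < 1L))
            return("tdrl loss pattern may not delete every copy of an element")
        if (any(rowSums(object@keep) < min(2L, k)))
            return("each tdrl copy must retain at least two elements (or the whole single-element segment)")
        for (r in seq_len(nrow(object@keep))) {
            w <- which(object@keep[r, ])
            if (length(w) && any(diff(w) != 1L))
                return("each tdrl copy must retain a contiguous block")
        }
    }
    if (object@kind == "prl" && length(object@drop) == 0L)
        return("prl must drop at least one element")
    TRUE
})

#' EventPath: a minimal series of events between two gene orders
#'
#' Replaying \code{events} on \code{source} yields \code{target}; this is
#' checked on construction.
#'
#' @slot source,target GeneOrder.
#' @slot events list of RearrangementEvent, applied in order.
#' @slot cost numeric total weighted cost.
#' @export
setClass("EventPath",
    representation(source = "GeneOrder", target = "GeneOrder",
                   events = "list", cost = "numeric"))

#' AnnotatedGenome: a mitogenome sequence with its feature table
#'
#' @slot identifier species/accession string.
#' @slot sequence character, circular DNA over A,C,G,T,N (reference = the
#'   strand on which most genes read forward, i.e. the deposited strand).
#' @slot features data.frame with columns \code{label}, \code{strand}
#'   (\code{"H"}/\code{"L"}), \code{start}, \code{end} (0-based half-open,
#'   circular; \code{end} may exceed the genome length only for
#'   origin-spanning features), \code{type}.
#' @slot completeness \code{"complete"} or \code{"partial"}.
#' @export
setClass("AnnotatedGenome",
    representation(identifier = "character", sequence = "character",
                   features = "data.frame", completeness = "character"),
    prototype(completeness = "complete"))

setValidity("AnnotatedGenome", function(object) {
    f <- object@features
    need <- c("label", "strand", "start", "end", "type")
    if (!all(need %in% names(f)))
        return(paste("features must have columns:", paste(need, collapse = ", ")))
    L <- nchar(object@sequence)
    if (nrow(f)) {
        if (any(f$start < 0) || any(f$start >= L))
            return("feature start must satisfy 0 <= start < genome length")
        if (any(f$end <= f$start))
            return("feature end must exceed start (half-open coordinates)")
        if (any(f$end > 2 * L))
            return("feature end beyond one full wrap")
        if (is.unsorted(f$start))
            return("features must be sorted by start")
        if (anyDuplicated(f[c("label", "start", "end")]))
            return("duplicate identical features")
        if (!all(f$strand %in% c("H", "L")))
            return("strand must be 'H' or 'L'")
    }
    if (!object@completeness %in% c("complete", "partial"))
        return("completeness must be 'complete' or 'partial'")
    TRUE
})

#' AncestralAssignment: gene orders mapped onto a phylogeny
#'
#' Result container of [reconstructAncestral()]: per-node gene-order
#' states under minimum total event cost (Sankoff parsimony over a finite
#' candidate state pool), per-edge minimal event paths, and the total
#' event count.
#'
#' @slot tree an \code{ape} \code{phylo} object (rooted).
#' @slot states character vector of pool-state names, indexed by node
#'   number (tips 1..Ntip, then internal nodes), for the primary
#'   (deterministic lexicographic) assignment.
#' @slot pool named list of candidate GeneOrder states.
#' @slot edges data.frame: one row per tree edge with parent/child states
#'   and edge cost.
#' @slot paths list of EventPath lists, parallel to \code{edges} rows.
#' @slot totalCost numeric minimal total cost.
#' @slot coOptimal list of alternative co-optimal state vectors (capped).
#' @slot distances numeric matrix of directed state-to-state costs.
#' @export
setClass("AncestralAssignment",
    representation(tree = "ANY", states = "character", pool = "list",
                   edges = "data.frame", paths = "list",
                   totalCost = "numeric", coOptimal = "list",
                   distances = "matrix"))
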