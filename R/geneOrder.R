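## Signed circular gene-order model: construction, canonical form,
## equality, copy tags, slicing.

## ---- internal plain representation -------------------------------------
## Inside search loops gene orders are plain lists: list(labels=, signs=).
## The S4 layer wraps these at the API boundary.

.go <- function(labels, signs) list(labels = labels, signs = as.integer(signs))

.goFromS4 <- function(x) .go(x@labels, x@signs)

.goKey <- function(g)
    paste0(c("-", "", "")[g$signs + 2L], g$labels, collapse = ",")

## rotate + mirror so cox1 (or fallback) is first with sign +
.goCanonical <- function(g, start = "cox1", fallback = NULL) {
    idx <- which(g$labels == start)
    partial <- FALSE
    if (length(idx) == 0L) {
        if (!is.null(fallback)) {
            idx <- which(g$labels == fallback)
            partial <- TRUE
        }
        if (length(idx) == 0L)
            stop("cannot canonicalize: element '", start,
                 "' absent", if (!is.null(fallback))
                     paste0(" (fallback '", fallback, "' also absent)"))
    }
    if (length(idx) > 1L)
        stop("cannot canonicalize: start element occurs more than once")
    if (g$signs[idx] < 0L) {
        g$labels <- rev(g$labels)
        g$signs <- -rev(g$signs)
        idx <- length(g$labels) - idx + 1L
    }
    n <- length(g$labels)
    ord <- c(idx:n, if (idx > 1L) 1:(idx - 1L))
    out <- .go(g$labels[ord], g$signs[ord])
    attr(out, "partial") <- partial
    out
}

## copy tags in traversal order: CoRe -> 1,2,...; others -> a,b,c
.goTags <- function(labels) {
    tags <- character(length(labels))
    dup <- labels %in% labels[duplicated(labels)]
    for (lab in unique(labels[dup])) {
        i <- which(labels == lab)
        tags[i] <- if (lab == "CoRe") as.character(seq_along(i))
                   else letters[seq_along(i)]
    }
    tags
}

## ---- constructors ------------------------------------------------------

#' Construct a GeneOrder
#'
#' @param labels character vector of element labels, or a single string in
#'   linearized notation (see [parseGeneOrder()]).
#' @param signs integer/numeric vector of strand signs (+1 H, -1 L);
#'   ignored when \code{labels} is a notation string. Elements of type
#'   origin (O_L) are always stored unsigned.
#' @param name optional display name.
#' @param canonical canonicalize on construction (default TRUE).
#' @param fallbackStart start label used when cox1 is absent (partial
#'   genomes); the result is flagged \code{partial} in its metadata.
#' @return a [GeneOrder-class] object.
#' @export
#' @examples
#' geneOrder("cox1,-S2,D,cox2", name = "toy")
geneOrder <- function(labels, signs = NULL, name = NA_character_,
                      canonical = TRUE, fallbackStart = NULL) {
    if (length(labels) == 1L && grepl(",", labels)) {
        p <- parseGeneOrder(labels)
        labels <- p$labels; signs <- p$signs
    }
    if (is.null(signs)) signs <- rep(1L, length(labels))
    signs <- as.integer(signs)
    signs[.elementType(labels) %in% "origin"] <- 0L
    g <- .go(labels, signs)
    meta <- list()
    if (canonical) {
        g <- .goCanonical(g, fallback = fallbackStart)
        if (isTRUE(attr(g, "partial"))) meta$partial <- TRUE
    }
    new("GeneOrder", name = name, labels = g$labels, signs = g$signs,
        meta = meta)
}

#' Parse the linearized gene-order notation
#'
#' Comma-separated labels, leading \code{-} for L-strand elements,
#' optional parenthesized copy tags which are ignored on input (they are
#' reassigned deterministically from the canonical start), e.g.
#' \code{"cox1,-S2,...,nad5,T(a),-P(a),CoRe(1),-nad6,...,F"}.
#'
#' @param x a single character string.
#' @return list with \code{labels} and \code{signs}.
#' @export
parseGeneOrder <- function(x) {
    toks <- trimws(strsplit(x, ",")[[1]])
    toks <- toks[nzchar(toks)]
    signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
    labels <- sub("^-", "", toks)
    labels <- sub("\\(.*\\)$", "", labels)
    list(labels = labels, signs = signs)
}

#' Format a GeneOrder in linearized notation
#'
#' @param x a GeneOrder.
#' @param tags include parenthesized copy tags for duplicated elements.
#' @return single character string.
#' @export
formatGeneOrder <- function(x, tags = TRUE) {
    lab <- x@labels
    if (tags) {
        tg <- .goTags(lab)
        lab <- ifelse(nzchar(tg), paste0(lab, "(", tg, ")"), lab)
    }
    paste0(ifelse(x@signs < 0L, "-", ""), lab, collapse = ",")
}

setMethod("show", "GeneOrder", function(object) {
    cat("GeneOrder", if (!is.na(object@name)) sQuote(object@name) else "",
        "with", length(object@labels), "elements\n")
    cat(" ", formatGeneOrder(object), "\n")
})

## ---- generics + accessors ----------------------------------------------

#' @rdname orderLabels
#' @export
setGeneric("orderLabels", function(x) standardGeneric("orderLabels"))

#' Accessors for GeneOrder
#'
#' \code{orderLabels} returns element labels, \code{orderSigns} strand
#' signs, \code{copyTags} the deterministic duplicate tags (a/b/c for
#' genes, 1/2 for Control Regions) assigned in traversal order from the
#' canonical start.
#'
#' @param x a GeneOrder.
#' @return character or integer vector.
#' @export
setMethod("orderLabels", "GeneOrder", function(x) x@labels)

#' @rdname orderLabels
#' @export
setGeneric("orderSigns", function(x) standardGeneric("orderSigns"))

#' @rdname orderLabels
#' @export
setMethod("orderSigns", "GeneOrder", function(x) x@signs)

#' @rdname orderLabels
#' @export
setGeneric("copyTags", function(x) standardGeneric("copyTags"))

#' @rdname orderLabels
#' @export
setMethod("copyTags", "GeneOrder", function(x) .goTags(x@labels))

## ---- canonicalization ---------------------------------------------------

#' Canonicalize a gene order
#'
#' Normal form of a circular signed order: rotated so \code{cox1} is
#' first; if \code{cox1} lies on the L-strand the whole order is mirrored
#' and complemented first (a circular DNA molecule has no intrinsic
#' reading side). Idempotent; all 2n readings (rotations x reading
#' directions) of one arrangement map to the same canonical list.
#'
#' @param order a GeneOrder (possibly non-canonical, e.g. freshly
#'   extracted from an annotation).
#' @param fallbackStart optional start label for partial genomes missing
#'   cox1.
#' @return canonical GeneOrder.
#' @export
canonicalizeOrder <- function(order, fallbackStart = NULL) {
    g <- .goCanonical(.goFromS4(order), fallback = fallbackStart)
    meta <- order@meta
    if (isTRUE(attr(g, "partial"))) meta$partial <- TRUE
    new("GeneOrder", name = order@name, labels = g$labels,
        signs = g$signs, meta = meta)
}

#' Test two gene orders for equality
#'
#' True iff the canonical element lists (label, orientation) are
#' identical; copy tags are reassigned deterministically and therefore
#' never differ between equal canonical lists. Unsigned elements (O_L)
#' participate in order comparison but not in orientation checks.
#'
#' @param a,b GeneOrder objects.
#' @return logical.
#' @export
ordersEqual <- function(a, b) {
    ga <- .goCanonical(.goFromS4(a))
    gb <- .goCanonical(.goFromS4(b))
    identical(.goKey(ga), .goKey(gb))
}

#' Count distinct gene orders
#'
#' Number of equivalence classes under [ordersEqual()] and a
#' class-to-members map.
#'
#' @param orders a (possibly named) list of GeneOrder objects.
#' @return list with \code{count}, \code{classes} (named list mapping a
#'   representative key to member names/indices) and \code{representatives}
#'   (list of one GeneOrder per class).
#' @export
distinctOrders <- function(orders) {
    if (is.null(names(orders)))
        names(orders) <- seq_along(orders)
    keys <- vapply(orders, function(o) .goKey(.goCanonical(.goFromS4(o))),
                   character(1))
    classes <- split(names(orders), keys)
    reps <- orders[!duplicated(keys)]
    names(reps) <- unique(keys)
    list(count = length(classes), classes = classes,
         representatives = reps)
}

#' Extract a contiguous circular slice of a gene order
#'
#' Used to restrict analyses to the nad5-trnF rearrangement hot spot.
#' The slice runs forward (in canonical direction) from the first
#' occurrence of \code{from} to the first occurrence of \code{to} at or
#' after it, inclusive of both endpoints, wrapping around the origin if
#' needed.
#'
#' @param order a GeneOrder.
#' @param from,to element labels delimiting the slice.
#' @return a GeneOrder holding the slice (not re-canonicalized).
#' @export
regionSlice <- function(order, from, to) {
    g <- .goCanonical(.goFromS4(order))
    n <- length(g$labels)
    i <- which(g$labels == from)[1]
    if (is.na(i)) stop("label absent from order: ", from)
    idx2 <- c(seq_len(n), seq_len(n))
    lab2 <- g$labels[((seq_len(2L * n) - 1L) %% n) + 1L]
    j <- which(lab2 == to & seq_len(2L * n) >= i)[1]
    if (is.na(j)) stop("label absent from order: ", to)
    sel <- ((seq(i, j) - 1L) %% n) + 1L
    new("GeneOrder", name = order@name, labels = g$labels[sel],
        signs = g$signs[sel], meta = order@meta)
}

#' Extract the gene order from an annotated genome
#'
#' Elements are taken in circular genomic order from the feature table;
#' orientation from the strand column; the result is canonicalized
#' (mirror-complement identified). Overlapping features of the same type
#' with identical span raise an error (caught by the AnnotatedGenome
#' validity); partial genomes lacking cox1 need \code{fallbackStart}.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param fallbackStart start label for partial genomes.
#' @return canonical GeneOrder, flagged \code{partial} in metadata when
#'   the fallback start was used.
#' @export
extractGeneOrder <- function(genome, fallbackStart = NULL) {
    f <- genome@features
    geneOrder(f$label, ifelse(f$strand == "H", 1L, -1L),
              name = genome@identifier, fallbackStart = fallbackStart)
}
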