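## Rearrangement event operators: construction, application, enumeration.

#' Event model: enabled kinds, costs and structural limits
#'
#' The default model charges unit cost for every event kind (events are
#' counted, not weighted): a duplication with its random-loss phase is ONE
#' event, as is a partial random loss dropping several redundant copies.
#' Structural limits: duplicated blocks span at most \code{maxDup}
#' elements (\code{maxTri} for triplications), and every copy of a
#' duplicated block must retain at least two elements -- a pattern in
#' which one copy is reduced to a single gene is operationally
#' indistinguishable from a single-gene move and is modeled by
#' transposition instead.
#'
#' @param kinds enabled event kinds.
#' @param costs named numeric costs per kind (default 1 each).
#' @param maxDup,maxTri maximum duplicated/triplicated block length.
#' @return list of class \code{"EventModel"}.
#' @export
eventModel <- function(kinds = c("inversion", "transposition",
                                 "inverse_transposition", "tdrl", "td",
                                 "trid", "prl"),
                       costs = NULL, maxDup = 6L, maxTri = 3L) {
    all <- c(inversion = 1, transposition = 1, inverse_transposition = 1,
             tdrl = 1, td = 1, trid = 1, prl = 1, loss = 1)
    if (!is.null(costs)) all[names(costs)] <- costs
    structure(list(kinds = kinds, costs = all,
                   maxDup = as.integer(maxDup), maxTri = as.integer(maxTri)),
              class = "EventModel")
}

#' Construct a rearrangement event
#'
#' Positions refer to the canonical linearization of the order the event
#' will be applied to; \code{segment} may also be given as a length-2
#' character vector of labels with optional copy tags (\code{"T(b)"}),
#' resolved against \code{order}.
#'
#' @param kind event kind (see [RearrangementEvent-class]).
#' @param segment integer positions \code{c(first, last)} or label pair.
#' @param at insertion position for (inverse) transpositions: the element
#'   position after which the segment is re-inserted (0 = front), counted
#'   in the source order.
#' @param copies number of tandem copies for \code{tdrl} (2 or 3).
#' @param keep logical matrix (copies x k) of retained elements for
#'   \code{tdrl}; defaults for \code{td}/\code{trid} to keeping all.
#' @param drop positions (or labels with tags) removed by \code{prl}.
#' @param order optional GeneOrder used to resolve labels.
#' @return a [RearrangementEvent-class].
#' @export
rearrangementEvent <- function(kind, segment = NULL, at = NA, copies = 2L,
                               keep = NULL, drop = NULL, order = NULL) {
    resolve <- function(x) {
        if (is.numeric(x)) return(as.integer(x))
        if (is.null(order))
            stop("label-based positions need `order`")
        vapply(x, function(lab) .resolveLabel(order, lab), integer(1))
    }
    seg <- if (!is.null(segment)) {
        s <- resolve(segment)
        if (length(s) == 1L) s <- c(s, s)
        as.integer(s)
    } else integer()
    dr <- if (!is.null(drop)) sort(resolve(drop)) else integer()
    if (kind %in% c("td", "trid")) {
        k <- seg[2] - seg[1] + 1L
        copies <- if (kind == "trid") 3L else 2L
        keep <- matrix(TRUE, copies, k)
        kind0 <- kind
    } else kind0 <- kind
    if (kind == "tdrl" && is.null(keep))
        stop("tdrl needs a keep matrix")
    if (is.null(keep)) keep <- matrix(logical(), 0, 0)
    new("RearrangementEvent", kind = kind0, seg = seg,
        at = as.integer(at), copies = as.integer(copies),
        keep = keep, drop = dr)
}

## resolve "T", "T(b)", "CoRe(2)" to a position in a canonical order
.resolveLabel <- function(order, lab) {
    m <- regmatches(lab, regexec("^(-?)([^()]+)(\\(([^)]+)\\))?$", lab))[[1]]
    base <- m[3]; tag <- m[5]
    labs <- orderLabels(order)
    idx <- which(labs == base)
    if (length(idx) == 0L) stop("label absent from order: ", base)
    if (nzchar(tag) && !is.na(tag) && length(idx) > 1L) {
        tg <- .goTags(labs)[idx]
        idx <- idx[tg == tag]
        if (length(idx) == 0L) stop("no copy with tag: ", lab)
    }
    idx[1]
}

## ---- application (plain representation) --------------------------------

.applyEventGo <- function(g, ev) {
    n <- length(g$labels)
    kind <- ev@kind
    if (kind == "prl") {
        dr <- ev@drop
        if (any(dr < 1L | dr > n)) stop("prl positions out of range")
        cnt <- table(g$labels)
        dcnt <- table(g$labels[dr])
        short <- names(dcnt)[dcnt >= cnt[names(dcnt)]]
        if (length(short))
            stop("prl would remove every copy of: ",
                 paste(short, collapse = ", "), " (use kind 'loss')")
        return(.go(g$labels[-dr], g$signs[-dr]))
    }
    i <- ev@seg[1]; j <- ev@seg[2]
    if (i < 1L || j > n) stop("segment out of range")
    sel <- i:j
    if (kind == "inversion") {
        g$labels[sel] <- rev(g$labels[sel])
        g$signs[sel] <- -rev(g$signs[sel])
        return(g)
    }
    if (kind == "loss")
        return(.go(g$labels[-sel], g$signs[-sel]))
    if (kind %in% c("transposition", "inverse_transposition")) {
        at <- ev@at
        if (is.na(at) || at < 0L || at > n || (at >= i - 1L && at <= j))
            stop("invalid insertion point")
        segl <- g$labels[sel]; segs <- g$signs[sel]
        if (kind == "inverse_transposition") {
            segl <- rev(segl); segs <- -rev(segs)
        }
        rl <- g$labels[-sel]; rs <- g$signs[-sel]
        pos <- if (at > j) at - length(sel) else at
        return(.go(append(rl, segl, after = pos),
                   append(rs, segs, after = pos)))
    }
    if (kind %in% c("tdrl", "td", "trid")) {
        keep <- ev@keep
        k <- length(sel)
        newl <- newsgn <- list()
        for (cpy in seq_len(nrow(keep))) {
            w <- keep[cpy, ]
            newl[[cpy]] <- g$labels[sel][w]
            newsgn[[cpy]] <- g$signs[sel][w]
        }
        lab <- c(if (i > 1L) g$labels[1:(i - 1L)], unlist(newl),
                 if (j < n) g$labels[(j + 1L):n])
        sg <- c(if (i > 1L) g$signs[1:(i - 1L)], unlist(newsgn),
                if (j < n) g$signs[(j + 1L):n])
        return(.go(lab, as.integer(sg)))
    }
    stop("unknown kind: ", kind)
}

#' Apply a rearrangement event to a gene order
#'
#' Deterministic transformation, re-canonicalized afterwards. An
#' inversion flips the orientation of every element in the segment and
#' reverses their order; a tdrl appends the duplicate block(s) adjacent
#' to the original before applying the loss pattern.
#'
#' @param order canonical GeneOrder.
#' @param event a [RearrangementEvent-class] (validated).
#' @return the transformed canonical GeneOrder.
#' @export
#' @examples
#' v <- notoGeneOrders("VertGO")[[1]]
#' ev <- rearrangementEvent("inversion", segment = c("nad6", "nad6"),
#'                          order = v)
#' applyEvent(v, ev)
applyEvent <- function(order, event) {
    validObject(event)
    g <- .applyEventGo(.goFromS4(order), event)
    g <- .goCanonical(g)
    new("GeneOrder", name = order@name, labels = g$labels,
        signs = g$signs, meta = order@meta)
}

## ---- reporting labels ---------------------------------------------------

#' Classify an event with the field's acronyms
#'
#' \code{I} inversion, \code{t} transposition, \code{it} inverse
#' transposition, \code{TDRL} completed tandem duplication random loss,
#' \code{TD-PRL}/\code{Tri-PRL} duplication/triplication with partial
#' random loss (some elements stay duplicated), \code{TD}/\code{TriD}
#' plain duplication/triplication, \code{PRL} partial random loss,
#' \code{loss}.
#'
#' @param event RearrangementEvent.
#' @return character acronym.
#' @export
eventKindLabel <- function(event) {
    switch(event@kind,
        inversion = "I", transposition = "t",
        inverse_transposition = "it",
        td = "TD", trid = "TriD", prl = "PRL", loss = "loss",
        tdrl = {
            cs <- colSums(event@keep)
            tri <- nrow(event@keep) == 3L
            if (all(cs == nrow(event@keep))) (if (tri) "TriD" else "TD")
            else if (all(cs == 1L)) "TDRL"
            else if (tri) "Tri-PRL" else "TD-PRL"
        })
}

setMethod("show", "RearrangementEvent", function(object) {
    cat("RearrangementEvent <", eventKindLabel(object), "> ", sep = "")
    if (length(object@seg))
        cat("segment [", object@seg[1], "..", object@seg[2], "]", sep = "")
    if (!is.na(object@at)) cat(" -> after", object@at)
    if (length(object@drop))
        cat("drop {", paste(object@drop, collapse = ","), "}")
    cat("\n")
})

setMethod("show", "EventPath", function(object) {
    cat("EventPath:", if (!is.na(object@source@name)) object@source@name
        else "<order>", "->",
        if (!is.na(object@target@name)) object@target@name else "<order>",
        "| cost", object@cost, "|",
        length(object@events), "event(s):",
        paste(vapply(object@events, eventKindLabel, character(1)),
              collapse = " + "), "\n")
})
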