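## Ancestral gene-order reconstruction: Sankoff dynamic programming over
## a finite candidate state pool, event counting, homoplasy detection,
## and topology comparison.

## directed pairwise cost matrix + representative paths over a state pool
.poolDistances <- function(pool, model, poolDepth, region, searchCap) {
    nm <- names(pool)
    k <- length(nm)
    D <- matrix(Inf, k, k, dimnames = list(nm, nm))
    diag(D) <- 0
    P <- vector("list", k * k)
    dim(P) <- c(k, k); dimnames(P) <- list(nm, nm)
    for (a in nm) for (b in nm) {
        if (a == b) next
        paths <- tryCatch(
            inferEvents(pool[[a]], pool[[b]], model, maxDepth = poolDepth,
                        region = region, searchCap = searchCap,
                        maxPaths = 8L),
            error = function(e) list())
        if (length(paths)) {
            D[a, b] <- paths[[1]]@cost
            P[[a, b]] <- paths[[1]]
        }
    }
    ## transitive closure through the pool (Floyd-Warshall), keeping a
    ## concatenated representative path for closed pairs
    for (m in nm) for (a in nm) for (b in nm) {
        if (a == b || a == m || b == m) next
        alt <- D[a, m] + D[m, b]
        if (alt < D[a, b]) {
            D[a, b] <- alt
            P[[a, b]] <- newEventPath(
                pool[[a]], pool[[b]],
                c(P[[a, m]]@events, P[[m, b]]@events), cost = alt)
        }
    }
    list(D = D, P = P)
}

#' Reconstruct ancestral gene orders on a fixed phylogeny
#'
#' Sankoff dynamic programming over a finite candidate state pool (the
#' observed tip orders plus optional extra states such as unsampled
#' intermediates), with directed edge costs from [eventDistance()]
#' computed at \code{poolDepth} and closed transitively through the pool.
#' All co-optimal root-to-tip assignments are enumerated (up to
#' \code{maxCoOptimal}); the primary assignment picks, at every tie, the
#' lexicographically smallest state name (deterministic tabulation).
#'
#' @param tree rooted \code{phylo} object; tip labels must match
#'   \code{names(tips)}.
#' @param tips named list of GeneOrder (or named character vector of
#'   names of [notoGeneOrders()] fixtures).
#' @param model an [eventModel()].
#' @param poolDepth maximum direct search depth between pool states;
#'   longer transitions are composed through the pool.
#' @param extraStates list of additional candidate GeneOrder states
#'   (e.g. the pre-inversion Trematominae intermediate).
#' @param region search region passed to [inferEvents()].
#' @param searchCap per-pair state cap.
#' @param maxCoOptimal cap on enumerated co-optimal assignments.
#' @return an [AncestralAssignment-class].
#' @export
#' @examples
#' \donttest{
#' tips <- notoTipOrders()
#' rec <- reconstructAncestral(notoReferenceTree(), tips,
#'     extraStates = notoGeneOrders("TremaIntGO"))
#' totalEventCount(rec)
#' }
reconstructAncestral <- function(tree, tips, model = eventModel(),
                                 poolDepth = 2L, extraStates = list(),
                                 region = "auto", searchCap = 200000L,
                                 maxCoOptimal = 64L) {
    if (is.character(tips)) {
        lib <- notoGeneOrders()
        tips <- setNames(lib[tips], names(tips))
    }
    if (is.null(names(tips)) || !all(tree$tip.label %in% names(tips)))
        stop("every tip needs an assigned gene order; missing: ",
             paste(setdiff(tree$tip.label, names(tips)), collapse = ", "))
    tips <- tips[tree$tip.label]
    ## candidate pool: distinct observed orders + extras
    pool <- list()
    addState <- function(o) {
        key <- .goKey(.goCanonical(.goFromS4(o)))
        hit <- vapply(pool, function(p)
            identical(.goKey(.goCanonical(.goFromS4(p))), key), logical(1))
        if (any(hit)) return(names(pool)[which(hit)[1]])
        nm <- if (!is.na(o@name)) o@name else paste0("state", length(pool) + 1L)
        while (nm %in% names(pool)) nm <- paste0(nm, "'")
        pool[[nm]] <<- o
        nm
    }
    tipState <- vapply(tips, addState, character(1))
    for (o in extraStates) addState(o)
    pd <- .poolDistances(pool, model, poolDepth, region, searchCap)
    D <- pd$D
    nm <- names(pool)
    unreached <- which(!is.finite(D), arr.ind = TRUE)
    if (nrow(unreached)) {
        bad <- unique(apply(unreached, 1, function(ij)
            paste(nm[ij[1]], "->", nm[ij[2]])))
        stop("state pair(s) unreachable within poolDepth even through ",
             "the pool: ", paste(bad, collapse = "; "),
             "; raise poolDepth or supply intermediate extraStates")
    }
    ## Sankoff DP (directed costs parent -> child)
    ntip <- length(tree$tip.label)
    nnode <- tree$Nnode
    nN <- ntip + nnode
    kids <- split(tree$edge[, 2], tree$edge[, 1])
    root <- ntip + 1L
    S <- matrix(Inf, nN, length(nm), dimnames = list(NULL, nm))
    for (i in seq_len(ntip)) S[i, tipState[i]] <- 0
    ## postorder: children are settled before their parent
    po <- reorder(tree, "postorder")$edge
    for (v in unique(po[, 1])) {
        for (s in seq_along(nm)) {
            tot <- 0
            for (ch in kids[[as.character(v)]])
                tot <- tot + min(D[s, ] + S[ch, ])
            S[v, s] <- tot
        }
    }
    totalCost <- min(S[root, ])
    ## backtracking: primary (lexicographic) + co-optimal enumeration
    pickChild <- function(parentState, ch) {
        costs <- D[parentState, ] + S[ch, ]
        names(costs)[costs == min(costs)]
    }
    rootChoices <- sort(nm[S[root, ] == totalCost])
    assignPrimary <- function() {
        st <- character(nN)
        st[root] <- rootChoices[1]
        walk <- function(v) {
            for (ch in kids[[as.character(v)]]) {
                st[ch] <<- sort(pickChild(st[v], ch))[1]
                if (ch > ntip) walk(ch)
            }
        }
        walk(root)
        st
    }
    states <- assignPrimary()
    coOpt <- list()
    enumerate <- function(st, todo) {
        if (length(coOpt) >= maxCoOptimal) return()
        if (!length(todo)) {
            coOpt[[length(coOpt) + 1L]] <<- st
            return()
        }
        v <- todo[1]
        ## expand node v's children jointly
        chs <- kids[[as.character(v)]]
        rec2 <- function(i, st2) {
            if (length(coOpt) >= maxCoOptimal) return()
            if (i > length(chs)) {
                enumerate(st2, c(todo[-1], chs[chs > ntip]))
                return()
            }
            for (s in pickChild(st2[v], chs[i])) {
                st3 <- st2; st3[chs[i]] <- s
                rec2(i + 1L, st3)
            }
        }
        rec2(1L, st)
    }
    for (rs in rootChoices) {
        st0 <- character(nN); st0[root] <- rs
        enumerate(st0, root)
        if (length(coOpt) >= maxCoOptimal) break
    }
    ## edge table + paths for the primary assignment
    ed <- tree$edge
    edges <- data.frame(parent = ed[, 1], child = ed[, 2],
                        parentState = states[ed[, 1]],
                        childState = states[ed[, 2]],
                        cost = NA_real_, nEvents = NA_integer_,
                        kinds = NA_character_,
                        childLabel = ifelse(ed[, 2] <= ntip,
                                            tree$tip.label[ed[, 2]],
                                            paste0("node", ed[, 2])),
                        stringsAsFactors = FALSE)
    paths <- vector("list", nrow(edges))
    for (r in seq_len(nrow(edges))) {
        a <- edges$parentState[r]; b <- edges$childState[r]
        if (a == b) {
            edges$cost[r] <- 0; edges$nEvents[r] <- 0L
            edges$kinds[r] <- ""
            paths[[r]] <- newEventPath(pool[[a]], pool[[b]], list(), 0)
        } else {
            p <- pd$P[[a, b]]
            edges$cost[r] <- p@cost
            edges$nEvents[r] <- length(p@events)
            edges$kinds[r] <- paste(vapply(p@events, eventKindLabel,
                                           character(1)), collapse = "+")
            paths[[r]] <- p
        }
    }
    new("AncestralAssignment", tree = tree, states = states, pool = pool,
        edges = edges, paths = paths, totalCost = totalCost,
        coOptimal = coOpt, distances = D)
}

setMethod("show", "AncestralAssignment", function(object) {
    cat("AncestralAssignment over", length(object@pool),
        "candidate states\n")
    cat("  total event cost:", object@totalCost, "|",
        length(object@coOptimal), "co-optimal assignment(s) enumerated\n")
    ch <- object@edges[object@edges$cost > 0, ]
    for (r in seq_len(nrow(ch)))
        cat(sprintf("  %s -> %s on edge to %s (%s)\n", ch$parentState[r],
                    ch$childState[r], ch$childLabel[r], ch$kinds[r]))
})

#' Total event count and per-kind breakdown of an assignment
#'
#' @param assignment an [AncestralAssignment-class].
#' @return list with \code{total} (number of events across all edges of
#'   the primary assignment) and \code{byKind} (named table).
#' @export
totalEventCount <- function(assignment) {
    kinds <- unlist(lapply(assignment@paths, function(p)
        vapply(p@events, eventKindLabel, character(1))))
    list(total = length(kinds),
         byKind = if (length(kinds)) table(kinds) else table(character()))
}

#' Detect homoplastic gene orders (independent parallel origins)
#'
#' A gene order is homoplastic iff it is derived (differs from the parent
#' state) on two or more edges that do not lie on a single root-to-tip
#' path. With \code{acrossCoOptimal = TRUE} (default) the report is the
#' union over all enumerated co-optimal assignments, mirroring the fact
#' that any of them is an equally parsimonious history.
#'
#' @param assignment an [AncestralAssignment-class].
#' @param acrossCoOptimal union over co-optimal assignments.
#' @return data.frame with columns \code{state}, \code{nOrigins},
#'   \code{edges} (semicolon-joined child labels of the origin edges in
#'   the assignment attaining \code{nOrigins}).
#' @export
detectHomoplasy <- function(assignment, acrossCoOptimal = TRUE) {
    tree <- assignment@tree
    ntip <- length(tree$tip.label)
    desc <- .descendantsMap(tree)
    lab <- function(v) if (v <= ntip) tree$tip.label[v] else paste0("node", v)
    ed <- assignment@tree$edge
    assignments <- list(assignment@states)
    if (acrossCoOptimal && length(assignment@coOptimal))
        assignments <- assignment@coOptimal
    best <- list()
    for (st in assignments) {
        derived <- which(st[ed[, 1]] != st[ed[, 2]])
        for (s in unique(st[ed[derived, 2]])) {
            eds <- derived[st[ed[derived, 2]] == s]
            if (length(eds) < 2L) next
            ## independent iff no origin edge child is an ancestor of
            ## another origin edge's child
            ch <- ed[eds, 2]
            indep <- eds
            nested <- vapply(seq_along(ch), function(i)
                any(ch[-i] %in% desc[[ch[i]]]), logical(1))
            ## count maximal set of mutually independent origins
            nOr <- sum(!nested) + 0L
            if (nOr < 2L) next
            prev <- best[[s]]
            if (is.null(prev) || nOr > prev$nOrigins)
                best[[s]] <- list(nOrigins = nOr,
                                  edges = paste(vapply(ed[eds, 2], lab,
                                                       character(1)),
                                                collapse = ";"))
        }
    }
    if (!length(best))
        return(data.frame(state = character(), nOrigins = integer(),
                          edges = character(), stringsAsFactors = FALSE))
    data.frame(state = names(best),
               nOrigins = vapply(best, `[[`, integer(1), "nOrigins"),
               edges = vapply(best, `[[`, character(1), "edges"),
               row.names = NULL, stringsAsFactors = FALSE)
}

## node -> all descendant nodes (excluding itself)
.descendantsMap <- function(tree) {
    nN <- length(tree$tip.label) + tree$Nnode
    desc <- vector("list", nN)
    po <- reorder(tree, "postorder")$edge
    for (r in seq_len(nrow(po))) {
        p <- po[r, 1]; ch <- po[r, 2]
        desc[[p]] <- c(desc[[p]], ch, desc[[ch]])
    }
    desc
}

#' Compare ancestral reconstructions on two topologies
#'
#' Runs [reconstructAncestral()] on both trees (same tip set) and reports
#' whether the inferred pathway sets are identical: same multiset of
#' parent-to-child gene-order transitions (with event-kind signatures)
#' and same total cost.
#'
#' @param treeA,treeB rooted \code{phylo} objects over the same tips.
#' @param tips named list of GeneOrder (or fixture-name character vector).
#' @param ... passed to [reconstructAncestral()].
#' @return list with \code{assignmentA}, \code{assignmentB},
#'   \code{identicalPathways} (logical), \code{transitionsA},
#'   \code{transitionsB}.
#' @export
compareTopologies <- function(treeA, treeB, tips, ...) {
    if (!setequal(treeA$tip.label, treeB$tip.label))
        stop("topologies must share the same tip set")
    recA <- reconstructAncestral(treeA, tips, ...)
    recB <- reconstructAncestral(treeB, tips, ...)
    trans <- function(rec) {
        ch <- rec@edges[rec@edges$cost > 0, ]
        sort(paste(ch$parentState, "->", ch$childState, "[", ch$kinds, "]"))
    }
    tA <- trans(recA); tB <- trans(recB)
    list(assignmentA = recA, assignmentB = recB,
         identicalPathways = identical(tA, tB) &&
             recA@totalCost == recB@totalCost,
         transitionsA = tA, transitionsB = tB)
}
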