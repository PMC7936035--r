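## Minimal event-path inference between gene orders: breadth-first search
## over rearrangement-operator expansions, with an exhaustive mode (small
## windows) and a target-guided mode (surplus/deficit and
## adjacency-repair pruning) for larger searches.

## ---- plain event application (hot path) --------------------------------
## e: list(kind, i, j, at, keep, drop)

.applyE <- function(g, e) {
    n <- length(g$labels)
    kind <- e$kind
    if (kind == "prl")
        return(.go(g$labels[-e$drop], g$signs[-e$drop]))
    i <- e$i; j <- e$j; sel <- i:j
    if (kind == "inversion") {
        g$labels[sel] <- rev(g$labels[sel])
        g$signs[sel] <- -rev(g$signs[sel])
        return(g)
    }
    if (kind == "loss")
        return(.go(g$labels[-sel], g$signs[-sel]))
    if (kind == "transposition" || kind == "inverse_transposition") {
        segl <- g$labels[sel]; segs <- g$signs[sel]
        if (kind == "inverse_transposition") {
            segl <- rev(segl); segs <- -rev(segs)
        }
        rl <- g$labels[-sel]; rs <- g$signs[-sel]
        pos <- if (e$at > j) e$at - length(sel) else e$at
        return(.go(append(rl, segl, after = pos),
                   append(rs, segs, after = pos)))
    }
    ## tdrl / td / trid
    keep <- e$keep
    newl <- newsgn <- vector("list", nrow(keep))
    for (cpy in seq_len(nrow(keep))) {
        w <- keep[cpy, ]
        newl[[cpy]] <- g$labels[sel][w]
        newsgn[[cpy]] <- g$signs[sel][w]
    }
    .go(c(if (i > 1L) g$labels[1:(i - 1L)], unlist(newl),
          if (j < n) g$labels[(j + 1L):n]),
        c(if (i > 1L) g$signs[1:(i - 1L)], unlist(newsgn),
          if (j < n) g$signs[(j + 1L):n]))
}

.plain2ev <- function(e) {
    new("RearrangementEvent", kind = e$kind,
        seg = if (!is.null(e$i)) c(e$i, e$j) else integer(),
        at = if (!is.null(e$at)) as.integer(e$at) else NA_integer_,
        copies = if (!is.null(e$keep) && nrow(e$keep))
            nrow(e$keep) else NA_integer_,
        keep = if (!is.null(e$keep)) e$keep else matrix(logical(), 0, 0),
        drop = if (!is.null(e$drop)) as.integer(e$drop) else integer())
}

.ev2plain <- function(ev) {
    list(kind = ev@kind,
         i = if (length(ev@seg)) ev@seg[1] else NULL,
         j = if (length(ev@seg)) ev@seg[2] else NULL,
         at = if (!is.na(ev@at)) ev@at else NA_integer_,
         keep = if (nrow(ev@keep)) ev@keep else NULL,
         drop = if (length(ev@drop)) ev@drop else NULL)
}

## deterministic sort key for an event
.evKey <- function(e) {
    paste(e$kind,
          if (!is.null(e$i)) sprintf("%03d-%03d", e$i, e$j) else "",
          if (!is.null(e$at) && !is.na(e$at)) sprintf("%03d", e$at) else "",
          if (!is.null(e$keep)) paste(as.integer(e$keep), collapse = "") else "",
          if (!is.null(e$drop)) paste(e$drop, collapse = ".") else "")
}

## ---- pattern enumeration helpers ---------------------------------------

## all tdrl keep-matrices for a block of k elements, two copies. The
## random-loss phase trims each copy to a contiguous retained block (an
## interleaved retention pattern is representable as a duplication plus
## further events); the two blocks must cover the whole segment (every
## element keeps >= 1 copy) and each block spans >= 2 elements, so that
## a duplication is never operationally identical to a single-gene move.
## Identity results (prefix/suffix partitions) and the full duplication
## (the TD kind) are excluded.
.tdrlPatterns <- function(k) {
    key <- paste0("k", k)
    cache <- .mitoCache$tdrl
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- list()
    if (k >= 2L) {
        blocks <- list()
        for (a in 1:k) for (b in a:k)
            if (b - a + 1L >= 2L) blocks[[length(blocks) + 1L]] <- c(a, b)
        for (b1 in blocks) for (b2 in blocks) {
            cover <- logical(k)
            cover[b1[1]:b1[2]] <- TRUE
            cover[b2[1]:b2[2]] <- TRUE
            if (!all(cover)) next
            if (b1[2] + 1L == b2[1] || (b1[1] == 1L && b1[2] == k &&
                b2[1] == 1L && b2[2] == k)) next  # identity / plain TD
            k1 <- k2 <- logical(k)
            k1[b1[1]:b1[2]] <- TRUE
            k2[b2[1]:b2[2]] <- TRUE
            out[[length(out) + 1L]] <- rbind(k1, k2)
        }
    }
    .mitoCache$tdrl[[key]] <- out
    out
}

## prl drop-sets: for each duplicated label choose a subset of its copies
## to drop, leaving >= 1; returns list of integer position vectors
.prlDropSets <- function(labels, win, keepAtLeast = NULL) {
    dupLabs <- unique(labels[duplicated(labels)])
    perLab <- list()
    for (lab in dupLabs) {
        pos <- which(labels == lab)
        inWin <- pos[pos >= win[1] & pos <= win[2]]
        if (!length(inWin)) next
        c0 <- length(pos)
        minKeep <- max(1L, if (is.null(keepAtLeast)) 1L
                       else keepAtLeast[lab])
        if (is.na(minKeep)) minKeep <- 1L
        maxDrop <- min(length(inWin), c0 - minKeep)
        if (maxDrop < 1L) next
        subs <- list(integer())
        for (sz in seq_len(maxDrop))
            subs <- c(subs, combn(inWin, sz, simplify = FALSE))
        perLab[[lab]] <- subs
    }
    if (!length(perLab)) return(list())
    combos <- Reduce(function(acc, subs) {
        out <- list()
        for (a in acc) for (s in subs)
            out[[length(out) + 1L]] <- c(a, s)
        out
    }, perLab, accumulate = FALSE, right = FALSE,
       init = list(integer()))
    combos <- Filter(length, combos)
    lapply(combos, sort)
}

## adjacency keys of a state (linear, canonical orientation)
.adjKeys <- function(g) {
    n <- length(g$labels)
    if (n < 2L) return(character())
    a <- paste0(g$signs[-n], g$labels[-n], "|", g$signs[-1], g$labels[-1])
    c(a, paste0(g$signs[n], g$labels[n], "|", g$signs[1], g$labels[1]))
}

## ---- neighbor enumeration ----------------------------------------------

## guide: NULL for exhaustive, else list(counts = target label counts,
## adj = target adjacency key set, signs = representative target sign per
## label, slack = remaining depth - 1)
.enumNeighbors <- function(g, model, winLabs, guide = NULL,
                           winPos = NULL) {
    n <- length(g$labels)
    win <- if (!is.null(winPos)) winPos else .windowPos(g, winLabs)
    if (is.null(win)) return(list())
    wi <- win[1]; wj <- win[2]
    if (wi > wj) return(list())
    kinds <- model$kinds
    out <- vector("list", 4096L); nout <- 0L
    add <- function(e) {
        nout <<- nout + 1L
        if (nout > length(out)) length(out) <<- 2L * length(out)
        out[[nout]] <<- e
    }
    deficit <- NULL
    elv <- paste0(g$signs, g$labels)
    elvInv <- paste0(-g$signs, g$labels)
    at1 <- function(pos) elv[((pos - 1L) %% n) + 1L]  # circular lookup
    tgtNew <- NULL; fixCum <- defCum <- NULL
    if (!is.null(guide)) {
        cnt <- table(g$labels)
        labs <- union(names(cnt), names(guide$counts))
        cc <- setNames(as.integer(cnt[labs]), labs); cc[is.na(cc)] <- 0L
        tt <- setNames(as.integer(guide$counts[labs]), labs)
        tt[is.na(tt)] <- 0L
        deficit <- tt - cc
        tgtNew <- setdiff(guide$adj, .adjKeys(g))
        ts <- guide$signs[g$labels]; ts[is.na(ts)] <- 0L
        fixable <- g$signs != 0L & ts != 0L & g$signs != ts
        fixCum <- cumsum(fixable)
        defpos <- deficit[g$labels] > 0L
        defpos[is.na(defpos)] <- FALSE
        defCum <- cumsum(defpos)
    }
    rangeAny <- function(cum, i, j)
        (cum[j] - if (i > 1L) cum[i - 1L] else 0L) > 0L

    ## inversions: admissible (guided) if they fix a strand mismatch or
    ## create a target adjacency at a boundary
    if ("inversion" %in% kinds) {
        for (i in wi:wj) for (j in i:wj) {
            if (!is.null(guide)) {
                ok <- rangeAny(fixCum, i, j) ||
                    paste0(at1(i - 1L), "|", elvInv[j]) %in% tgtNew ||
                    paste0(elvInv[i], "|", at1(j + 1L)) %in% tgtNew
                if (!ok) next
            }
            add(list(kind = "inversion", i = i, j = j))
        }
    }
    ## transpositions / inverse transpositions: admissible (guided) only
    ## if they create a target adjacency (at a new junction or by sealing
    ## the excision site)
    for (kind in intersect(c("transposition", "inverse_transposition"),
                           kinds)) {
        inv <- kind == "inverse_transposition"
        for (i in wi:wj) for (j in i:wj) {
            ats <- (wi - 1L):wj
            ats <- ats[ats < i - 1L | ats > j]
            if (!length(ats)) next
            if (!is.null(guide)) {
                seal <- paste0(at1(i - 1L), "|", at1(j + 1L)) %in% tgtNew
                if (!seal) {
                    segFirst <- if (inv) elvInv[j] else elv[i]
                    segLast <- if (inv) elvInv[i] else elv[j]
                    ok <- paste0(at1(ats), "|", segFirst) %in% tgtNew |
                          paste0(segLast, "|", at1(ats + 1L)) %in% tgtNew
                    ats <- ats[ok]
                    if (!length(ats)) next
                }
            }
            for (at in ats)
                add(list(kind = kind, i = i, j = j, at = at))
        }
    }
    ## tandem duplications with random loss (+ plain TD / TriD)
    if (any(c("tdrl", "td", "trid") %in% kinds)) {
        for (i in wi:wj) {
            maxj <- min(wj, i + model$maxDup - 1L)
            for (j in i:maxj) {
                k <- j - i + 1L
                if (!is.null(guide) && !rangeAny(defCum, i, j)) next
                segLabs <- g$labels[i:j]
                if ("td" %in% kinds)
                    add(list(kind = "td", i = i, j = j,
                             keep = matrix(TRUE, 2L, k)))
                if ("trid" %in% kinds && k <= model$maxTri)
                    add(list(kind = "trid", i = i, j = j,
                             keep = matrix(TRUE, 3L, k)))
                if ("tdrl" %in% kinds && k >= 2L) {
                    ## guided searches keep tdrl patterns strict at every
                    ## level: a pattern may only duplicate labels the
                    ## target still lacks (plain TD/TriD, cleaned up by a
                    ## later PRL, cover overshooting intermediates)
                    strict <- !is.null(guide)
                    segDef <- if (strict) deficit[segLabs] else NULL
                    for (keep in .tdrlPatterns(k)) {
                        if (strict) {
                            extra <- colSums(keep) - 1L
                            if (any(extra > 0L)) {
                                ## partial pattern: may only duplicate
                                ## labels the target still lacks
                                gain <- tapply(extra, segLabs, sum)
                                sd <- segDef[!duplicated(segLabs)]
                                if (any(gain > sd[names(gain)],
                                        na.rm = TRUE)) next
                                if (!any(gain > 0L & sd[names(gain)] > 0L,
                                         na.rm = TRUE)) next
                            }
                            ## completed patterns (block swaps) are
                            ## content-neutral and always admissible
                        }
                        add(list(kind = "tdrl", i = i, j = j, keep = keep))
                    }
                }
            }
        }
    }
    ## partial random loss of redundant copies
    if ("prl" %in% kinds) {
        keepAtLeast <- if (!is.null(guide)) guide$counts else NULL
        drops <- .prlDropSets(g$labels, c(wi, wj), keepAtLeast)
        for (d in drops) add(list(kind = "prl", drop = d))
    }
    out[seq_len(nout)]
}

## all drop-position sets turning g into tgt by element deletion
## (embeddings of tgt as a subsequence of g), capped
.embedDrops <- function(g, tgt, cap = 25L) {
    gl <- paste0(g$signs, g$labels)
    tl <- paste0(tgt$signs, tgt$labels)
    nd <- length(gl) - length(tl)
    if (nd <= 0L) return(list())
    out <- list()
    rec <- function(gi, ti, drops) {
        if (length(out) >= cap) return()
        remG <- length(gl) - gi + 1L
        remT <- length(tl) - ti + 1L
        if (remG < remT || length(drops) + (remG - remT) > nd) return()
        if (ti > length(tl)) {
            if (gi <= length(gl)) drops <- c(drops, gi:length(gl))
            if (length(drops) == nd)
                out[[length(out) + 1L]] <<- drops
            return()
        }
        if (gl[gi] == tl[ti]) rec(gi + 1L, ti + 1L, drops)
        if (length(drops) < nd) rec(gi + 1L, ti, c(drops, gi))
    }
    rec(1L, 1L, integer())
    out
}

## events that turn g into the target in exactly ONE step; exact and
## cheap (candidates are derived from the mismatch region, not
## enumerated blindly), used for depth-1 searches and the final level of
## guided searches
.completionEvents <- function(g, tgt, model, winLabs, guide) {
    win <- .windowPos(g, winLabs)
    if (is.null(win) || win[1] > win[2]) return(list())
    cnt <- table(g$labels)
    labs <- union(names(cnt), names(guide$counts))
    cc <- setNames(as.integer(cnt[labs]), labs); cc[is.na(cc)] <- 0L
    tt <- setNames(as.integer(guide$counts[labs]), labs); tt[is.na(tt)] <- 0L
    d <- tt - cc
    pos <- labs[d > 0L]; neg <- labs[d < 0L]
    if (length(pos) && length(neg)) return(list())  # no event gains & loses
    kinds <- model$kinds
    if (length(neg) && !length(pos)) {
        ## one prl: target must be a subsequence of g
        if (!"prl" %in% kinds) return(list())
        drops <- .embedDrops(g, tgt)
        drops <- Filter(function(dr) all(dr >= win[1] & dr <= win[2]),
                        drops)
        return(lapply(drops, function(dr)
            list(kind = "prl", drop = sort(dr))))
    }
    sameAs <- function(g2)
        identical(g2$labels, tgt$labels) && identical(g2$signs, tgt$signs)
    ## locate the mismatch region of g vs tgt
    gl <- paste0(g$signs, g$labels); tl <- paste0(tgt$signs, tgt$labels)
    ng <- length(gl); nt <- length(tl)
    p <- 0L
    while (p < min(ng, nt) && gl[p + 1L] == tl[p + 1L]) p <- p + 1L
    s <- 0L
    while (s < min(ng, nt) - p && gl[ng - s] == tl[nt - s]) s <- s + 1L
    out <- list()
    if (length(pos)) {
        ## one duplication: the duplicated segment must start at or just
        ## before the first mismatch and reach at least the last one
        if (!any(c("tdrl", "td", "trid") %in% kinds)) return(list())
        iLo <- max(win[1], ng - s - model$maxDup + 1L)
        iHi <- min(p + 1L, win[2])
        if (iLo > iHi) return(list())
        for (i in iLo:iHi) {
            jLo <- max(i, ng - s)
            jHi <- min(win[2], i + model$maxDup - 1L)
            if (jLo > jHi) next
            for (j in jLo:jHi) {
                k <- j - i + 1L
                cand <- list()
                if ("td" %in% kinds)
                    cand <- c(cand, list(list(kind = "td", i = i, j = j,
                                              keep = matrix(TRUE, 2L, k))))
                if ("trid" %in% kinds && k <= model$maxTri)
                    cand <- c(cand, list(list(kind = "trid", i = i, j = j,
                                              keep = matrix(TRUE, 3L, k))))
                if ("tdrl" %in% kinds)
                    cand <- c(cand, lapply(.tdrlPatterns(k), function(kp)
                        list(kind = "tdrl", i = i, j = j, keep = kp)))
                for (e in cand)
                    if (sameAs(.applyE(g, e)))
                        out[[length(out) + 1L]] <- e
            }
        }
        return(out)
    }
    ## content equal: a single neutral event; after trimming the common
    ## flanks it must be the relocation (+/- inversion) of a block at one
    ## end of the mismatch region, or an inversion spanning it
    if (ng != nt) return(list())
    m <- ng - s - p
    if (m < 1L) return(list())
    A <- list(labels = g$labels[(p + 1L):(ng - s)],
              signs = g$signs[(p + 1L):(ng - s)])
    B <- list(labels = tgt$labels[(p + 1L):(ng - s)],
              signs = tgt$signs[(p + 1L):(ng - s)])
    iA <- p + 1L; jA <- ng - s
    inWin <- function(i, j, at) i >= win[1] && j <= win[2] &&
        at >= win[1] - 1L && at <= win[2]
    eq <- function(la, sa, lb, sb) identical(la, lb) && identical(sa, sb)
    rc <- function(x, idx) list(l = rev(x$labels[idx]),
                                s = -rev(x$signs[idx]))
    if ("inversion" %in% kinds &&
        eq(rev(A$labels), -rev(A$signs), B$labels, B$signs) &&
        inWin(iA, jA, iA - 1L))
        out[[length(out) + 1L]] <- list(kind = "inversion", i = iA, j = jA)
    for (L in seq_len(max(0L, m - 1L))) {
        hd <- seq_len(L); tl2 <- (m - L + 1L):m
        restA_hd <- (L + 1L):m; restB_hd <- seq_len(m - L)
        ## head block moved to the right end
        if ("transposition" %in% kinds &&
            eq(A$labels[hd], A$signs[hd], B$labels[tl2], B$signs[tl2]) &&
            eq(A$labels[restA_hd], A$signs[restA_hd],
               B$labels[restB_hd], B$signs[restB_hd]) &&
            inWin(iA, iA + L - 1L, jA))
            out[[length(out) + 1L]] <-
                list(kind = "transposition", i = iA, j = iA + L - 1L,
                     at = jA)
        ## tail block moved to the left end
        if ("transposition" %in% kinds &&
            eq(A$labels[tl2], A$signs[tl2], B$labels[hd], B$signs[hd]) &&
            eq(A$labels[restB_hd], A$signs[restB_hd],
               B$labels[restA_hd], B$signs[restA_hd]) &&
            inWin(jA - L + 1L, jA, iA - 1L))
            out[[length(out) + 1L]] <-
                list(kind = "transposition", i = jA - L + 1L, j = jA,
                     at = iA - 1L)
        if ("inverse_transposition" %in% kinds) {
            rcHd <- rc(A, hd); rcTl <- rc(A, tl2)
            if (eq(rcHd$l, rcHd$s, B$labels[tl2], B$signs[tl2]) &&
                eq(A$labels[restA_hd], A$signs[restA_hd],
                   B$labels[restB_hd], B$signs[restB_hd]) &&
                inWin(iA, iA + L - 1L, jA))
                out[[length(out) + 1L]] <-
                    list(kind = "inverse_transposition", i = iA,
                         j = iA + L - 1L, at = jA)
            if (eq(rcTl$l, rcTl$s, B$labels[hd], B$signs[hd]) &&
                eq(A$labels[restB_hd], A$signs[restB_hd],
                   B$labels[restA_hd], B$signs[restA_hd]) &&
                inWin(jA - L + 1L, jA, iA - 1L))
                out[[length(out) + 1L]] <-
                    list(kind = "inverse_transposition", i = jA - L + 1L,
                         j = jA, at = iA - 1L)
        }
    }
    out
}

## window anchors -> positions; anchors are labels that every state on a
## search path retains. winLabs = NULL means the whole order (minus the
## canonical start anchor at position 1); an NA right anchor means "to
## the end of the order".
.windowPos <- function(g, winLabs) {
    n <- length(g$labels)
    if (is.null(winLabs)) return(c(2L, n))
    iL <- which(g$labels == winLabs[1])[1]
    if (is.na(iL)) return(NULL)
    if (is.na(winLabs[2])) return(c(iL + 1L, n))
    iR <- which(g$labels == winLabs[2])
    iR <- iR[length(iR)]
    if (!length(iR)) return(NULL)
    c(iL + 1L, iR - 1L)
}

## auto window: labels flanking the differing region of two canonical
## orders (longest common prefix/suffix on sign+label pairs), padded by
## the maximum duplication length so that duplication segments reaching
## into the conserved flanks stay searchable.
.autoWindow <- function(ga, gb, pad = 6L) {
    pa <- paste0(ga$signs, ga$labels); pb <- paste0(gb$signs, gb$labels)
    na <- length(pa); nb <- length(pb)
    p <- 0L
    while (p < min(na, nb) && pa[p + 1L] == pb[p + 1L]) p <- p + 1L
    s <- 0L
    while (s < min(na, nb) - p && pa[na - s] == pb[nb - s]) s <- s + 1L
    if (p == 0L) return(NULL)        # should not happen (cox1 anchor)
    wL <- max(2L, p + 1L - pad)
    wR <- min(na, na - s + pad)
    left <- ga$labels[wL - 1L]
    right <- if (wR < na) ga$labels[wR + 1L] else NA_character_
    c(left, right)
}

## ---- BFS ----------------------------------------------------------------

.searchPaths <- function(src, tgt, model, maxDepth, winLabs, mode,
                         searchCap, maxPaths) {
    skey <- .goKey(src); tkey <- .goKey(tgt)
    if (identical(skey, tkey))
        return(list(found = TRUE, depth = 0L, paths = list(list())))
    guide <- NULL
    if (mode == "guided") {
        guide <- list(counts = table(tgt$labels), adj = .adjKeys(tgt),
                      signs = local({
                          s <- tapply(tgt$signs, tgt$labels,
                                      function(x) x[1])
                          storage.mode(s) <- "integer"; s
                      }),
                      slack = 0L)
    }
    states <- new.env(parent = emptyenv())
    assign(skey, list(g = src, depth = 0L, preds = list()), envir = states)
    frontier <- skey
    nStates <- 1L
    foundDepth <- NA_integer_
    for (depth in seq_len(maxDepth)) {
        if (!is.na(foundDepth)) break
        newFrontier <- character()
        for (fk in frontier) {
            st <- get(fk, envir = states)
            if (!is.null(guide)) guide$slack <- maxDepth - depth
            ## at the last level of a guided search, construct completing
            ## events directly instead of expanding blindly
            nb <- if (!is.null(guide) && depth == maxDepth)
                .completionEvents(st$g, tgt, model, winLabs, guide)
            else .enumNeighbors(st$g, model, winLabs, guide)
            for (e in nb) {
                g2 <- .applyE(st$g, e)
                k2 <- .goKey(g2)
                if (exists(k2, envir = states)) {
                    s2 <- get(k2, envir = states)
                    if (s2$depth == depth) {
                        s2$preds[[length(s2$preds) + 1L]] <-
                            list(pkey = fk, e = e)
                        assign(k2, s2, envir = states)
                    }
                } else {
                    nStates <- nStates + 1L
                    if (nStates > searchCap)
                        stop("search space cap exceeded (", searchCap,
                             " states); raise searchCap or narrow the region",
                             call. = FALSE)
                    assign(k2, list(g = g2, depth = depth,
                                    preds = list(list(pkey = fk, e = e))),
                           envir = states)
                    newFrontier[[length(newFrontier) + 1L]] <- k2
                }
                if (k2 == tkey) foundDepth <- depth
            }
        }
        frontier <- newFrontier
        if (!length(frontier) && is.na(foundDepth)) break
    }
    if (is.na(foundDepth))
        return(list(found = FALSE, depth = NA_integer_, paths = list()))
    ## backtrack all minimal paths
    paths <- list()
    walk <- function(key, suffix) {
        if (length(paths) >= maxPaths) return()
        if (key == skey) {
            paths[[length(paths) + 1L]] <<- suffix
            return()
        }
        st <- get(key, envir = states)
        for (p in st$preds)
            walk(p$pkey, c(list(p$e), suffix))
    }
    walk(tkey, list())
    list(found = TRUE, depth = foundDepth, paths = paths)
}

## ---- public API ---------------------------------------------------------

#' Infer minimal rearrangement event paths between two gene orders
#'
#' Breadth-first search over rearrangement-operator expansions under an
#' [eventModel()], returning all minimal paths (up to \code{maxPaths}),
#' sorted by a deterministic key. The search is restricted to the region
#' of the order where the two arrangements differ (\code{region =
#' "auto"}), to an explicit label-delimited slice such as
#' \code{c("nad5","F")} (the notothenioid hot spot), or runs unrestricted
#' (\code{region = NULL} searches everything downstream of the canonical
#' start anchor).
#'
#' For single-step searches the expansion is exhaustive; deeper searches
#' use a target-guided expansion (only events that shrink the
#' surplus/deficit of element copies, repair a target adjacency, or fix a
#' strand mismatch), which keeps multi-event searches tractable.
#' \code{mode} overrides this choice.
#'
#' @param source,target GeneOrder objects (canonicalizable).
#' @param model an [eventModel()].
#' @param maxDepth maximum number of events (>= 1).
#' @param region \code{"auto"}, a length-2 label vector, or NULL.
#' @param mode \code{"auto"}, \code{"exhaustive"} or \code{"guided"}.
#' @param searchCap maximum number of explored states before an explicit
#'   truncation error is raised.
#' @param maxPaths cap on the number of returned co-minimal paths.
#' @return list of [EventPath-class]; empty if no path within depth.
#' @export
#' @examples
#' go <- notoGeneOrders()
#' p <- inferEvents(go$Noto1GO, go$DissoGO)
#' p[[1]]
inferEvents <- function(source, target, model = eventModel(),
                        maxDepth = 3L, region = "auto", mode = "auto",
                        searchCap = 200000L, maxPaths = 100L) {
    gs <- .goCanonical(.goFromS4(source))
    gt <- .goCanonical(.goFromS4(target))
    winLabs <- if (is.null(region)) NULL
        else if (identical(region, "auto"))
            .autoWindow(gs, gt, pad = model$maxDup)
        else as.character(region)
    if (identical(.goKey(gs), .goKey(gt))) {
        return(list(new("EventPath", source = source, target = target,
                        events = list(), cost = 0)))
    }
    res <- NULL
    for (depth in seq_len(maxDepth)) {
        m <- if (mode == "auto") "guided" else mode
        res <- .searchPaths(gs, gt, model, depth, winLabs, m, searchCap,
                            maxPaths)
        if (res$found) break
    }
    if (!res$found) return(list())
    paths <- res$paths
    ord <- order(vapply(paths, function(p)
        paste(vapply(p, .evKey, character(1)), collapse = ";"),
        character(1)))
    paths <- paths[ord]
    lapply(paths, function(p) {
        evs <- lapply(p, .plain2ev)
        cost <- sum(model$costs[vapply(p, `[[`, character(1), "kind")])
        newEventPath(source, target, evs, cost)
    })
}

#' Construct (and replay-validate) an EventPath
#'
#' @param source,target GeneOrder.
#' @param events list of RearrangementEvent.
#' @param cost total cost; defaults to the number of events.
#' @return EventPath; errors if replaying \code{events} on \code{source}
#'   does not yield \code{target}.
#' @export
newEventPath <- function(source, target, events, cost = length(events)) {
    cur <- canonicalizeOrder(source)
    for (ev in events) cur <- applyEvent(cur, ev)
    if (!ordersEqual(cur, target))
        stop("event path replay does not reproduce the target order")
    new("EventPath", source = source, target = target, events = events,
        cost = cost)
}

#' Minimal event cost between two gene orders
#'
#' @inheritParams inferEvents
#' @return integer cost, or NA (sentinel: unreached within
#'   \code{maxDepth}).
#' @export
eventDistance <- function(source, target, model = eventModel(),
                          maxDepth = 3L, region = "auto", mode = "auto",
                          searchCap = 200000L) {
    p <- inferEvents(source, target, model, maxDepth, region, mode,
                     searchCap, maxPaths = 1L)
    if (!length(p)) return(NA_integer_)
    as.integer(p[[1]]@cost)
}
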