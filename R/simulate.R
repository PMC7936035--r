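## Mitogenome simulator: VertGO ancestor with realistic element lengths,
## sequence evolution with strand-asymmetric substitution (deamination
## bias), per-gene purifying selection (omega accept/reject), scripted
## rearrangement events along a tree with decaying pseudogene remnants,
## and a machine-readable truth log.

## deterministic substream seed from the master seed and a name
.subSeed <- function(seed, name) {
    h <- 0
    for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147480009
    as.integer((seed * 7919 + h) %% 2147480009)
}

.withSubstream <- function(seed, name, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    set.seed(.subSeed(seed, name))
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    force(expr)
}

#' Simulator configuration
#'
#' Free parameters of the mitogenome simulator. Lengths approximate the
#' canonical vertebrate values (whole genome about 16.5 kb); the
#' substitution model is HKY-like (transition/transversion ratio
#' \code{kappa}) with two strand-asymmetry multipliers emulating
#' hydrolytic deamination of the heavy strand (A->G and C->T on the
#' heavy strand, i.e. T->C and G->A on the deposited majority-coding
#' strand), which drives the positive AT-skew / negative GC-skew of
#' unrearranged mitogenomes; per-gene omega values set the strength of
#' purifying selection used for Ka/Ks simulations; remnant parameters
#' control pseudogene decay inside rearrangement-derived spacers.
#'
#' @param seed mandatory master seed; every stochastic component draws
#'   from a named substream of it.
#' @param geneScale scale factor on all element lengths (smaller, faster
#'   genomes for calibration studies).
#' @param kappa transition/transversion rate ratio.
#' @param deamAG,deamCT heavy-strand deamination multipliers.
#' @param omega named per-gene nonsynonymous acceptance probabilities;
#'   defaults span strong (cox1) to relaxed (atp8) purifying selection.
#' @param remnantDecay substitutions per site per unit branch length
#'   applied to pseudogenized copies on top of the neutral process.
#' @param remnantDeletion per-site deletion-chunk initiation probability
#'   per unit branch length (chunk length geometric, mean 4 nt).
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(seed, geneScale = 1, kappa = 4,
                      deamAG = 2, deamCT = 6,
                      omega = NULL, remnantDecay = 0.05,
                      remnantDeletion = 0.01) {
    stopifnot(!missing(seed))
    pcgLen <- c(cox1 = 1551, cox2 = 690, cox3 = 786, atp6 = 684,
                atp8 = 168, cob = 1140, nad1 = 975, nad2 = 1047,
                nad3 = 348, nad4 = 1380, nad4L = 297, nad5 = 1839,
                nad6 = 522)
    om <- c(cox1 = 0.03, cox2 = 0.06, cox3 = 0.06, atp6 = 0.08,
            atp8 = 0.45, cob = 0.08, nad1 = 0.12, nad2 = 0.18,
            nad3 = 0.18, nad4 = 0.15, nad4L = 0.20, nad5 = 0.15,
            nad6 = 0.35)
    if (!is.null(omega)) om[names(omega)] <- omega
    structure(list(seed = as.integer(seed), geneScale = geneScale,
                   pcgLen = pcgLen, trnaLen = 70L, rrnSLen = 950L,
                   rrnLLen = 1680L, coreLen = 930L, olLen = 35L,
                   kappa = kappa, deamAG = deamAG, deamCT = deamCT,
                   omega = om, remnantDecay = remnantDecay,
                   remnantDeletion = remnantDeletion),
              class = "SimConfig")
}

## third-position / neutral base composition of the deposited strand:
## modest positive AT-skew, strongly negative GC-skew (the typical
## vertebrate mitogenome pattern); near the mutational equilibrium so
## unrearranged lineages keep their skew signs
.simBaseFreqs <- c(A = 0.32, C = 0.36, G = 0.12, T = 0.20)

## first/second codon position composition (mildly biased; third
## positions and neutral elements use .simBaseFreqs)
.simPos12Freqs <- c(A = 0.28, C = 0.26, G = 0.22, T = 0.24)

## nucleotide substitution rate matrix on the deposited strand for a
## genome of given polarity (+1 typical; -1 after a Control Region
## inversion flips the replication asymmetry). Asymmetric deamination of
## the heavy strand appears on the deposited strand as T->C and G->A.
.simRates <- function(config, polarity = 1L) {
    b <- c("A", "C", "G", "T")
    R <- matrix(1, 4, 4, dimnames = list(b, b))
    R["A", "G"] <- R["G", "A"] <- R["C", "T"] <- R["T", "C"] <- config$kappa
    if (polarity >= 0) {
        R["T", "C"] <- R["T", "C"] * config$deamCT
        R["G", "A"] <- R["G", "A"] * config$deamAG
    } else {
        R["C", "T"] <- R["C", "T"] * config$deamCT
        R["A", "G"] <- R["A", "G"] * config$deamAG
    }
    diag(R) <- 0
    R / mean(rowSums(R))
}

## evolve integer-coded sequence x (1..4) for branch length b (expected
## substitutions per site, roughly); elements with omega < 1 use
## codon-aware accept/reject; returns integer vector
.evolveSeq <- function(x, b, R, omega = 1, isPCG = FALSE) {
    if (length(x) == 0L || b <= 0) return(x)
    code <- .mitoCode()
    bases <- c("A", "C", "G", "T")
    out <- rowSums(R)
    nRounds <- max(1L, ceiling(b / 0.08))
    pRound <- b / nRounds
    for (rnd in seq_len(nRounds)) {
        pSite <- pmin(1, pRound * out[x] / mean(out))
        hit <- which(runif(length(x)) < pSite)
        if (!length(hit)) next
        for (i in hit) {
            probs <- R[x[i], ]
            nb <- sample.int(4L, 1L, prob = probs)
            if (isPCG) {
                ci <- ((i - 1L) %/% 3L)
                cod <- x[(ci * 3L + 1L):(ci * 3L + 3L)]
                newcod <- cod; newcod[i - ci * 3L] <- nb
                aaOld <- code[[paste(bases[cod], collapse = "")]]
                aaNew <- code[[paste(bases[newcod], collapse = "")]]
                if (aaNew == "*") next
                if (aaNew != aaOld && runif(1) > omega) next
            }
            x[i] <- nb
        }
    }
    x
}

.seq2int <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
.int2seq <- function(x) paste(c("A", "C", "G", "T")[x], collapse = "")

## random in-frame coding sequence without internal stops; third
## positions follow the neutral (near-equilibrium) composition so that
## synonymous-site pools start with the typical strand bias
.randomCDS <- function(nCodon, freqs) {
    code <- .mitoCode()
    n <- nCodon - 2L
    b <- names(freqs)
    mk <- function(m) paste0(sample(b, m, TRUE, .simPos12Freqs),
                             sample(b, m, TRUE, .simPos12Freqs),
                             sample(b, m, TRUE, freqs))
    body <- mk(n)
    repeat {
        bad <- which(code[body] == "*")
        if (!length(bad)) break
        body[bad] <- mk(length(bad))
    }
    paste0("ATG", paste(body, collapse = ""), "TAA")
}

.randomSeq <- function(n, freqs)
    paste(sample(names(freqs), n, replace = TRUE, prob = freqs),
          collapse = "")

#' Simulate a VertGO ancestor genome
#'
#' Builds an annotated mitogenome in the typical vertebrate arrangement
#' with realistic element lengths (about 16.5 kb at \code{geneScale =
#' 1}), protein-coding genes as valid ORFs under the vertebrate
#' mitochondrial code, and the typical strand-compositional bias.
#'
#' @param config a [simConfig()].
#' @return list of class \code{SimGenome}: element table (label, sign,
#'   type, sequence in sense orientation), per-gap spacer sequences,
#'   genome polarity, and the assembled [AnnotatedGenome-class]
#'   (accessible via [assembleGenome()]).
#' @export
simulateAncestor <- function(config) {
    v <- notoGeneOrders("VertGO")[[1]]
    labs <- orderLabels(v); signs <- orderSigns(v)
    types <- .elementType(labs)
    sc <- config$geneScale
    .withSubstream(config$seed, "ancestor", {
        elems <- lapply(seq_along(labs), function(i) {
            lab <- labs[i]; ty <- types[i]
            len <- switch(ty,
                PCG = max(30L, round(config$pcgLen[[lab]] * sc / 3)) * 3L,
                tRNA = max(15L, round(config$trnaLen * sc)),
                rRNA = if (lab == "rrnS")
                    max(30L, round(config$rrnSLen * sc))
                    else max(30L, round(config$rrnLLen * sc)),
                control_region = max(30L, round(config$coreLen * sc)),
                origin = max(15L, round(config$olLen * sc)))
            seq <- if (ty == "PCG") .randomCDS(len %/% 3L, .simBaseFreqs)
                   else .randomSeq(len, .simBaseFreqs)
            list(label = lab, sign = signs[i], type = ty, seq = seq)
        })
        structure(list(elems = elems,
                       spacers = rep("", length(elems)),
                       remnants = list(), polarity = 1L,
                       id = "ancestor", config = config),
                  class = "SimGenome")
    })
}

#' Assemble a simulated genome into an AnnotatedGenome
#'
#' Concatenates element sequences (L-strand elements are
#' reverse-complemented into the deposited strand) and the spacer
#' sequences that follow them, producing the feature table in 0-based
#' half-open coordinates.
#'
#' @param sim a \code{SimGenome}.
#' @param identifier genome identifier.
#' @return [AnnotatedGenome-class].
#' @export
assembleGenome <- function(sim, identifier = sim$id) {
    pos <- 0L
    rows <- list(); seqParts <- character()
    for (i in seq_along(sim$elems)) {
        el <- sim$elems[[i]]
        len <- nchar(el$seq)
        seqParts[[length(seqParts) + 1L]] <-
            if (el$sign < 0L) .revcomp(el$seq) else el$seq
        rows[[i]] <- data.frame(
            label = el$label, strand = if (el$sign < 0L) "L" else "H",
            start = pos, end = pos + len, type = el$type,
            stringsAsFactors = FALSE)
        pos <- pos + len
        sp <- sim$spacers[[i]]
        if (nzchar(sp)) {
            seqParts[[length(seqParts) + 1L]] <- sp
            pos <- pos + nchar(sp)
        }
    }
    annotatedGenome(identifier, paste(seqParts, collapse = ""),
                    do.call(rbind, rows), checkTranslation = FALSE)
}

#' Gene order of a simulated genome
#'
#' @param sim a \code{SimGenome}.
#' @return canonical [GeneOrder-class].
#' @export
simGeneOrder <- function(sim) {
    geneOrder(vapply(sim$elems, `[[`, character(1), "label"),
              vapply(sim$elems, `[[`, integer(1), "sign"),
              name = sim$id)
}

## apply a rearrangement event to a SimGenome (sequence level); dropped
## copies become spacer remnants; an inversion containing the Control
## Region flips the genome polarity
.applySimEvent <- function(sim, ev) {
    n <- length(sim$elems)
    labelsNow <- vapply(sim$elems, `[[`, character(1), "label")
    dropToRemnant <- function(sim, dropIdx) {
        keepIdx <- setdiff(seq_along(sim$elems), dropIdx)
        for (runStart in split(dropIdx, cumsum(c(1, diff(dropIdx) != 1)))) {
            anchor <- max(keepIdx[keepIdx < runStart[1]], 0L)
            rem <- paste(vapply(runStart, function(i) {
                el <- sim$elems[[i]]
                if (el$sign < 0L) .revcomp(el$seq) else el$seq
            }, character(1)), collapse = "")
            remLab <- paste(labelsNow[runStart], collapse = "+")
            if (anchor == 0L) anchor <- keepIdx[1]
            sim$remnants[[length(sim$remnants) + 1L]] <-
                list(after = labelsNow[anchor], source = remLab,
                     length = nchar(rem))
            sim$spacers[[anchor]] <- paste0(sim$spacers[[anchor]], rem)
        }
        sim$elems <- sim$elems[keepIdx]
        sim$spacers <- c(sim$spacers[keepIdx])
        sim
    }
    kind <- ev@kind
    if (kind %in% c("prl", "loss")) {
        drop <- if (kind == "prl") ev@drop else ev@seg[1]:ev@seg[2]
        return(dropToRemnant(sim, sort(drop)))
    }
    if (kind == "inversion") {
        i <- ev@seg[1]; j <- ev@seg[2]
        seg <- sim$elems[i:j]
        seg <- rev(lapply(seg, function(el) {
            el$sign <- -el$sign; el
        }))
        sim$elems[i:j] <- seg
        sim$spacers[i:j] <- vapply(rev(sim$spacers[i:j]), function(s)
            if (nzchar(s)) .revcomp(s) else s, character(1))
        if (any(vapply(seg, `[[`, character(1), "label") == "CoRe"))
            sim$polarity <- -sim$polarity
        return(sim)
    }
    if (kind %in% c("transposition", "inverse_transposition")) {
        i <- ev@seg[1]; j <- ev@seg[2]; at <- ev@at
        idx <- seq_along(sim$elems)
        seg <- i:j
        rest <- setdiff(idx, seg)
        pos <- if (at > j) at - length(seg) else at
        newOrder <- append(rest, seg, after = pos)
        if (kind == "inverse_transposition") {
            sim$elems[seg] <- rev(lapply(sim$elems[seg], function(el) {
                el$sign <- -el$sign; el
            }))
        }
        sim$elems <- sim$elems[newOrder]
        sim$spacers <- sim$spacers[newOrder]
        return(sim)
    }
    if (kind %in% c("tdrl", "td", "trid")) {
        i <- ev@seg[1]; j <- ev@seg[2]
        keep <- ev@keep
        newElems <- list(); newSpacers <- character()
        pre <- if (i > 1L) 1:(i - 1L) else integer()
        post <- if (j < n) (j + 1L):n else integer()
        for (cpy in seq_len(nrow(keep))) {
            kept <- which(keep[cpy, ])
            dropped <- which(!keep[cpy, ])
            ## dropped run(s) of this copy become a remnant attached to
            ## the previous kept element (or the element before the
            ## segment)
            for (idx2 in kept) {
                newElems[[length(newElems) + 1L]] <-
                    sim$elems[[i + idx2 - 1L]]
                newSpacers[[length(newSpacers) + 1L]] <- ""
            }
            if (length(dropped)) {
                rem <- paste(vapply(dropped, function(d) {
                    el <- sim$elems[[i + d - 1L]]
                    if (el$sign < 0L) .revcomp(el$seq) else el$seq
                }, character(1)), collapse = "")
                at <- length(newElems)
                tgtIdx <- if (at > 0L) at else NA_integer_
                if (!is.na(tgtIdx)) {
                    newSpacers[[tgtIdx]] <-
                        paste0(newSpacers[[tgtIdx]], rem)
                    sim$remnants[[length(sim$remnants) + 1L]] <-
                        list(after = newElems[[tgtIdx]]$label,
                             source = paste(labelsNow[i + dropped - 1L],
                                            collapse = "+"),
                             length = nchar(rem))
                }
            }
        }
        sim$elems <- c(sim$elems[pre], newElems, sim$elems[post])
        sim$spacers <- c(sim$spacers[pre], newSpacers, sim$spacers[post])
        return(sim)
    }
    stop("unsupported event kind in simulator: ", kind)
}

## mutate every element/spacer of a SimGenome along a branch
.mutateSim <- function(sim, b, config) {
    if (b <= 0) return(sim)
    R <- .simRates(config, sim$polarity)
    for (i in seq_along(sim$elems)) {
        el <- sim$elems[[i]]
        ## element sequences are stored in sense orientation; elements
        ## on the L-strand see the mirrored asymmetry
        Ruse <- if (el$sign < 0L) .simRates(config, -sim$polarity) else R
        x <- .seq2int(el$seq)
        isP <- el$type == "PCG"
        om <- if (isP) config$omega[[el$label]] else 1
        if (is.null(om) || is.na(om)) om <- 1
        x <- .evolveSeq(x, b, Ruse, om, isP)
        sim$elems[[i]]$seq <- .int2seq(x)
        sp <- sim$spacers[[i]]
        if (nzchar(sp)) {
            y <- .seq2int(sp)
            y <- .evolveSeq(y, b, Ruse)
            ## extra pseudogene decay: substitutions + deletion chunks
            y <- .evolveSeq(y, config$remnantDecay * b * 10, Ruse)
            delP <- config$remnantDeletion * b * 10
            if (delP > 0 && length(y) > 5L) {
                starts <- which(runif(length(y)) < delP)
                if (length(starts)) {
                    dropIdx <- unique(unlist(lapply(starts, function(s)
                        s:min(length(y), s + stats::rgeom(1, 0.25)))))
                    if (length(dropIdx) < length(y) - 5L)
                        y <- y[-dropIdx]
                }
            }
            sim$spacers[[i]] <- .int2seq(y)
        }
    }
    sim
}

#' Evolve a simulated genome along a tree with scripted events
#'
#' Recursively descends the (rooted) tree from the ancestor: on every
#' branch the sequences evolve under the strand-asymmetric substitution
#' model scaled by branch length, scripted rearrangement events are
#' applied at their branches (each duplication initially leaves complete
#' extra copies; losses convert dropped copies into spacer remnants that
#' decay from then on), and a truth log records planted events, node
#' gene orders and the remnant registry.
#'
#' @param ancestor a \code{SimGenome} from [simulateAncestor()].
#' @param tree rooted \code{phylo}; if it has no branch lengths,
#'   \code{defaultBranch} is used for every edge.
#' @param events named list: child node label (tip label or
#'   \code{"nodeN"}) -> list of [RearrangementEvent-class] applied at
#'   the start of that branch.
#' @param config the [simConfig()].
#' @param defaultBranch branch length (expected substitutions/site) when
#'   the tree has none.
#' @return list with \code{tips} (named list of \code{SimGenome}),
#'   \code{genomes} (named list of [AnnotatedGenome-class]) and
#'   \code{truth} (nodeOrders, events, remnants data.frame).
#' @export
evolveOnTree <- function(ancestor, tree, events = list(), config,
                         defaultBranch = 0.05) {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    lens <- if (!is.null(tree$edge.length)) tree$edge.length
            else rep(defaultBranch, nrow(tree$edge))
    nodeName <- function(v) if (v <= ntip) tree$tip.label[v]
                            else paste0("node", v)
    badBranch <- setdiff(names(events),
                         vapply(seq_len(ntip + tree$Nnode), nodeName,
                                character(1)))
    if (length(badBranch))
        stop("event script references absent branch(es): ",
             paste(badBranch, collapse = ", "))
    kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
    truth <- list(nodeOrders = list(), events = events,
                  remnants = list())
    tips <- list()
    rec <- function(v, sim) {
        nm <- nodeName(v)
        sim$id <- nm
        truth$nodeOrders[[nm]] <<- simGeneOrder(sim)
        if (v <= ntip) { tips[[nm]] <<- sim; return(invisible()) }
        for (e in kids[[as.character(v)]]) {
            ch <- tree$edge[e, 2]
            chName <- nodeName(ch)
            csim <- sim
            evs <- events[[chName]]
            if (!is.null(evs))
                .withSubstream(config$seed, paste0("events.", chName), {
                    for (ev in evs) csim <- .applySimEvent(csim, ev)
                })
            csim <- .withSubstream(config$seed, paste0("branch.", chName),
                                   .mutateSim(csim, lens[e], config))
            rec(ch, csim)
        }
    }
    rec(root, ancestor)
    remn <- do.call(rbind, lapply(names(tips), function(nm) {
        rl <- tips[[nm]]$remnants
        if (!length(rl)) return(NULL)
        data.frame(genome = nm,
                   after = vapply(rl, `[[`, character(1), "after"),
                   source = vapply(rl, `[[`, character(1), "source"),
                   length = vapply(rl, `[[`, numeric(1), "length"),
                   stringsAsFactors = FALSE)
    }))
    truth$remnants <- if (is.null(remn))
        data.frame(genome = character(), after = character(),
                   source = character(), length = numeric(),
                   stringsAsFactors = FALSE) else remn
    genomes <- lapply(tips, assembleGenome)
    list(tips = tips, genomes = genomes, truth = truth)
}

#' Generate null spacers (random composition)
#'
#' I.i.d. sequences for calibrating the spacer scanner's false-positive
#' rate.
#'
#' @param n number of spacers.
#' @param length spacer length (nt).
#' @param composition base probabilities (A, C, G, T).
#' @param seed seed.
#' @return character vector.
#' @export
makeNullSpacers <- function(n, length,
                            composition = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                            seed = 1L) {
    if (n == 0L) return(character())
    .withSubstream(seed, "nullspacers",
        vapply(seq_len(n), function(i) .randomSeq(length, composition),
               character(1)))
}

#' Sample a random plantable rearrangement event
#'
#' Draws an event from the default model's repertoire (inversion,
#' transposition, inverse transposition, duplication with partial
#' random loss, partial random loss of redundant copies), with segment
#' positions concentrated in the nad5-trnF region (the notothenioid
#' rearrangement hot spot) and guaranteed to change the order.
#'
#' @param order canonical GeneOrder to plant into.
#' @param model an [eventModel()].
#' @param region length-2 label vector delimiting the hot spot.
#' @return a [RearrangementEvent-class].
#' @export
samplePlantedEvent <- function(order, model = eventModel(),
                               region = c("nad5", "F")) {
    g <- .goCanonical(.goFromS4(order))
    win <- .windowPos(g, region)
    if (is.null(win)) win <- c(2L, length(g$labels))
    ## events stay strictly between the anchors, so the region bounds
    ## (nad5 and trnF by default) are never moved themselves
    wi <- max(2L, win[1]); wj <- win[2]
    if (wj < wi) stop("empty planting window")
    key0 <- .goKey(g)
    for (try in 1:200) {
        kind <- sample(c("inversion", "transposition",
                         "inverse_transposition", "td", "tdrl", "prl"),
                       1L)
        ev <- NULL
        if (kind == "prl") {
            dupPos <- which(g$labels %in% g$labels[duplicated(g$labels)])
            dupPos <- dupPos[dupPos >= wi & dupPos <= wj]
            if (!length(dupPos)) next
            k <- sample.int(min(2L, length(dupPos)), 1L)
            dr <- sort(dupPos[sample.int(length(dupPos), k)])
            cnt <- table(g$labels)
            if (any(table(g$labels[dr]) >= cnt[names(table(g$labels[dr]))]))
                next
            ev <- new("RearrangementEvent", kind = "prl",
                      drop = as.integer(dr), seg = integer(),
                      at = NA_integer_, copies = NA_integer_,
                      keep = matrix(logical(), 0, 0))
        } else {
            i <- (wi:wj)[sample.int(wj - wi + 1L, 1L)]
            maxLen <- if (kind %in% c("td", "tdrl"))
                min(model$maxDup, wj - i + 1L) else wj - i + 1L
            if (maxLen < 1L) next
            len <- sample.int(maxLen, 1L)
            j <- i + len - 1L
            if (kind %in% c("transposition", "inverse_transposition")) {
                ats <- setdiff(max(2L, wi - 1L):wj, (i - 1L):j)
                if (!length(ats)) next
                ev <- new("RearrangementEvent", kind = kind,
                          seg = c(i, j),
                          at = ats[sample.int(length(ats), 1L)],
                          copies = NA_integer_,
                          keep = matrix(logical(), 0, 0),
                          drop = integer())
            } else if (kind == "inversion") {
                ev <- new("RearrangementEvent", kind = "inversion",
                          seg = c(i, j), at = NA_integer_,
                          copies = NA_integer_,
                          keep = matrix(logical(), 0, 0),
                          drop = integer())
            } else if (kind == "td") {
                ev <- new("RearrangementEvent", kind = "td",
                          seg = c(i, j), at = NA_integer_, copies = 2L,
                          keep = matrix(TRUE, 2L, len), drop = integer())
            } else {
                ## plant only duplication patterns that retain at least
                ## one duplicated element: a completed TDRL is
                ## arrangement-identical to a transposition and hence
                ## unidentifiable as a duplication
                pats <- Filter(function(kp) any(colSums(kp) == nrow(kp)),
                               .tdrlPatterns(len))
                if (!length(pats)) next
                ev <- new("RearrangementEvent", kind = "tdrl",
                          seg = c(i, j), at = NA_integer_, copies = 2L,
                          keep = pats[[sample(length(pats), 1L)]],
                          drop = integer())
            }
        }
        g2 <- tryCatch(.applyE(g, .ev2plain(ev)), error = function(e) NULL)
        if (is.null(g2)) next
        g2 <- .goCanonical(g2)
        if (!identical(.goKey(g2), key0)) return(ev)
    }
    stop("could not sample a non-trivial event")
}

#' Scripted strand-reversal scenarios
#'
#' Three single-lineage scenarios exercising the full-reversal decision
#' rule: \code{"none"} -- no rearrangement, the genome keeps the typical
#' compositional bias; \code{"partial"} -- a Control Region inversion
#' flips the replication asymmetry shortly before sampling (branch
#' length 0.3 substitutions/site), long enough for the weakly biased
#' AT-skews to cross zero but not the strongly biased GC-skews (the
#' pattern of a recent inversion); \code{"full"} -- the same inversion
#' followed by a long branch (1.5 substitutions/site), past
#' re-equilibration of both skews. Branch lengths were chosen from the
#' substitution model's relaxation dynamics (from the shipped baseline
#' composition, AT4 crosses zero near b = 0.17 after a flip, GC4 near
#' b = 0.42).
#'
#' @param scenario one of "none", "partial", "full".
#' @param seed master seed.
#' @param geneScale genome scale factor (pool sizes grow with it).
#' @return list with \code{genome} ([AnnotatedGenome-class]),
#'   \code{degSets}, \code{decision} (the [decideReversal()] output).
#' @export
simulateReversalScenario <- function(scenario = c("none", "partial",
                                                  "full"),
                                     seed, geneScale = 0.5) {
    scenario <- match.arg(scenario)
    cfg <- simConfig(seed, geneScale = geneScale)
    anc <- simulateAncestor(cfg)
    b <- c(none = 0.3, partial = 0.3, full = 1.5)[[scenario]]
    sim <- anc
    if (scenario != "none") {
        v <- simGeneOrder(sim)
        ev <- rearrangementEvent("inversion",
                                 segment = c("CoRe", "CoRe"), order = v)
        sim <- .withSubstream(cfg$seed, "reversal.event",
                              .applySimEvent(sim, ev))
    }
    sim <- .withSubstream(cfg$seed, "reversal.branch",
                          .mutateSim(sim, b, cfg))
    sim$id <- paste0("reversal_", scenario)
    genome <- assembleGenome(sim)
    degSets <- extractDegenerateSets(genome)
    list(genome = genome, degSets = degSets,
         decision = decideReversal(degSets))
}
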