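## Independent oracle implementations used to cross-check the package's
## algorithms on small instances. These are deliberately written from
## scratch (plain depth-first enumeration, direct code-table
## transcription) and never call the package's search internals.

## ---- toy signed orders --------------------------------------------------

## random toy gene order over k distinct labels (always contains cox1 so
## canonicalization is anchored)
randomToyOrder <- function(k, name = NA_character_) {
  labs <- c("cox1", paste0("g", seq_len(k - 1L)))
  perm <- c(1L, 1L + sample(k - 1L))
  signs <- sample(c(1L, -1L), k, replace = TRUE)
  signs[perm == 1L] <- 1L
  geneOrder(labs[perm], signs, name = name)
}

## ---- brute-force event-path oracle --------------------------------------

## canonical string key, independent of the package internals
oracleKey <- function(order) {
  labs <- orderLabels(order); signs <- orderSigns(order)
  paste(ifelse(signs < 0, paste0("~", labs), labs), collapse = "/")
}

## enumerate every event of the restricted toy model (inversion,
## transposition, prl, tdrl with maxDup) as application FUNCTIONS on
## (labels, signs) pairs; independent of the package's enumerator
oracleMoves <- function(labs, signs, maxDup = 3L,
                        kinds = c("inversion", "transposition", "prl",
                                  "tdrl")) {
  n <- length(labs)
  moves <- list()
  addMove <- function(f) moves[[length(moves) + 1L]] <<- f
  if ("inversion" %in% kinds)
    for (i in 2:n) for (j in i:n)
      local({ i0 <- i; j0 <- j
        addMove(function(l, s) {
          l[i0:j0] <- rev(l[i0:j0]); s[i0:j0] <- -rev(s[i0:j0])
          list(l = l, s = s) }) })
  if ("transposition" %in% kinds)
    for (i in 2:n) for (j in i:n) for (at in c(1:n)) {
      if (at >= i - 1L && at <= j) next
      local({ i0 <- i; j0 <- j; at0 <- at
        addMove(function(l, s) {
          seg <- i0:j0
          nl <- l[-seg]; ns <- s[-seg]
          pos <- if (at0 > j0) at0 - length(seg) else at0
          list(l = append(nl, l[seg], after = pos),
               s = append(ns, s[seg], after = pos)) }) })
    }
  if ("prl" %in% kinds) {
    dup <- labs[duplicated(labs)]
    pos <- which(labs %in% dup)
    if (length(pos))
      for (sz in 1:min(3L, length(pos)))
        for (cmb in combn(pos, sz, simplify = FALSE)) {
          keepCnt <- table(labs[-cmb])
          if (!all(unique(labs) %in% names(keepCnt))) next
          local({ cmb0 <- cmb
            addMove(function(l, s)
              list(l = l[-cmb0], s = s[-cmb0])) })
        }
  }
  if ("tdrl" %in% kinds)
    for (i in 2:n) for (j in i:min(n, i + maxDup - 1L)) {
      k <- j - i + 1L
      if (k < 2L) next
      ## contiguous kept blocks (>=2 each) covering the segment
      blocks <- list()
      for (a in 1:k) for (b2 in a:k)
        if (b2 - a + 1L >= 2L) blocks[[length(blocks) + 1L]] <- c(a, b2)
      for (b1 in blocks) for (b2 in blocks) {
        cov <- logical(k); cov[b1[1]:b1[2]] <- TRUE
        cov[b2[1]:b2[2]] <- TRUE
        if (!all(cov)) next
        if (b1[2] + 1L == b2[1]) next
        if (b1[1] == 1L && b1[2] == k && b2[1] == 1L && b2[2] == k) next
        local({ i0 <- i; j0 <- j; k1 <- b1; k2 <- b2
          addMove(function(l, s) {
            seg <- i0:j0
            segL <- l[seg]; segS <- s[seg]
            midL <- c(segL[k1[1]:k1[2]], segL[k2[1]:k2[2]])
            midS <- c(segS[k1[1]:k1[2]], segS[k2[1]:k2[2]])
            list(l = c(l[seq_len(i0 - 1L)], midL,
                       if (j0 < length(l)) l[(j0 + 1L):length(l)]),
                 s = c(s[seq_len(i0 - 1L)], midS,
                       if (j0 < length(s)) s[(j0 + 1L):length(s)])) }) })
      }
    }
  moves
}

## oracle canonicalization: rotate to cox1, mirror if cox1 negative
oracleCanon <- function(l, s) {
  i <- which(l == "cox1")[1]
  if (s[i] < 0) { l <- rev(l); s <- -rev(s); i <- length(l) - i + 1L }
  ord <- c(i:length(l), if (i > 1L) 1:(i - 1L))
  list(l = l[ord], s = s[ord])
}

oracleLS2Key <- function(l, s)
  paste(ifelse(s < 0, paste0("~", l), l), collapse = "/")

## minimal number of events from src to tgt by plain breadth-first
## enumeration over ALL event sequences (no pruning); NA if unreached
oracleDistance <- function(src, tgt, maxDepth = 2L, maxDup = 3L,
                           kinds = c("inversion", "transposition",
                                     "prl", "tdrl")) {
  c0 <- oracleCanon(orderLabels(src), orderSigns(src))
  ct <- oracleCanon(orderLabels(tgt), orderSigns(tgt))
  tkey <- oracleLS2Key(ct$l, ct$s)
  frontier <- list(c0)
  seen <- oracleLS2Key(c0$l, c0$s)
  if (identical(seen, tkey)) return(0L)
  for (depth in seq_len(maxDepth)) {
    nxt <- list()
    for (st in frontier) {
      for (mv in oracleMoves(st$l, st$s, maxDup, kinds)) {
        r <- mv(st$l, st$s)
        r <- oracleCanon(r$l, r$s)
        key <- oracleLS2Key(r$l, r$s)
        if (key == tkey) return(depth)
        if (!key %in% seen) {
          seen <- c(seen, key)
          nxt[[length(nxt) + 1L]] <- r
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  NA_integer_
}

## ---- vertebrate mitochondrial code, transcribed independently ----------

## translation table 2, written out by hand (codon order TTT..GGG is not
## used; explicit pairs instead)
oracleMitoCode <- function() {
  aa <- c(
    TTT="F",TTC="F",TTA="L",TTG="L", CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="M",ATG="M", GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S", CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T", GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*", CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K", GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="W",TGG="W", CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="*",AGG="*", GGT="G",GGC="G",GGA="G",GGG="G")
  aa
}

## degeneracy class of every codon derived by enumeration from the
## transcribed table
oracleDegeneracy <- function(codon) {
  aa <- oracleMitoCode()
  if (aa[[codon]] == "*") return("other")
  pre <- substr(codon, 1, 2)
  third <- substr(codon, 3, 3)
  fam <- paste0(pre, c("A", "C", "G", "T"))
  syn <- fam[aa[fam] == aa[[codon]]]
  if (length(syn) == 4L) return("NNN4")
  if (identical(sort(syn), sort(paste0(pre, c("A", "G")))) &&
      third %in% c("A", "G")) return("NNR2")
  if (identical(sort(syn), sort(paste0(pre, c("C", "T")))) &&
      third %in% c("C", "T")) return("NNY2")
  "other"
}

## ---- Nei-Gojobori oracle ------------------------------------------------

## independent NG86 implementation: explicit site fractions and explicit
## recursion over substitution orderings
oracleNG86 <- function(a, b) {
  aa <- oracleMitoCode()
  bases <- c("A", "C", "G", "T")
  nc <- nchar(a) %/% 3L
  ca <- substring(a, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cb <- substring(b, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  keep <- aa[ca] != "*" & aa[cb] != "*" &
      !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  synSites <- function(cod) {
    s <- 0
    for (p in 1:3) for (bs in bases) {
      if (bs == substr(cod, p, p)) next
      mut <- cod; substr(mut, p, p) <- bs
      if (aa[[mut]] != "*" && aa[[mut]] == aa[[cod]]) s <- s + 1 / 3
    }
    s
  }
  S <- sum(vapply(ca, synSites, numeric(1)) +
           vapply(cb, synSites, numeric(1))) / 2
  N <- 3 * length(ca) - S
  countPair <- function(x, y) {
    if (x == y) return(c(0, 0))
    dpos <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    best <- NULL
    recur <- function(cur, remaining, sd, nd, stopped) {
      if (!length(remaining)) {
        best[[length(best) + 1L]] <<- c(sd, nd, stopped)
        return()
      }
      for (p in remaining) {
        nxt <- cur; substr(nxt, p, p) <- substr(y, p, p)
        hitStop <- stopped || aa[[nxt]] == "*"
        syn <- aa[[cur]] != "*" && aa[[nxt]] != "*" &&
            aa[[cur]] == aa[[nxt]]
        recur(nxt, setdiff(remaining, p),
              sd + as.numeric(syn), nd + as.numeric(!syn), hitStop)
      }
    }
    recur(x, dpos, 0, 0, FALSE)
    m <- do.call(rbind, best)
    ok <- m[, 3] == 0
    if (!any(ok)) ok <- rep(TRUE, nrow(m))
    c(mean(m[ok, 1]), mean(m[ok, 2]))
  }
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    d <- countPair(ca[i], cb[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

## ---- misc helpers -------------------------------------------------------

## small deterministic mutator for planting divergence in remnants
mutateSequence <- function(seq, divergence, seed) {
  set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  n <- max(0L, round(length(v) * divergence))
  if (n > 0) {
    idx <- sample(length(v), n)
    v[idx] <- vapply(v[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(v, collapse = "")
}

## brute-force Sankoff oracle: enumerate every assignment of pool states
## to internal nodes and take the minimum total edge cost under the same
## distance matrix
bruteMinCost <- function(tree, tipStates, D) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  pool <- colnames(D)
  grids <- rep(list(pool), nint)
  best <- Inf
  combo <- expand.grid(grids, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combo))) {
    st <- c(tipStates[tree$tip.label], as.character(combo[r, ]))
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      tot <- tot + D[st[p], st[ch]]
    }
    if (tot < best) best <- tot
  }
  best
}

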