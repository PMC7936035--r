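## Reading and writing annotated mitogenomes (TSV feature tables and a
## minimal GenBank flat-file dialect), newick trees, and result tables.
## Coordinate convention: 0-based half-open, circular; origin-spanning
## features carry end > genome length (interpreted modulo length).

#' Construct an AnnotatedGenome
#'
#' @param identifier species/accession string.
#' @param sequence character DNA string (deposited strand).
#' @param features data.frame with columns \code{label}, \code{strand}
#'   ("H"/"L"), \code{start}, \code{end} (0-based half-open, circular),
#'   \code{type}; rows are sorted by start.
#' @param completeness "complete" or "partial".
#' @param checkTranslation warn if a protein-coding feature does not
#'   translate cleanly (no internal stops) under the vertebrate
#'   mitochondrial code. A warning, not an error: partial genomes and
#'   decayed annotations are tolerated.
#' @return [AnnotatedGenome-class].
#' @export
annotatedGenome <- function(identifier, sequence, features,
                            completeness = "complete",
                            checkTranslation = TRUE) {
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
    obj <- new("AnnotatedGenome", identifier = identifier,
               sequence = toupper(sequence), features = features,
               completeness = completeness)
    if (checkTranslation) {
        for (r in which(features$type == "PCG")) {
            aa <- .translate2(featureSequence(obj, r))
            body <- substr(aa, 1, nchar(aa) - 1L)
            if (grepl("*", body, fixed = TRUE))
                warning(identifier, ": internal stop codon in ",
                        features$label[r],
                        if (completeness == "partial")
                            " (partial genome)" else "")
        }
    }
    obj
}

#' Accessors for AnnotatedGenome
#'
#' @param x an AnnotatedGenome.
#' @return \code{genomeFeatures}: the feature data.frame;
#'   \code{genomeSequence}: the sequence string; \code{genomeLength}:
#'   length in bp.
#' @export
genomeFeatures <- function(x) x@features

#' @rdname genomeFeatures
#' @export
genomeSequence <- function(x) x@sequence

#' @rdname genomeFeatures
#' @export
genomeLength <- function(x) nchar(x@sequence)

setMethod("show", "AnnotatedGenome", function(object) {
    cat("AnnotatedGenome", sQuote(object@identifier), "-",
        nchar(object@sequence), "bp,", nrow(object@features),
        "features (", object@completeness, ")\n")
})

#' Extract a feature's sequence in reading orientation
#'
#' Circular coordinates: an origin-spanning feature (end > genome length)
#' wraps around; L-strand features are reverse-complemented so the
#' returned string reads 5' to 3' in the gene's sense.
#'
#' @param genome AnnotatedGenome.
#' @param which feature row index or label (first match).
#' @return character DNA string.
#' @export
featureSequence <- function(genome, which) {
    f <- genome@features
    r <- if (is.character(which)) match(which, f$label) else which
    if (is.na(r) || r < 1L || r > nrow(f)) stop("no such feature: ", which)
    L <- nchar(genome@sequence)
    s <- f$start[r]; e <- f$end[r]
    seq <- if (e <= L) substr(genome@sequence, s + 1L, e)
           else paste0(substr(genome@sequence, s + 1L, L),
                       substr(genome@sequence, 1L, e - L))
    if (f$strand[r] == "L") .revcomp(seq) else seq
}

#' Read an annotated mitogenome
#'
#' Two dialects: \code{"tsv"} -- a tab-separated feature table (columns
#' \code{label}, \code{strand}, \code{start}, \code{end}, \code{type};
#' 0-based half-open coordinates) plus the sequence from a FASTA file;
#' \code{"genbank_flat"} -- a minimal GenBank flat-file parser covering
#' CDS/tRNA/rRNA/D-loop/rep_origin features with \code{/gene} or
#' \code{/product} qualifiers and an ORIGIN sequence block. Labels are
#' normalized through [normalizeLabels()].
#'
#' @param path feature table (tsv) or flat file (genbank_flat).
#' @param dialect \code{"tsv"} or \code{"genbank_flat"}.
#' @param fasta FASTA path holding the genome sequence (required for
#'   tsv; ignored for genbank_flat when the record has ORIGIN).
#' @param identifier genome identifier; defaults to the file/record name.
#' @param completeness "complete" or "partial".
#' @return [AnnotatedGenome-class].
#' @export
readFeatureTable <- function(path, dialect = c("tsv", "genbank_flat"),
                             fasta = NULL, identifier = NULL,
                             completeness = "complete") {
    dialect <- match.arg(dialect)
    if (dialect == "tsv") {
        f <- read.table(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
        need <- c("label", "strand", "start", "end", "type")
        if (!all(need %in% names(f)))
            stop("TSV feature table needs columns: ",
                 paste(need, collapse = ", "))
        f$start <- suppressWarnings(as.integer(f$start))
        f$end <- suppressWarnings(as.integer(f$end))
        if (any(is.na(f$start)) || any(is.na(f$end)))
            stop("malformed coordinates in feature table line(s): ",
                 paste(which(is.na(f$start) | is.na(f$end)), collapse = ","))
        if (is.null(fasta)) stop("tsv dialect needs `fasta`")
        seqs <- Biostrings::readDNAStringSet(fasta)
        sq <- as.character(seqs[[1]])
        f$label <- as.character(normalizeLabels(f$label))
        if (is.null(identifier))
            identifier <- sub("\\.[^.]*$", "", basename(path))
        return(annotatedGenome(identifier, sq, f, completeness))
    }
    .readGenbankFlat(path, identifier, completeness)
}

## minimal GenBank flat file parser (LOCUS/FEATURES/ORIGIN)
.readGenbankFlat <- function(path, identifier = NULL,
                             completeness = "complete") {
    lines <- readLines(path, warn = FALSE)
    if (is.null(identifier)) {
        loc <- grep("^LOCUS", lines, value = TRUE)
        identifier <- if (length(loc)) strsplit(loc[1], "\\s+")[[1]][2]
                      else sub("\\.[^.]*$", "", basename(path))
    }
    fStart <- grep("^FEATURES", lines)
    oStart <- grep("^ORIGIN", lines)
    if (!length(fStart)) stop("no FEATURES block")
    if (!length(oStart)) stop("no ORIGIN block")
    feat <- lines[(fStart + 1L):(oStart - 1L)]
    seqLines <- lines[(oStart + 1L):length(lines)]
    seqLines <- seqLines[!grepl("^//", seqLines)]
    sq <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
    typeMap <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                 D_loop = "control_region", misc_feature = "control_region",
                 rep_origin = "origin")
    isKey <- grepl("^\\s{5}\\S", feat)
    idx <- which(isKey)
    rows <- list()
    for (q in seq_along(idx)) {
        ln <- feat[idx[q]]
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        key <- sub("-", "_", parts[1], fixed = TRUE)
        if (!key %in% names(typeMap)) next
        locStr <- parts[2]
        comp <- grepl("complement", locStr)
        nums <- as.integer(regmatches(locStr,
                                      gregexpr("[0-9]+", locStr))[[1]])
        if (length(nums) < 2L)
            stop("malformed coordinates at line ", idx[q] + fStart, ": ",
                 trimws(ln))
        ## GenBank is 1-based closed; convert to 0-based half-open.
        ## join(a..L,1..b) denotes an origin-spanning feature.
        if (grepl("join", locStr) && length(nums) >= 4L) {
            start <- nums[1] - 1L; end <- nchar(sq) + nums[4]
        } else {
            start <- nums[1] - 1L; end <- nums[2]
        }
        end2 <- idx[q + 1L] - 1L
        if (q == length(idx)) end2 <- length(feat)
        quals <- feat[(idx[q] + 1L):end2]
        getQ <- function(name) {
            m <- grep(paste0("/", name, "="), quals, value = TRUE)
            if (!length(m)) return(NA_character_)
            gsub("\"", "", sub(paste0(".*?/", name, "="), "", m[1]))
        }
        lab <- getQ("gene")
        if (is.na(lab)) lab <- getQ("product")
        if (is.na(lab)) lab <- key
        rows[[length(rows) + 1L]] <- data.frame(
            label = lab, strand = if (comp) "L" else "H",
            start = start, end = end, type = typeMap[[key]],
            stringsAsFactors = FALSE)
    }
    f <- do.call(rbind, rows)
    ## a CDS plus gene pair produces duplicates; keep first occurrence
    f <- f[!duplicated(f[c("start", "end")]), , drop = FALSE]
    f$label <- as.character(normalizeLabels(f$label))
    annotatedGenome(identifier, sq, f, completeness)
}

#' Write an AnnotatedGenome as TSV feature table + FASTA
#'
#' Inverse of the tsv dialect of [readFeatureTable()]; reading back
#' reproduces the feature table exactly.
#'
#' @param genome AnnotatedGenome.
#' @param tsv,fasta output paths.
#' @export
writeFeatureTable <- function(genome, tsv, fasta = NULL) {
    write.table(genome@features, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(fasta)) {
        x <- Biostrings::DNAStringSet(genome@sequence)
        names(x) <- genome@identifier
        Biostrings::writeXStringSet(x, fasta)
    }
    invisible(tsv)
}

#' Read a rooted newick tree
#'
#' Thin wrapper over \code{ape::read.tree} with validation: the tree must
#' be rooted (or rootable on a supplied outgroup) and, when a genome set
#' is given, every tip must have a genome.
#'
#' @param path newick file (or a string containing "(" treated as
#'   newick text).
#' @param genomeIds optional character vector of available genome
#'   identifiers to validate tips against.
#' @param outgroup optional tip to root an unrooted input on.
#' @return rooted \code{phylo}.
#' @export
readNewickTree <- function(path, genomeIds = NULL, outgroup = NULL) {
    tr <- if (grepl("(", path, fixed = TRUE))
        ape::read.tree(text = path) else ape::read.tree(path)
    if (is.null(tr)) stop("cannot parse newick input")
    if (!ape::is.rooted(tr)) {
        if (is.null(outgroup))
            stop("tree is unrooted; supply `outgroup` to root it")
        tr <- ape::root(tr, outgroup, resolve.root = TRUE)
    }
    if (anyDuplicated(tr$tip.label))
        stop("duplicate tip names: ",
             paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                   collapse = ", "))
    if (!is.null(genomeIds)) {
        miss <- setdiff(tr$tip.label, genomeIds)
        if (length(miss))
            stop("tip name(s) absent from genome set: ",
                 paste(miss, collapse = ", "))
    }
    tr
}

#' Serialize result tables
#'
#' Loss-free serialization of the package's result data.frames (and
#' nested structures such as event paths) as TSV or JSON.
#'
#' @param tables a data.frame, or a named list of data.frames/lists.
#' @param path output file (TSV) or file/prefix (JSON).
#' @param format "tsv" or "json".
#' @export
writeReport <- function(tables, path, format = c("tsv", "json")) {
    format <- match.arg(format)
    if (format == "tsv") {
        if (!is.data.frame(tables))
            stop("tsv format needs a single data.frame")
        write.table(tables, path, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    } else {
        jsonlite::write_json(tables, path, auto_unbox = TRUE, digits = NA,
                             null = "null", na = "null", force = TRUE)
    }
    invisible(path)
}

#' Serialize an EventPath as a plain list (for JSON reports)
#'
#' @param path an [EventPath-class].
#' @return nested list with source/target notation strings and one
#'   record per event.
#' @export
eventPathRecord <- function(path) {
    list(source = formatGeneOrder(path@source),
         target = formatGeneOrder(path@target),
         cost = path@cost,
         events = lapply(path@events, function(e) {
             rec <- list(kind = eventKindLabel(e))
             if (length(e@seg)) rec$segment <- as.integer(e@seg)
             if (!is.na(e@at)) rec$insertion_point <- as.integer(e@at)
             if (length(e@drop)) rec$drop <- as.integer(e@drop)
             if (nrow(e@keep)) rec$keep <- apply(e@keep, 1, function(r)
                 paste(as.integer(r), collapse = ""))
             rec
         }))
}
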