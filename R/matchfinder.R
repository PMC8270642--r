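#' @useDynLib hgtmatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## canonical alphabet: uppercase, RNA folded to DNA, anything else N
.sanitizeDNA <- function(x) {
    x <- toupper(x)
    x <- chartr("U", "T", x)
    gsub("[^ACGT]", "N", x)
}

#' Build a ContigSet from sequences
#'
#' @param seqs A \code{DNAStringSet}, or a (preferably named) character
#'   vector of DNA sequences. Sequences are uppercased, U mapped to T and
#'   all remaining non-ACGT characters mapped to N.
#' @param taxonLabel Group label (e.g. genus name).
#' @param nGenomes Optional number of genomes the contigs represent.
#' @return A [ContigSet-class].
#' @examples
#' cs <- ContigSet(c(chr1 = "ACGTACGTACGT"), taxonLabel = "Escherichia")
#' totalLength(cs)
#' @export
ContigSet <- function(seqs, taxonLabel = "unnamed", nGenomes = NA_integer_) {
    if (is.character(seqs)) {
        if (is.null(names(seqs)) && length(seqs))
            names(seqs) <- paste0("contig", seq_along(seqs))
        seqs <- Biostrings::DNAStringSet(.sanitizeDNA(seqs))
    } else if (is(seqs, "DNAStringSet")) {
        seqs <- Biostrings::DNAStringSet(.sanitizeDNA(as.character(seqs)))
    } else {
        stop("'seqs' must be a character vector or DNAStringSet")
    }
    new("ContigSet", seqs = seqs, taxonLabel = taxonLabel,
        nGenomes = as.integer(nGenomes))
}

#' Read contigs from a FASTA file
#'
#' Reads a (possibly gzipped) multi-FASTA file, sanitises the sequences
#' (uppercase, U to T, non-ACGT to N) and drops contigs shorter than
#' \code{minContigLength}. Short contigs are excluded because they are more
#' likely to carry assembly or taxon-assignment errors; the analyses here
#' use 1e5 bp by default and 1e6 bp for a conservative restricted set.
#'
#' @param path Path to a FASTA file.
#' @param minContigLength Minimum retained contig length in bp (default
#'   1e5). Use 0 to keep everything.
#' @param taxonLabel Group label attached to the resulting set.
#' @return A [ContigSet-class]; empty (zero contigs) if nothing passes the
#'   filter.
#' @export
readContigs <- function(path, minContigLength = 1e5, taxonLabel = "unnamed") {
    if (!file.exists(path)) stop("cannot read FASTA file: ", path)
    ## read as raw strings first so arbitrary characters survive until
    ## sanitisation (the DNA parser would silently drop invalid letters)
    seqs <- Biostrings::readBStringSet(path)
    seqs <- Biostrings::DNAStringSet(.sanitizeDNA(as.character(seqs)))
    ## FASTA descriptions: keep the first word as the id
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    keep <- Biostrings::width(seqs) >= minContigLength
    new("ContigSet", seqs = seqs[keep], taxonLabel = taxonLabel,
        nGenomes = NA_integer_)
}

#' Reverse complement of a DNA string
#'
#' Strict reverse complement over the alphabet {A,C,G,T,N}; N maps to N,
#' any other character is an error.
#'
#' @param seq A single DNA string.
#' @return The reverse-complemented string.
#' @examples
#' revComp("AAACGT") # "ACGTTT"
#' @export
revComp <- function(seq) {
    stopifnot(is.character(seq), length(seq) == 1L)
    if (grepl("[^ACGTN]", seq))
        stop("sequence contains characters outside {A,C,G,T,N}")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.emptyMatches <- function() {
    S4Vectors::DataFrame(ref_id = character(), qry_id = character(),
                         ref_start = integer(), qry_start = integer(),
                         length = integer(), strand = character())
}

.sortMatches <- function(df) {
    o <- order(df$ref_start, df$qry_start,
               match(df$strand, c("forward", "reverse")))
    df[o, , drop = FALSE]
}

#' Find all maximal exact matches between two sequences
#'
#' Enumerates every maximal exact match (MEM) of length at least
#' \code{minLength} between the forward strands of \code{ref} and
#' \code{qry}, and, when \code{bothStrands}, between the forward strand of
#' \code{ref} and the reverse complement of \code{qry}. All matches are
#' reported regardless of uniqueness; ambiguous bases (N) never match.
#' A match is maximal when extending it one bp left or right either
#' mismatches or runs off a sequence end.
#'
#' Implementation: k-mer seeding (k = min(31, minLength)) with maximal
#' bidirectional extension and leftmost-seed deduplication per diagonal.
#'
#' Reverse-strand coordinates: \code{qry_start} is the 1-based start of the
#' match within the reverse-complemented query sequence (the coordinate
#' convention of MUMmer's reverse-match output without -c).
#'
#' @param ref,qry Single DNA sequences (character or \code{DNAString}).
#' @param minLength Minimum reported match length in bp (default 300, the
#'   threshold below which chance matches between diverged orthologs become
#'   likely).
#' @param bothStrands Also search the reverse complement of \code{qry}
#'   (default TRUE).
#' @param refId,qryId Sequence ids recorded in the output.
#' @return A [S4Vectors::DataFrame] with columns \code{ref_id},
#'   \code{qry_id}, \code{ref_start}, \code{qry_start}, \code{length},
#'   \code{strand} ("forward"/"reverse"), sorted by \code{ref_start}, then
#'   \code{qry_start}, then strand (forward first).
#' @examples
#' s <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
#' findMEMs(s, s, minLength = 300, bothStrands = FALSE)
#' @export
findMEMs <- function(ref, qry, minLength = 300, bothStrands = TRUE,
                     refId = "ref", qryId = "qry") {
    if (!is.numeric(minLength) || minLength < 1)
        stop("'minLength' must be >= 1")
    ref <- .sanitizeDNA(as.character(ref))
    qry <- .sanitizeDNA(as.character(qry))
    hits <- cpp_find_mems(ref, qry, as.integer(minLength))
    out <- S4Vectors::DataFrame(
        ref_id = rep(refId, nrow(hits)), qry_id = rep(qryId, nrow(hits)),
        ref_start = hits$ref_start, qry_start = hits$qry_start,
        length = hits$length, strand = rep("forward", nrow(hits)))
    if (bothStrands) {
        rc <- revComp(qry)
        hits <- cpp_find_mems(ref, rc, as.integer(minLength))
        out <- rbind(out, S4Vectors::DataFrame(
            ref_id = rep(refId, nrow(hits)), qry_id = rep(qryId, nrow(hits)),
            ref_start = hits$ref_start, qry_start = hits$qry_start,
            length = hits$length, strand = rep("reverse", nrow(hits))))
    }
    if (nrow(out) == 0L) return(.emptyMatches())
    .sortMatches(out)
}

#' Find maximal exact matches between two contig sets
#'
#' Runs [findMEMs()] over the Cartesian product of the contigs of two
#' groups and concatenates the results. A contig present in both sets
#' (same id) is never compared against itself.
#'
#' @param setA,setB [ContigSet-class] objects (reference and query sides).
#' @param minLength Minimum match length (bp).
#' @param bothStrands Search the query reverse complement too.
#' @return Combined match \code{DataFrame} as from [findMEMs()].
#' @export
findAllPairs <- function(setA, setB, minLength = 300, bothStrands = TRUE) {
    stopifnot(is(setA, "ContigSet"), is(setB, "ContigSet"))
    if (length(contigs(setA)) == 0L || length(contigs(setB)) == 0L) {
        warning("empty contig set: no comparisons performed")
        return(.emptyMatches())
    }
    a <- contigs(setA); b <- contigs(setB)
    res <- list()
    for (i in seq_along(a)) for (j in seq_along(b)) {
        if (identical(names(a)[i], names(b)[j])) next
        res[[length(res) + 1L]] <- findMEMs(
            as.character(a[[i]]), as.character(b[[j]]),
            minLength = minLength, bothStrands = bothStrands,
            refId = names(a)[i], qryId = names(b)[j])
    }
    if (!length(res)) return(.emptyMatches())
    do.call(rbind, res)
}

#' Write / read a match table
#'
#' Tab-separated table with columns ref_id, qry_id, ref_start, qry_start,
#' length, strand. \code{readMatches(writeMatches(x))} is the identity.
#'
#' @param records Match \code{DataFrame} as produced by [findMEMs()].
#' @param path Output (input) file path.
#' @return \code{writeMatches}: the path, invisibly. \code{readMatches}:
#'   a match \code{DataFrame}.
#' @export
writeMatches <- function(records, path) {
    df <- as.data.frame(records)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatches
#' @export
readMatches <- function(path) {
    lines <- readLines(path)
    if (!length(lines)) stop("empty match file: ", path)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    want <- c("ref_id", "qry_id", "ref_start", "qry_start", "length",
              "strand")
    if (!identical(header, want))
        stop("malformed header at line 1 of ", path)
    if (length(lines) == 1L) return(.emptyMatches())
    fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 6L)
    if (length(bad))
        stop("malformed line ", bad[1L] + 1L, " in ", path)
    m <- do.call(rbind, fields)
    starts <- suppressWarnings(as.integer(m[, 3L]))
    qstarts <- suppressWarnings(as.integer(m[, 4L]))
    lens <- suppressWarnings(as.integer(m[, 5L]))
    bad <- which(is.na(starts) | is.na(qstarts) | is.na(lens) |
                 !(m[, 6L] %in% c("forward", "reverse")))
    if (length(bad))
        stop("malformed line ", bad[1L] + 1L, " in ", path)
    S4Vectors::DataFrame(ref_id = m[, 1L], qry_id = m[, 2L],
                         ref_start = starts, qry_start = qstarts,
                         length = lens, strand = m[, 6L])
}

#' Write / read matches in a MUMmer-3-style text dialect
#'
#' Per-query header lines \code{"> qry_id"} (forward) or
#' \code{"> qry_id Reverse"} (reverse), followed by data lines
#' \code{"ref_id  ref_start  qry_start  length"}. Reverse-strand
#' \code{qry_start} is the position within the reverse-complemented query.
#'
#' @param records Match \code{DataFrame} as produced by [findMEMs()].
#' @param path File path.
#' @return \code{writeMummer}: the path, invisibly. \code{readMummer}: a
#'   match \code{DataFrame}.
#' @export
writeMummer <- function(records, path) {
    df <- as.data.frame(records)
    con <- file(path, "w"); on.exit(close(con))
    for (q in unique(df$qry_id)) {
        for (st in c("forward", "reverse")) {
            sel <- df[df$qry_id == q & df$strand == st, , drop = FALSE]
            if (st == "forward" || nrow(sel) > 0L)
                writeLines(paste0("> ", q,
                                  if (st == "reverse") " Reverse" else ""),
                           con)
            if (nrow(sel))
                writeLines(sprintf("%s\t%d\t%d\t%d", sel$ref_id,
                                   sel$ref_start, sel$qry_start,
                                   sel$length), con)
        }
    }
    invisible(path)
}

#' @rdname writeMummer
#' @export
readMummer <- function(path) {
    lines <- readLines(path)
    qry <- NA_character_; strand <- "forward"
    rows <- vector("list", length(lines)); nr <- 0L
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        if (startsWith(ln, ">")) {
            hdr <- trimws(sub("^>", "", ln))
            if (grepl(" Reverse$", hdr)) {
                qry <- sub(" Reverse$", "", hdr); strand <- "reverse"
            } else { qry <- hdr; strand <- "forward" }
            next
        }
        if (is.na(qry)) stop("malformed line ", i, " in ", path,
                             ": data before any query header")
        f <- strsplit(ln, "[ \t]+")[[1L]]
        v <- suppressWarnings(as.integer(f[-1L]))
        if (length(f) != 4L || anyNA(v))
            stop("malformed line ", i, " in ", path)
        nr <- nr + 1L
        rows[[nr]] <- data.frame(ref_id = f[1L], qry_id = qry,
                                 ref_start = v[1L], qry_start = v[2L],
                                 length = v[3L], strand = strand,
                                 stringsAsFactors = FALSE)
    }
    if (!nr) return(.emptyMatches())
    df <- do.call(rbind, rows[seq_len(nr)])
    S4Vectors::DataFrame(df)
}
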