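# Brute-force maximal-exact-match enumerator: scans every diagonal of the
# comparison matrix and reports runs of equal ACGT bases of length >=
# minLength. Independent of the k-mer seeded implementation under test.

randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.code <- function(s) {
    x <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
    x[is.na(x)] <- 0L  # ambiguous: matches nothing, not even itself
    x
}

.oracleForward <- function(rc, qc, minLength) {
    n <- length(rc); m <- length(qc)
    out <- list(); k <- 0L
    for (d in seq(-(n - 1L), m - 1L)) {
        i1 <- max(1L, 1L - d); i2 <- min(n, m - d)
        if (i2 - i1 + 1L < minLength) next
        ri <- rc[i1:i2]; qi <- qc[(i1 + d):(i2 + d)]
        eq <- ri == qi & ri > 0L & qi > 0L
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        sel <- which(r$values & r$lengths >= minLength)
        for (s in sel) {
            k <- k + 1L
            out[[k]] <- c(i1 + starts[s] - 1L,
                          i1 + starts[s] - 1L + d, r$lengths[s])
        }
    }
    if (!k) return(data.frame(ref_start = integer(),
                              qry_start = integer(), length = integer()))
    m <- do.call(rbind, out)
    data.frame(ref_start = m[, 1L], qry_start = m[, 2L], length = m[, 3L])
}

oracleMEMs <- function(ref, qry, minLength, bothStrands = TRUE) {
    rc <- .code(ref)
    fwd <- .oracleForward(rc, .code(qry), minLength)
    fwd$strand <- rep("forward", nrow(fwd))
    if (bothStrands) {
        rev <- .oracleForward(rc, .code(revComp(gsub("[^ACGTN]", "N", qry))),
                              minLength)
        rev$strand <- rep("reverse", nrow(rev))
        fwd <- rbind(fwd, rev)
    }
    o <- order(fwd$ref_start, fwd$qry_start,
               match(fwd$strand, c("forward", "reverse")))
    fwd[o, , drop = FALSE]
}

# drop ids and normalise for comparison against oracle output
matchCoords <- function(df) {
    out <- data.frame(ref_start = as.integer(df$ref_start),
                      qry_start = as.integer(df$qry_start),
                      length = as.integer(df$length),
                      strand = as.character(df$strand))
    rownames(out) <- NULL
    out
}

# plant a shared segment (optionally mutated) into two random backgrounds;
# returns the two sequences and the insertion loci
plantPair <- function(lenA, lenB, K, offsetA = NULL, offsetB = NULL,
                      nMut = 0L) {
    a <- strsplit(randomDNA(lenA), "")[[1L]]
    b <- strsplit(randomDNA(lenB), "")[[1L]]
    seg <- strsplit(randomDNA(K), "")[[1L]]
    if (is.null(offsetA)) offsetA <- sample.int(lenA - K + 1L, 1L)
    if (is.null(offsetB)) offsetB <- sample.int(lenB - K + 1L, 1L)
    a[offsetA:(offsetA + K - 1L)] <- seg
    segB <- seg
    if (nMut > 0L)
        for (i in sample.int(K, nMut))
            segB[i] <- sample(setdiff(c("A", "C", "G", "T"), segB[i]), 1L)
    b[offsetB:(offsetB + K - 1L)] <- segB
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
         offsetA = offsetA, offsetB = offsetB)
}

# empty match table in the package's column layout
.emptyMatchesDF <- function() {
    S4Vectors::DataFrame(ref_id = character(), qry_id = character(),
                         ref_start = integer(), qry_start = integer(),
                         length = integer(), strand = character())
}
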