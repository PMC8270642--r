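test_that("readContigs filters by length and sanitises sequences", {
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">short desc text", strrep("A", 50),
                 ">long", paste0(strrep("acgt", 49), "acguNx__")),
               fa)
    cs <- readContigs(fa, minContigLength = 100, taxonLabel = "Testus")
    expect_s4_class(cs, "ContigSet")
    expect_identical(length(contigs(cs)), 1L)
    expect_identical(names(contigs(cs)), "long")
    expect_identical(totalLength(cs), 204)
    seq <- as.character(contigs(cs)[[1]])
    expect_identical(substr(seq, 1, 8), "ACGTACGT")  # lowercase folded
    expect_identical(substr(seq, 197, 204), "ACGTNNNN")  # U -> T, junk -> N
    expect_identical(taxonLabel(cs), "Testus")

    all <- readContigs(fa, minContigLength = 0)
    expect_identical(length(contigs(all)), 2L)
    expect_error(readContigs(tempfile()), "cannot read")
})

test_that("revComp complements, reverses, and rejects bad alphabets", {
    expect_identical(revComp("ACGT"), "ACGT")
    expect_identical(revComp("AAA"), "TTT")
    expect_identical(revComp("ANC"), "GNT")
    expect_error(revComp("ACGU"), "outside")
    set.seed(11)
    for (i in 1:5) {
        x <- randomDNA(sample(10:200, 1))
        expect_identical(revComp(revComp(x)), x)
    }
})

test_that("findMEMs reports self-identity and rejects bad minLength", {
    set.seed(7)
    s <- randomDNA(500)
    m <- findMEMs(s, s, minLength = 300, bothStrands = FALSE)
    expect_identical(matchCoords(m),
                     data.frame(ref_start = 1L, qry_start = 1L,
                                length = 500L, strand = "forward"))
    expect_error(findMEMs(s, s, minLength = 0), "minLength")
})

test_that("independent random sequences share no match >= 300 bp", {
    set.seed(21)
    a <- randomDNA(2000); b <- randomDNA(2000)
    m <- findMEMs(a, b, minLength = 300)
    expect_identical(nrow(m), 0L)
    expect_identical(nrow(oracleMEMs(a, b, 300)), 0L)
})

test_that("a planted identical segment is recovered at its coordinates", {
    set.seed(33)
    p <- plantPair(5000, 5000, 400, offsetA = 1234, offsetB = 2345)
    m <- findMEMs(p$a, p$b, minLength = 300)
    o <- oracleMEMs(p$a, p$b, 300)
    expect_identical(matchCoords(m), matchCoords(o))
    ## the planted match is present (possibly extended by chance flanks)
    hit <- m[m$strand == "forward" & m$length >= 400, ]
    expect_identical(nrow(hit), 1L)
    expect_true(hit$ref_start <= 1234 && hit$ref_start + hit$length >= 1634)
    expect_true(hit$qry_start <= 2345)
})

test_that("ambiguous bases never match, splitting planted segments", {
    set.seed(44)
    p <- plantPair(3000, 3000, 900, offsetA = 1000, offsetB = 1000)
    aN <- p$a
    substr(aN, 1450, 1450) <- "N"  # N inside the planted segment
    m <- findMEMs(aN, p$b, minLength = 300, bothStrands = FALSE)
    o <- oracleMEMs(aN, p$b, 300, bothStrands = FALSE)
    expect_identical(matchCoords(m), matchCoords(o))
    expect_identical(nrow(m), 2L)  # split at the N
    expect_false(any(m$ref_start <= 1450 & m$ref_start + m$length > 1450))
})

test_that("findMEMs equals the brute-force oracle on random instances", {
    set.seed(101)
    for (i in 1:25) {
        lenA <- sample(200:1200, 1); lenB <- sample(200:1200, 1)
        K <- sample(60:250, 1)
        p <- plantPair(lenA, lenB, K, nMut = sample(0:4, 1))
        minLen <- sample(c(20L, 50L), 1)
        m <- findMEMs(p$a, p$b, minLength = minLen, bothStrands = TRUE)
        o <- oracleMEMs(p$a, p$b, minLen, bothStrands = TRUE)
        expect_identical(matchCoords(m), matchCoords(o))
    }
})

test_that("reported matches are maximal", {
    set.seed(55)
    p <- plantPair(2000, 2000, 500, nMut = 3)
    m <- findMEMs(p$a, p$b, minLength = 50)
    qf <- revComp(p$b)
    for (i in seq_len(nrow(m))) {
        q <- if (m$strand[i] == "forward") p$b else qf
        rs <- m$ref_start[i]; qs <- m$qry_start[i]; L <- m$length[i]
        expect_identical(substr(p$a, rs, rs + L - 1L),
                         substr(q, qs, qs + L - 1L))
        if (rs > 1 && qs > 1)
            expect_false(substr(p$a, rs - 1L, rs - 1L) ==
                         substr(q, qs - 1L, qs - 1L))
        if (rs + L <= nchar(p$a) && qs + L <= nchar(q))
            expect_false(substr(p$a, rs + L, rs + L) ==
                         substr(q, qs + L, qs + L))
    }
})

test_that("raising the length threshold only removes matches", {
    set.seed(66)
    p <- plantPair(3000, 3000, 800, nMut = 6)
    lo <- matchCoords(findMEMs(p$a, p$b, minLength = 30))
    hi <- matchCoords(findMEMs(p$a, p$b, minLength = 100))
    expect_true(all(hi$length >= 100))
    key <- function(d) paste(d$ref_start, d$qry_start, d$length, d$strand)
    expect_true(all(key(hi) %in% key(lo)))
    expect_identical(key(lo)[lo$length >= 100], key(hi))
})

test_that("strand populations swap when the query is reverse-complemented", {
    set.seed(77)
    p <- plantPair(2000, 2000, 400)
    m1 <- findMEMs(p$a, p$b, minLength = 50)
    m2 <- findMEMs(p$a, revComp(p$b), minLength = 50)
    key <- function(d, st) {
        d <- d[d$strand == st, ]
        sort(paste(d$ref_start, d$qry_start, d$length))
    }
    expect_identical(key(matchCoords(m1), "forward"),
                     key(matchCoords(m2), "reverse"))
    expect_identical(key(matchCoords(m1), "reverse"),
                     key(matchCoords(m2), "forward"))
})

test_that("findAllPairs drives the contig Cartesian product", {
    set.seed(88)
    bgs <- replicate(4, randomDNA(800))
    p <- plantPair(800, 800, 350, offsetA = 100, offsetB = 200)
    A <- ContigSet(c(a1 = p$a, a2 = bgs[1]), taxonLabel = "GenusA")
    B <- ContigSet(c(b1 = bgs[2], b2 = p$b), taxonLabel = "GenusB")
    m <- findAllPairs(A, B, minLength = 300)
    expect_true(all(m$ref_id == "a1" & m$qry_id == "b2"))
    expect_true(any(m$length >= 350))

    ## no shared content anywhere
    C <- ContigSet(c(c1 = bgs[3], c2 = bgs[4]))
    expect_identical(nrow(findAllPairs(C, ContigSet(c(d1 = randomDNA(800))),
                                       minLength = 300)), 0L)

    ## swapping the sets transposes forward coordinates
    mt <- findAllPairs(B, A, minLength = 300)
    fwd <- m[m$strand == "forward", ]; fwdT <- mt[mt$strand == "forward", ]
    expect_identical(sort(paste(fwd$ref_start, fwd$qry_start, fwd$length)),
                     sort(paste(fwdT$qry_start, fwdT$ref_start,
                                fwdT$length)))
    expect_identical(nrow(m), nrow(mt))

    ## a contig present in both sets is never self-compared
    S <- ContigSet(c(s1 = p$a))
    expect_identical(nrow(findAllPairs(S, S, minLength = 300)), 0L)

    expect_warning(findAllPairs(ContigSet(character()), A), "empty")
})

test_that("match tables round-trip through TSV and the MUMmer dialect", {
    set.seed(99)
    p <- plantPair(2000, 2000, 400)
    m <- findMEMs(p$a, p$b, minLength = 50)
    expect_true(nrow(m) >= 1L)

    tsv <- tempfile(fileext = ".tsv")
    writeMatches(m, tsv)
    expect_identical(matchCoords(readMatches(tsv)), matchCoords(m))

    ## empty table: header only
    writeMatches(m[0, ], tsv)
    expect_identical(nrow(readMatches(tsv)), 0L)

    ## reverse-strand records survive the MUMmer dialect
    rec <- S4Vectors::DataFrame(
        ref_id = c("r1", "r1"), qry_id = c("q1", "q1"),
        ref_start = c(10L, 30L), qry_start = c(5L, 7L),
        length = c(320L, 410L), strand = c("forward", "reverse"))
    mum <- tempfile(fileext = ".mum")
    writeMummer(rec, mum)
    back <- readMummer(mum)
    expect_identical(matchCoords(back), matchCoords(rec))

    writeLines(c("ref_id\tqry_id\tref_start\tqry_start\tlength\tstrand",
                 "a\tb\t1\t2\tnotanumber\tforward"), tsv)
    expect_error(readMatches(tsv), "line 2")
    writeLines(c("> q1", "r1 10 5"), mum)
    expect_error(readMummer(mum), "line 2")
})
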