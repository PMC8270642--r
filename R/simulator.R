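#' Fragment a transferred segment by random substitutions
#'
#' Simulates the fate of a single transferred segment of length K a time t
#' after the event: each site has been hit in at least one of the two
#' diverging copies with probability 1 - exp(-2 mu t) (substitutions at
#' rate mu per bp per generation in each lineage). Hit sites are placed
#' uniformly at random without replacement; the maximal unhit runs are the
#' surviving exact matches.
#'
#' Uses R's global RNG; call \code{set.seed()} for reproducibility.
#'
#' @param K Segment length (bp).
#' @param t Event age in generations (>= 0).
#' @param mu Substitution rate per bp per generation.
#' @return Integer vector of fragment lengths (zero-length runs dropped);
#'   the sum of all runs plus the number of hit sites equals K.
#' @export
simulateSegmentBreaking <- function(K, t, mu) {
    stopifnot(K >= 1, t >= 0, mu > 0)
    p <- 1 - exp(-2 * mu * t)
    nMut <- stats::rbinom(1L, as.integer(K), p)
    if (nMut == 0L) return(as.integer(K))
    pos <- sort(sample.int(as.integer(K), nMut))
    frag <- diff(c(0L, pos, as.integer(K) + 1L)) - 1L
    frag[frag > 0L]
}

#' Forward-simulate the steady-state match population
#'
#' Draws event ages (uniform by default) over (0, tMax], fragments one
#' transferred segment of length K per event via
#' [simulateSegmentBreaking()], and pools the fragments of length at least
#' \code{minReportLength}. When \code{1/(2 mu tMax)} is much smaller than
#' \code{minReportLength}, the oldest events contribute no reportable
#' fragments and the pooled population is in the steady-state regime whose
#' length distribution follows the r^-3 power law.
#'
#' @param nEvents Number of transfer events to simulate.
#' @param K Transferred segment length (bp).
#' @param mu Substitution rate per bp per generation.
#' @param tMax Age window in generations; ages are drawn on (0, tMax].
#' @param minReportLength Minimum pooled fragment length (bp, default 300).
#' @param ageDistribution "uniform" (constant transfer rate) or
#'   "exponential" (deletion-suppressed ages, rate \code{lambda}).
#' @param lambda Suppression rate for \code{ageDistribution =
#'   "exponential"}.
#' @param seed Optional integer seed; recorded in the output.
#' @return List with \code{fragments} (integer lengths), \code{ages}
#'   (per-fragment event age), \code{event} (per-fragment event index) and
#'   \code{config} (echo of all arguments).
#' @export
simulateSteadyState <- function(nEvents, K, mu, tMax,
                                minReportLength = 300,
                                ageDistribution = c("uniform",
                                                    "exponential"),
                                lambda = NULL, seed = NULL) {
    ageDistribution <- match.arg(ageDistribution)
    stopifnot(nEvents >= 0, K >= 1, mu > 0, tMax > 0)
    if (!is.null(seed)) set.seed(seed)
    if (1 / (2 * mu * tMax) > minReportLength / 5)
        warning("tMax too small for the steady-state regime: ",
                "mean fragment length at tMax is not well below ",
                "minReportLength")
    ages <- switch(ageDistribution,
        uniform = stats::runif(nEvents, 0, tMax),
        exponential = {
            if (is.null(lambda) || lambda <= 0)
                stop("'lambda' must be > 0 for exponential ages")
            stats::qexp(stats::runif(nEvents) *
                        stats::pexp(tMax, lambda), lambda)
        })
    frags <- vector("list", nEvents)
    for (i in seq_len(nEvents)) {
        f <- simulateSegmentBreaking(K, ages[i], mu)
        frags[[i]] <- f[f >= minReportLength]
    }
    nf <- lengths(frags)
    list(fragments = as.integer(unlist(frags)),
         ages = rep(ages, nf),
         event = rep(seq_len(nEvents), nf),
         config = list(nEvents = nEvents, K = K, mu = mu, tMax = tMax,
                       minReportLength = minReportLength,
                       ageDistribution = ageDistribution,
                       lambda = lambda, seed = seed))
}

#' Build an MLD from a vector of match or fragment lengths
#'
#' Tabulates lengths into a [MatchLengthDistribution-class] with the given
#' normalisation; the bridge between simulated fragment populations and
#' the binning/fitting machinery.
#'
#' @param lengths Integer vector of lengths (bp).
#' @param normalisation Normalisation in bp^2 (default 1: raw counts).
#' @return A [MatchLengthDistribution-class].
#' @export
mldFromLengths <- function(lengths, normalisation = 1) {
    stopifnot(normalisation > 0)
    if (length(lengths)) {
        tab <- table(lengths)
        lens <- as.integer(names(tab)); cnts <- as.numeric(tab)
        o <- order(lens); lens <- lens[o]; cnts <- cnts[o]
    } else {
        lens <- integer(); cnts <- numeric()
    }
    new("MatchLengthDistribution", lengths = lens, counts = cnts,
        density = cnts / normalisation, normalisation = normalisation,
        nPairsAveraged = 1L)
}

#' Sum of analytic exponential MLDs at sampled event ages
#'
#' Evaluates the single-event exponential contribution [mldConditional()]
#' at \code{nComponents} sampled ages and sums them on a length grid: the
#' mixture-of-exponentials construction showing how contributions of
#' events of different ages combine into an r^-3 power law when ages are
#' not strongly biased.
#'
#' @param rGrid Numeric grid of match lengths (bp).
#' @param params An [HGTModelParams-class].
#' @param nComponents Number of exponential components (default 50).
#' @param tMax Ages are sampled uniformly on (0, tMax] unless \code{ages}
#'   is given.
#' @param ages Optional explicit ages (overrides sampling).
#' @return List with \code{r} (the grid), \code{density} (summed curve),
#'   \code{components} (matrix, one column per component) and \code{ages}.
#' @export
exponentialMixtureMLD <- function(rGrid, params, nComponents = 50,
                                  tMax = NULL, ages = NULL) {
    stopifnot(is(params, "HGTModelParams"))
    if (is.null(ages)) {
        if (is.null(tMax) || tMax <= 0)
            stop("supply 'ages' or a positive 'tMax'")
        stopifnot(nComponents >= 1)
        ages <- stats::runif(nComponents, 0, tMax)
    }
    comp <- vapply(ages, function(t) mldConditional(rGrid, t, params),
                   numeric(length(rGrid)))
    comp <- matrix(comp, nrow = length(rGrid))
    list(r = rGrid, density = rowSums(comp), components = comp,
         ages = ages)
}

#' OLS slope of a density curve in log-log space
#'
#' Ordinary least squares of ln(density) on ln(r) over the grid points
#' with positive density inside [rMin, rMax]; the free-slope diagnostic
#' for analytic or summed curves that are not count histograms.
#'
#' @param r Length grid (bp).
#' @param density Densities on the grid.
#' @param rMin,rMax Fit window (default: whole grid).
#' @return Named list with \code{slope}, \code{intercept}, \code{nPoints}.
#' @export
fitLogLogSlope <- function(r, density, rMin = -Inf, rMax = Inf) {
    use <- density > 0 & r >= rMin & r <= rMax
    if (sum(use) < 3L) stop("need >= 3 positive points in the fit window")
    fit <- stats::lm(log(density[use]) ~ log(r[use]))
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         nPoints = sum(use))
}

.randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutateSegment <- function(seg, pSub) {
    if (pSub <= 0) return(seg)
    s <- strsplit(seg, "")[[1L]]
    hit <- which(stats::runif(length(s)) < pSub)
    for (i in hit)
        s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1L)
    paste(s, collapse = "")
}

## place nSeg intervals of lengths K inside [2, len-1] without overlap
.placeSegments <- function(len, K, maxTries = 1000L) {
    n <- length(K)
    for (try in seq_len(maxTries)) {
        ## segment [s, s+k-1] needs flanking bases at s-1 and s+k,
        ## so s ranges over [2, len-k]
        starts <- vapply(K, function(k) {
            if (len - k - 1L < 1L) return(NA_integer_)
            sample.int(len - k - 1L, 1L) + 1L
        }, integer(1L))
        if (anyNA(starts)) break
        o <- order(starts)
        ## keep a >= 2 bp gap so flank-breaking edits cannot collide
        if (n < 2L ||
            all(starts[o][-1L] > starts[o][-n] + K[o][-n] + 1L))
            return(starts)
    }
    stop("could not place segments without overlap after bounded retries")
}

#' Generate a genome pair with planted xenologous segments
#'
#' Builds two independent uniform-random genomes and plants shared
#' segments emulating transfer events of known age: for each event a
#' common random segment of length K is copied into both genomes at random
#' non-overlapping loci (random or fixed strand in genome B), then each
#' copy accumulates independent substitutions with per-site probability
#' 1 - exp(-mu t). The bases flanking each planted copy are forced to
#' mismatch on the match diagonal, so an unmutated event of length K
#' yields a maximal exact match of exactly K at the recorded loci.
#'
#' @param lenA,lenB Background genome lengths (bp).
#' @param planted \code{data.frame} with columns \code{K} (segment length),
#'   \code{t} (event age, generations) and optionally \code{strand}
#'   ("forward", "reverse" or "random", the default). Zero rows plant
#'   nothing.
#' @param mu Substitution rate per bp per generation (default 1e-9).
#' @param seed Optional integer seed.
#' @param idA,idB Sequence ids of the two genomes.
#' @return List with \code{seqA}, \code{seqB} (named character sequences)
#'   and \code{truth}, a \code{data.frame} with columns \code{locus_a},
#'   \code{locus_b}, \code{K}, \code{t}, \code{strand}; \code{locus_b} for
#'   reverse-strand events is the start within the reverse-complemented
#'   genome B, matching the coordinate convention of [findMEMs()].
#' @export
generateGenomePair <- function(lenA, lenB, planted = NULL, mu = 1e-9,
                               seed = NULL, idA = "genomeA",
                               idB = "genomeB") {
    if (!is.null(seed)) set.seed(seed)
    lenA <- as.integer(lenA); lenB <- as.integer(lenB)
    if (is.null(planted))
        planted <- data.frame(K = integer(), t = numeric())
    n <- nrow(planted)
    if (n > 0L && sum(planted$K) > min(lenA, lenB) / 2)
        stop("total planted length exceeds half the shorter genome")
    strand <- if ("strand" %in% names(planted) && n > 0L)
        as.character(planted$strand) else rep("random", n)
    strand[strand == "random"] <-
        sample(c("forward", "reverse"), sum(strand == "random"),
               replace = TRUE)
    a <- strsplit(.randomDNA(lenA), "")[[1L]]
    b <- strsplit(.randomDNA(lenB), "")[[1L]]
    locusA <- integer(n); locusB <- integer(n)
    if (n > 0L) {
        K <- as.integer(planted$K)
        startsA <- .placeSegments(lenA, K)
        startsB <- .placeSegments(lenB, K)
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        for (e in seq_len(n)) {
            seg <- .randomDNA(K[e])
            pSub <- 1 - exp(-mu * planted$t[e])
            segA <- strsplit(.mutateSegment(seg, pSub), "")[[1L]]
            segB <- strsplit(.mutateSegment(seg, pSub), "")[[1L]]
            sa <- startsA[e]; sb <- startsB[e]
            a[sa:(sa + K[e] - 1L)] <- segA
            locusA[e] <- sa
            if (strand[e] == "forward") {
                b[sb:(sb + K[e] - 1L)] <- segB
                locusB[e] <- sb
                ## break the diagonal at both flanks
                if (b[sb - 1L] == a[sa - 1L])
                    b[sb - 1L] <- sample(setdiff(names(comp),
                                                 a[sa - 1L]), 1L)
                if (b[sb + K[e]] == a[sa + K[e]])
                    b[sb + K[e]] <- sample(setdiff(names(comp),
                                                   a[sa + K[e]]), 1L)
            } else {
                b[sb:(sb + K[e] - 1L)] <- rev(unname(comp[segB]))
                ## start within revcomp(B): forward [sb, sb+K-1] maps to
                ## lenB - (sb + K - 1) + 1
                locusB[e] <- lenB - (sb + K[e] - 1L) + 1L
                ## flanks on the revcomp diagonal: revcompB[q-1] is the
                ## complement of B[sb+K], revcompB[q+K] of B[sb-1]
                if (comp[b[sb + K[e]]] == a[sa - 1L])
                    b[sb + K[e]] <- sample(setdiff(names(comp),
                                                   comp[a[sa - 1L]]), 1L)
                if (comp[b[sb - 1L]] == a[sa + K[e]])
                    b[sb - 1L] <- sample(setdiff(names(comp),
                                                 comp[a[sa + K[e]]]), 1L)
            }
        }
    }
    truth <- data.frame(locus_a = locusA, locus_b = locusB,
                        K = if (n) as.integer(planted$K) else integer(),
                        t = if (n) planted$t else numeric(),
                        strand = strand, stringsAsFactors = FALSE)
    seqA <- paste(a, collapse = ""); names(seqA) <- idA
    seqB <- paste(b, collapse = ""); names(seqB) <- idB
    list(seqA = seqA, seqB = seqB, truth = truth)
}

#' Write a generated genome pair to FASTA plus a truth table
#'
#' @param pair Output of [generateGenomePair()].
#' @param dir Output directory (created if needed); writes
#'   \code{genomeA.fa}, \code{genomeB.fa} and \code{truth.tsv}.
#' @return The directory, invisibly.
#' @export
writeFixture <- function(pair, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(pair$seqA), file.path(dir, "genomeA.fa"))
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(pair$seqB), file.path(dir, "genomeB.fa"))
    utils::write.table(pair$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}
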