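#' Compute the match-length distribution of a pair of groups
#'
#' Tabulates the number of matches M(r) of each exact length r and
#' normalises by the product of the total retained contig lengths of the
#' two groups, m(r) = M(r) / (l_a * l_b). The normalisation removes the
#' dependence on the amount of sequence data available for each group, so
#' distributions from differently sampled groups are comparable.
#'
#' @param matches Match \code{DataFrame} (from [findAllPairs()] or
#'   [readMatches()]); every \code{ref_id}/\code{qry_id} must name a contig
#'   of \code{setA}/\code{setB}.
#' @param setA,setB The two [ContigSet-class] groups compared.
#' @return A [MatchLengthDistribution-class].
#' @export
computeMLD <- function(matches, setA, setB) {
    stopifnot(is(setA, "ContigSet"), is(setB, "ContigSet"))
    ra <- names(contigs(setA)); rb <- names(contigs(setB))
    if (nrow(matches)) {
        unk <- setdiff(matches$ref_id, ra)
        if (length(unk)) stop("match references unknown contig(s) in set A: ",
                              paste(unk, collapse = ", "))
        unk <- setdiff(matches$qry_id, rb)
        if (length(unk)) stop("match references unknown contig(s) in set B: ",
                              paste(unk, collapse = ", "))
    }
    norm <- totalLength(setA) * totalLength(setB)
    if (norm <= 0) stop("normalisation is zero: empty contig set")
    if (nrow(matches)) {
        tab <- table(matches$length)
        lens <- as.integer(names(tab))
        counts <- as.numeric(tab)
        o <- order(lens)
        lens <- lens[o]; counts <- counts[o]
    } else {
        lens <- integer(); counts <- numeric()
    }
    new("MatchLengthDistribution", lengths = lens, counts = counts,
        density = counts / norm, normalisation = norm,
        nPairsAveraged = 1L)
}

#' Average match-length distributions over group pairs
#'
#' Unweighted arithmetic mean of the member densities at every observed
#' length; the denominator counts pairs, so members whose distribution is
#' identically zero still dilute the average.
#'
#' @param mlds Non-empty list of [MatchLengthDistribution-class] objects.
#' @return A [MatchLengthDistribution-class] with
#'   \code{nPairsAveraged = length(mlds)}; counts are mean counts and the
#'   normalisation is \code{NA} unless all members share one.
#' @export
averageMLDs <- function(mlds) {
    if (!is.list(mlds) || length(mlds) == 0L)
        stop("'mlds' must be a non-empty list")
    ok <- vapply(mlds, is, logical(1L), "MatchLengthDistribution")
    if (!all(ok)) stop("all elements must be MatchLengthDistribution")
    npairs <- sum(vapply(mlds, function(m) m@nPairsAveraged, integer(1L)))
    lens <- sort(unique(unlist(lapply(mlds, function(m) m@lengths))))
    dens <- numeric(length(lens)); cnts <- numeric(length(lens))
    for (m in mlds) {
        idx <- match(m@lengths, lens)
        dens[idx] <- dens[idx] + m@density * m@nPairsAveraged
        cnts[idx] <- cnts[idx] + m@counts * m@nPairsAveraged
    }
    norms <- vapply(mlds, function(m) m@normalisation, numeric(1L))
    norm <- if (length(unique(norms)) == 1L) norms[1L] else NA_real_
    new("MatchLengthDistribution", lengths = as.integer(lens),
        counts = cnts / npairs, density = dens / npairs,
        normalisation = norm, nPairsAveraged = as.integer(npairs))
}

#' Logarithmically bin the tail of a match-length distribution
#'
#' Builds geometric bins from \code{rMin} up to the largest observed
#' length and converts count mass to density: (mass in bin) / (bin width
#' in bp) / normalisation. Bin coordinates are the geometric means of the
#' edges. Matches below \code{rMin} are ignored.
#'
#' @param mld A [MatchLengthDistribution-class].
#' @param rMin Lower edge of the first bin (bp); defaults to 300, the
#'   match-length threshold of the analysis.
#' @param binsPerDecade Number of geometric bins per decade (default 8).
#' @return A [BinnedMLD-class].
#' @export
binLogarithmic <- function(mld, rMin = 300, binsPerDecade = 8) {
    stopifnot(is(mld, "MatchLengthDistribution"), rMin >= 1,
              binsPerDecade >= 1)
    sel <- mld@lengths >= rMin
    if (!any(sel)) stop("empty tail: no matches at r >= ", rMin)
    lens <- mld@lengths[sel]
    norm <- mld@normalisation
    if (is.na(norm)) {
        ## averaged MLD without a common normalisation: its density is
        ## already in final units, so bin density mass with norm 1
        cnts <- mld@density[sel]
        norm <- 1
    } else {
        cnts <- mld@counts[sel]
    }
    rMax <- max(lens)
    nBins <- max(1L, ceiling(log10(rMax / rMin) * binsPerDecade))
    edges <- rMin * 10^(seq(0L, nBins) / binsPerDecade)
    edges[nBins + 1L] <- max(edges[nBins + 1L], rMax + 1)
    idx <- findInterval(lens, edges, rightmost.closed = FALSE)
    mass <- vapply(seq_len(nBins), function(b) sum(cnts[idx == b]),
                   numeric(1L))
    widths <- diff(edges)
    dens <- mass / widths / norm
    centers <- sqrt(edges[-1L] * edges[-(nBins + 1L)])
    new("BinnedMLD", edges = edges, centers = centers, density = dens,
        counts = mass, occupied = mass > 0, normalisation = norm)
}

#' Fit the fixed-slope -3 power law to a binned MLD tail
#'
#' One-parameter linear regression in log-log space with the slope held at
#' -3: ln A is the mean of ln(density) + 3 ln(center) over the occupied
#' bins with center >= \code{fitMin}. The prefactor A estimates the
#' effective transfer rate per genome length.
#'
#' @param binned A [BinnedMLD-class].
#' @param fitMin Smallest bin center entering the fit (bp, default 300).
#' @return A [PowerLawFit-class].
#' @export
fitPrefactor <- function(binned, fitMin = 300) {
    stopifnot(is(binned, "BinnedMLD"))
    use <- binned@occupied & binned@centers >= fitMin
    if (sum(use) < 2L)
        stop("insufficient tail: need >= 2 occupied bins at r >= ", fitMin)
    lc <- log(binned@centers[use]); ld <- log(binned@density[use])
    lA <- mean(ld + 3 * lc)
    res <- ld + 3 * lc - lA
    new("PowerLawFit", prefactor = exp(lA), logPrefactor = lA,
        fixedExponent = -3,
        fitRange = range(binned@centers[use]),
        nBinsUsed = as.integer(sum(use)),
        residualRMS = sqrt(mean(res^2)))
}

#' Free-slope diagnostic fit of a binned MLD tail
#'
#' Ordinary least squares of ln(density) on ln(center) over the occupied
#' bins with center >= \code{fitMin}; used to verify that an empirical or
#' simulated tail is consistent with the predicted exponent -3 before the
#' fixed-slope fit is trusted.
#'
#' @param binned A [BinnedMLD-class].
#' @param fitMin Smallest bin center entering the fit (bp, default 300).
#' @return Named list with \code{slope}, \code{intercept} (natural-log
#'   scale), \code{nBins}.
#' @export
fitFreeSlope <- function(binned, fitMin = 300) {
    stopifnot(is(binned, "BinnedMLD"))
    use <- binned@occupied & binned@centers >= fitMin
    if (sum(use) < 3L)
        stop("insufficient tail: need >= 3 occupied bins at r >= ", fitMin)
    lc <- log(binned@centers[use]); ld <- log(binned@density[use])
    if (diff(range(lc)) == 0) stop("degenerate abscissae")
    fit <- stats::lm(ld ~ lc)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         nBins = sum(use))
}

#' Write / read an MLD as TSV plus JSON sidecar
#'
#' Two-column TSV (length, density) plus a \code{.json} sidecar holding
#' the normalisation, number of pairs averaged, and raw counts.
#'
#' @param mld A [MatchLengthDistribution-class].
#' @param path TSV path; sidecar written to \code{paste0(path, ".json")}.
#' @return \code{writeMLD}: the path, invisibly; \code{readMLD}: the
#'   reconstructed [MatchLengthDistribution-class].
#' @export
writeMLD <- function(mld, path) {
    utils::write.table(
        data.frame(length = mld@lengths, density = mld@density),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(normalisation = mld@normalisation,
             nPairsAveraged = mld@nPairsAveraged,
             counts = mld@counts),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeMLD
#' @export
readMLD <- function(path) {
    df <- utils::read.delim(path)
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    counts <- as.numeric(side$counts)
    if (!length(counts)) counts <- numeric()
    new("MatchLengthDistribution", lengths = as.integer(df$length),
        counts = counts, density = as.numeric(df$density),
        normalisation = as.numeric(side$normalisation),
        nPairsAveraged = as.integer(side$nPairsAveraged))
}
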