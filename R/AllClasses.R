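#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' ContigSet: a taxon-labelled set of contigs
#'
#' A thin wrapper around a [Biostrings::DNAStringSet] holding the retained
#' contigs of one taxon group (e.g. a genus), the unit of pairwise comparison.
#' The total retained length \eqn{\ell} (sum of contig lengths) is the
#' normalisation constant of the match-length distribution; the optional
#' genome count \eqn{n} and mean genome length \eqn{L} (with
#' \eqn{\ell = n L}) feed the transfer-rate model.
#'
#' @slot seqs A \code{DNAStringSet} of contigs (uppercase, non-ACGT as N).
#' @slot taxonLabel Single string naming the group (e.g. genus).
#' @slot nGenomes Integer count of genomes the contigs came from
#'   (informational; \code{NA} when unknown).
#'
#' @seealso [readContigs()], [totalLength()], [findAllPairs()]
#' @export
setClass("ContigSet",
    representation(seqs = "ANY", taxonLabel = "character",
                   nGenomes = "integer"),
    prototype(taxonLabel = "unnamed", nGenomes = NA_integer_))

setValidity("ContigSet", function(object) {
    msg <- NULL
    if (!is(object@seqs, "DNAStringSet"))
        msg <- c(msg, "'seqs' must be a DNAStringSet")
    else if (length(object@seqs) > 0L && any(Biostrings::width(object@seqs) == 0L))
        msg <- c(msg, "all contigs must have length > 0")
    if (length(object@taxonLabel) != 1L)
        msg <- c(msg, "'taxonLabel' must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' MatchLengthDistribution: normalised histogram of exact-match lengths
#'
#' Stores the raw per-length match counts \eqn{M(r)} together with the
#' normalisation \eqn{\ell_i \ell_j} (product of the total contig lengths of
#' the two groups, in bp\eqn{^2}) and the resulting density
#' \eqn{m(r) = M(r) / (\ell_i \ell_j)}. Averages over several group pairs
#' keep \code{nPairsAveraged > 1} and carry mean densities (counts are then
#' mean counts, not integers).
#'
#' @slot lengths Integer vector of distinct match lengths r (bp), sorted.
#' @slot counts Numeric vector, \eqn{M(r)} (integer for a single pair).
#' @slot density Numeric vector, \eqn{m(r)} in bp\eqn{^{-2}}.
#' @slot normalisation Single numeric, \eqn{\ell_i \ell_j} (bp\eqn{^2});
#'   \code{NA} for averaged distributions with heterogeneous normalisations.
#' @slot nPairsAveraged Integer, number of group pairs averaged (1 = single).
#'
#' @seealso [computeMLD()], [averageMLDs()], [binLogarithmic()]
#' @export
setClass("MatchLengthDistribution",
    representation(lengths = "integer", counts = "numeric",
                   density = "numeric", normalisation = "numeric",
                   nPairsAveraged = "integer"))

setValidity("MatchLengthDistribution", function(object) {
    msg <- NULL
    nl <- length(object@lengths)
    if (length(object@counts) != nl || length(object@density) != nl)
        msg <- c(msg, "'lengths', 'counts' and 'density' must be parallel")
    if (nl > 1L && is.unsorted(object@lengths, strictly = TRUE))
        msg <- c(msg, "'lengths' must be strictly increasing")
    if (any(object@counts < 0) || any(object@density < 0))
        msg <- c(msg, "counts and densities must be nonnegative")
    if (object@nPairsAveraged < 1L)
        msg <- c(msg, "'nPairsAveraged' must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' BinnedMLD: logarithmically binned tail of an MLD
#'
#' Geometric bins over match length; per-bin density is the count mass in
#' the bin divided by the bin width (bp) and by the normalisation, so it is
#' directly comparable to the model density \eqn{A/r^3}. Empty bins are kept
#' but flagged, since log-density is undefined there.
#'
#' @slot edges Numeric vector of strictly increasing bin edges (bp).
#' @slot centers Numeric vector, geometric mean of adjacent edges (bp).
#' @slot density Numeric per-bin density (bp\eqn{^{-2}}); 0 in empty bins.
#' @slot counts Numeric per-bin raw count mass.
#' @slot occupied Logical mask of bins holding any mass.
#' @slot normalisation Normalisation carried over from the MLD.
#'
#' @seealso [binLogarithmic()], [fitPrefactor()], [fitFreeSlope()]
#' @export
setClass("BinnedMLD",
    representation(edges = "numeric", centers = "numeric",
                   density = "numeric", counts = "numeric",
                   occupied = "logical", normalisation = "numeric"))

setValidity("BinnedMLD", function(object) {
    msg <- NULL
    nb <- length(object@centers)
    if (length(object@edges) != nb + 1L)
        msg <- c(msg, "need one more edge than centers")
    if (any(diff(object@edges) <= 0))
        msg <- c(msg, "'edges' must be strictly increasing")
    if (length(object@density) != nb || length(object@counts) != nb ||
        length(object@occupied) != nb)
        msg <- c(msg, "per-bin slots must be parallel to 'centers'")
    if (is.null(msg)) TRUE else msg
})

#' PowerLawFit: fixed-slope -3 fit of an MLD tail
#'
#' The one-parameter fit of \eqn{m(r) = A / r^3} to the occupied bins of a
#' log-binned MLD tail: the slope is held at -3 and only the intercept
#' \eqn{\ln A} is estimated, so \eqn{\ln A} is the mean of
#' \eqn{\ln m + 3 \ln r} over the bins used. A is the effective transfer
#' rate per genome length (bp).
#'
#' @slot prefactor Numeric, A.
#' @slot logPrefactor Numeric, \eqn{\ln A}.
#' @slot fixedExponent Numeric, always -3.
#' @slot fitRange Numeric length-2, [r_min, r_max] of bin centers used (bp).
#' @slot nBinsUsed Integer, occupied bins entering the fit.
#' @slot residualRMS Numeric, RMS of \eqn{\ln m + 3\ln r - \ln A}.
#'
#' @seealso [fitPrefactor()], [hgtPrefactor()]
#' @export
setClass("PowerLawFit",
    representation(prefactor = "numeric", logPrefactor = "numeric",
                   fixedExponent = "numeric", fitRange = "numeric",
                   nBinsUsed = "integer", residualRMS = "numeric"),
    prototype(fixedExponent = -3))

setValidity("PowerLawFit", function(object) {
    msg <- NULL
    if (!identical(object@fixedExponent, -3))
        msg <- c(msg, "'fixedExponent' must be -3")
    if (length(object@fitRange) != 2L)
        msg <- c(msg, "'fitRange' must have length 2")
    if (is.null(msg)) TRUE else msg
})

#' HGTModelParams: parameters of the transfer-and-fragmentation model
#'
#' All parameters of the stochastic model in which segments of length K are
#' transferred between two taxon groups at rate rho, fix in fractions f1/f2
#' of the recipient populations, and are subsequently fragmented by
#' substitutions at effective rate mu per bp per generation in each lineage.
#' An optional deletion rate lambda exponentially suppresses old events.
#'
#' @slot rho Transfer events per generation between the two group populations.
#' @slot mu Substitution rate per bp per generation (effective
#'   \eqn{\mu = (\mu_1+\mu_2)/2} for a pair of groups).
#' @slot K Transferred segment length (bp), \eqn{K \gg 1}.
#' @slot f1,f2 Fixation fractions in the two groups, in [0, 1].
#' @slot L1,L2 Mean genome lengths of the two groups (bp).
#' @slot lambda Deletion (suppression) rate per generation; 0 disables it.
#'
#' @seealso [hgtParams()], [mldSteady()], [hgtPrefactor()]
#' @export
setClass("HGTModelParams",
    representation(rho = "numeric", mu = "numeric", K = "numeric",
                   f1 = "numeric", f2 = "numeric",
                   L1 = "numeric", L2 = "numeric", lambda = "numeric"))

setValidity("HGTModelParams", function(object) {
    msg <- NULL
    if (object@mu <= 0) msg <- c(msg, "'mu' must be > 0")
    if (object@K < 1) msg <- c(msg, "'K' must be >= 1")
    if (object@f1 < 0 || object@f1 > 1 || object@f2 < 0 || object@f2 > 1)
        msg <- c(msg, "fixation fractions must lie in [0, 1]")
    if (object@L1 <= 0 || object@L2 <= 0)
        msg <- c(msg, "mean genome lengths must be > 0")
    if (object@rho < 0) msg <- c(msg, "'rho' must be >= 0")
    if (object@lambda < 0) msg <- c(msg, "'lambda' must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' AgeEstimate: most-likely age of a transfer event
#'
#' The mode of the age posterior for an exact match of length r,
#' \eqn{t_{ML} = 1/(\mu r)} generations, with a calendar conversion via the
#' assumed generation time.
#'
#' @slot tGenerations Numeric, \eqn{1/(\mu r)}.
#' @slot tYears Numeric, generations x generationTimeHours / hoursPerYear.
#' @slot generationTimeHours Numeric, assumed generation time (default 10 h).
#' @slot hoursPerYear Numeric, default 8766 (365.25 d).
#'
#' @seealso [mostLikelyAge()], [agePosterior()]
#' @export
setClass("AgeEstimate",
    representation(tGenerations = "numeric", tYears = "numeric",
                   generationTimeHours = "numeric", hoursPerYear = "numeric"))

#' EnrichmentResult: weighted hit totals and their ratio
#'
#' Weighted hit totals \eqn{H = \sum_i w_i n_i} for an observed and a control
#' match set, their standard errors, and the enrichment ratio with a
#' first-order propagated interval.
#'
#' @slot HObserved,HControl Weighted totals.
#' @slot deltaHObserved,deltaHControl Standard errors of the totals.
#' @slot ratio \code{HObserved / HControl} (\code{NA} when HControl is 0).
#' @slot ratioInterval Length-2 numeric, ratio +/- propagated error
#'   (\code{NA} when undefined).
#' @slot stderrMethod Label of the standard-error formula used.
#'
#' @seealso [enrichmentRatio()], [weightedHits()], [hitsStderr()]
#' @export
setClass("EnrichmentResult",
    representation(HObserved = "numeric", HControl = "numeric",
                   deltaHObserved = "numeric", deltaHControl = "numeric",
                   ratio = "numeric", ratioInterval = "numeric",
                   stderrMethod = "character"))
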