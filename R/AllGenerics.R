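#' Total retained sequence length of a contig set
#'
#' Sum of retained contig lengths (the MLD normalisation constant
#' \eqn{\ell}, in bp).
#'
#' @param x A [ContigSet-class].
#' @return Numeric, total length in bp.
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' Taxon label of a contig set
#'
#' @param x A [ContigSet-class].
#' @return Single string.
#' @export
setGeneric("taxonLabel", function(x) standardGeneric("taxonLabel"))

#' Contig sequences
#'
#' @param x A [ContigSet-class].
#' @return A \code{DNAStringSet}.
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' Power-law prefactor of a fit or model
#'
#' For a [PowerLawFit-class], the fitted prefactor A of \eqn{m(r)=A/r^3};
#' for [HGTModelParams-class] see [hgtPrefactor()].
#'
#' @param x Object carrying a prefactor.
#' @return Numeric A (bp).
#' @export
setGeneric("prefactor", function(x) standardGeneric("prefactor"))

#' Density values of a distribution object
#'
#' @param x A [MatchLengthDistribution-class] or [BinnedMLD-class].
#' @return Numeric vector of densities (bp^-2).
#' @export
setGeneric("mldDensity", function(x) standardGeneric("mldDensity"))

#' @rdname totalLength
setMethod("totalLength", "ContigSet", function(x)
    sum(as.numeric(Biostrings::width(x@seqs))))

#' @rdname taxonLabel
setMethod("taxonLabel", "ContigSet", function(x) x@taxonLabel)

#' @rdname contigs
setMethod("contigs", "ContigSet", function(x) x@seqs)

#' @rdname prefactor
setMethod("prefactor", "PowerLawFit", function(x) x@prefactor)

#' @rdname mldDensity
setMethod("mldDensity", "MatchLengthDistribution", function(x) x@density)

#' @rdname mldDensity
setMethod("mldDensity", "BinnedMLD", function(x) x@density)

setMethod("show", "ContigSet", function(object) {
    cat("ContigSet of", length(object@seqs), "contig(s),",
        "taxon:", object@taxonLabel, "\n")
    cat("  total length:", format(totalLength(object), big.mark = ","),
        "bp\n")
})

setMethod("show", "MatchLengthDistribution", function(object) {
    cat("MatchLengthDistribution:", length(object@lengths),
        "distinct length(s),", sum(object@counts), "match(es)\n")
    cat("  normalisation:", format(object@normalisation, digits = 4),
        "bp^2;", object@nPairsAveraged, "pair(s) averaged\n")
    if (length(object@lengths))
        cat("  length range: [", min(object@lengths), ",",
            max(object@lengths), "] bp\n")
})

setMethod("show", "BinnedMLD", function(object) {
    cat("BinnedMLD:", length(object@centers), "bin(s) (",
        sum(object@occupied), "occupied ) over [",
        format(min(object@edges), digits = 4), ",",
        format(max(object@edges), digits = 4), "] bp\n")
})

setMethod("show", "PowerLawFit", function(object) {
    cat("PowerLawFit: m(r) = A / r^3\n")
    cat("  A =", format(object@prefactor, digits = 4),
        " (ln A =", format(object@logPrefactor, digits = 4), ")\n")
    cat("  fit range: [", object@fitRange[1L], ",", object@fitRange[2L],
        "] bp over", object@nBinsUsed, "bin(s); residual RMS =",
        format(object@residualRMS, digits = 3), "\n")
})

setMethod("show", "HGTModelParams", function(object) {
    cat("HGTModelParams: rho =", object@rho, " mu =", object@mu,
        " K =", object@K, "\n  f1 =", object@f1, " f2 =", object@f2,
        " L1 =", object@L1, " L2 =", object@L2,
        " lambda =", object@lambda, "\n")
})

setMethod("show", "AgeEstimate", function(object) {
    cat("AgeEstimate: ", format(object@tGenerations, digits = 4),
        " generations ~ ", format(object@tYears, digits = 4), " years\n",
        "  (generation time ", object@generationTimeHours, " h, ",
        object@hoursPerYear, " h/yr)\n", sep = "")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult: H_obs =", object@HObserved, "+/-",
        format(object@deltaHObserved, digits = 4),
        "; H_ctrl =", object@HControl, "+/-",
        format(object@deltaHControl, digits = 4), "\n")
    cat("  ratio =", format(object@ratio, digits = 4),
        " interval [", format(object@ratioInterval[1L], digits = 4), ",",
        format(object@ratioInterval[2L], digits = 4), "]",
        " (stderr:", object@stderrMethod, ")\n")
})
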