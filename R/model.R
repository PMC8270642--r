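#' Construct HGT model parameters
#'
#' Convenience constructor with validity checking for the parameters of the
#' transfer-and-fragmentation model. For a pair of groups with different
#' substitution rates, pass the effective rate mu = (mu1 + mu2)/2.
#'
#' @param rho Transfer rate (events per generation between the two group
#'   populations).
#' @param mu Substitution rate per bp per generation.
#' @param K Transferred segment length (bp).
#' @param f1,f2 Fixation fractions in the two groups (default 1).
#' @param L1,L2 Mean genome lengths (bp).
#' @param lambda Deletion rate per generation (default 0 = no suppression).
#' @return An [HGTModelParams-class].
#' @examples
#' p <- hgtParams(rho = 1e-4, mu = 1e-9, K = 1e4, L1 = 1e6, L2 = 1e6)
#' hgtPrefactor(p) # 1e-3
#' @export
hgtParams <- function(rho, mu, K, f1 = 1, f2 = 1, L1, L2, lambda = 0) {
    new("HGTModelParams", rho = as.numeric(rho), mu = as.numeric(mu),
        K = as.numeric(K), f1 = as.numeric(f1), f2 = as.numeric(f2),
        L1 = as.numeric(L1), L2 = as.numeric(L2),
        lambda = as.numeric(lambda))
}

#' MLD contribution of a single transfer event of age t
#'
#' Density of exact matches of length r contributed by one transferred
#' segment of length K that entered both genomes a time t ago and has since
#' been fragmented by substitutions in both lineages (total rate 2 mu per
#' bp):
#' \deqn{m(r | t) = \frac{f_1 f_2 K}{L_1 L_2} (2\mu t)^2 e^{-2\mu t r}}
#' Valid in the regime 1 << r < K.
#'
#' @param r Match length (bp); vectorised.
#' @param t Event age in generations (> 0).
#' @param params An [HGTModelParams-class].
#' @return Density in bp^-2.
#' @export
mldConditional <- function(r, t, params) {
    stopifnot(is(params, "HGTModelParams"))
    if (any(t <= 0)) stop("'t' must be > 0")
    pre <- params@f1 * params@f2 * params@K / (params@L1 * params@L2)
    pre * (2 * params@mu * t)^2 * exp(-2 * params@mu * t * r)
}

#' Steady-state MLD under a constant transfer rate
#'
#' Integrating the single-event contribution over uniformly distributed
#' event ages at constant rate rho yields the power law
#' \deqn{m(r) = \frac{f_1 f_2 K}{L_1 L_2} \frac{\rho}{\mu} r^{-3}.}
#'
#' @param r Match length (bp); vectorised.
#' @param params An [HGTModelParams-class].
#' @return Density in bp^-2.
#' @export
mldSteady <- function(r, params) {
    stopifnot(is(params, "HGTModelParams"))
    hgtPrefactor(params) / r^3
}

#' Power-law prefactor A of the steady-state MLD
#'
#' \deqn{A = \frac{K f_1 f_2}{L_1 L_2} \frac{\rho}{\mu}} interpreted as an
#' effective transfer rate per genome length: it grows with the bare event
#' rate rho, the segment length K and the fixation fractions, and falls
#' with the genome lengths and the substitution rate.
#'
#' @param params An [HGTModelParams-class].
#' @return Numeric A (bp).
#' @export
hgtPrefactor <- function(params) {
    stopifnot(is(params, "HGTModelParams"))
    params@K * params@f1 * params@f2 * params@rho /
        (params@L1 * params@L2 * params@mu)
}

#' Steady-state MLD with exponentially suppressed event ages
#'
#' When xenologs are slowly removed by deletions at rate lambda, event ages
#' are exponentially suppressed, P(t) = exp(-lambda t), and the MLD becomes
#' \deqn{m(r) = \frac{f_1 f_2 K}{L_1 L_2} \frac{\rho}{\mu}
#'   \left(r + \frac{\lambda}{2\mu}\right)^{-3},}
#' recovering the pure power law for r >> lambda / (2 mu).
#'
#' @param r Match length (bp); vectorised.
#' @param params An [HGTModelParams-class]; uses \code{lambda}.
#' @return Density in bp^-2.
#' @export
mldSuppressed <- function(r, params) {
    stopifnot(is(params, "HGTModelParams"))
    pre <- params@f1 * params@f2 * params@K / (params@L1 * params@L2)
    pre * (params@rho / params@mu) *
        (r + params@lambda / (2 * params@mu))^(-3)
}

#' MLD for a polynomial (Taylor) age distribution
#'
#' For an event-age distribution written as a Taylor series
#' P(t) = sum_i a_i t^i / i!, the age integral of the single-event
#' contribution evaluates term by term via the gamma integral
#' \deqn{\int_0^\infty t^i (2\mu t)^2 e^{-2\mu t r} dt =
#'   (i+1)(i+2)\,(2\mu)^{-(i+1)}\, r^{-(3+i)},}
#' so each term contributes a power law with exponent -(3+i); the tail is
#' dominated by the first non-zero coefficient and exponent -3 survives
#' whenever a_0 = P(0) > 0. With a = c(1) this reduces exactly to
#' [mldSteady()].
#'
#' @param r Match length (bp); vectorised.
#' @param params An [HGTModelParams-class].
#' @param coeffs Numeric vector of Taylor coefficients a_i (a_0 first).
#' @param nTerms Number of leading terms to evaluate (default all).
#' @return Density in bp^-2.
#' @export
mldTaylor <- function(r, params, coeffs, nTerms = length(coeffs)) {
    stopifnot(is(params, "HGTModelParams"), nTerms <= length(coeffs),
              nTerms >= 1)
    pre <- params@f1 * params@f2 * params@K / (params@L1 * params@L2) *
        params@rho
    out <- numeric(length(r))
    for (i in seq_len(nTerms) - 1L) {
        a <- coeffs[i + 1L]
        if (a == 0) next
        out <- out + a * (i + 1) * (i + 2) *
            (2 * params@mu)^(-(i + 1)) * r^(-(3 + i))
    }
    pre * out
}

#' Age posterior of an exact match
#'
#' Probability density (per generation) that a match of length r stems
#' from a transfer event of age t, under uniform event ages:
#' \deqn{p(t | r) = r^3 \mu (2\mu t)^2 e^{-2\mu t r}.}
#' It integrates to 1 over t in (0, Inf) and peaks at t = 1/(mu r).
#'
#' @param t Age in generations (>= 0); vectorised.
#' @param r Match length (bp).
#' @param mu Substitution rate per bp per generation.
#' @return Density per generation.
#' @export
agePosterior <- function(t, r, mu) {
    stopifnot(r >= 1, mu > 0)
    if (any(t < 0)) stop("'t' must be >= 0")
    r^3 * mu * (2 * mu * t)^2 * exp(-2 * mu * t * r)
}

#' Most likely age of a transfer event from a match length
#'
#' The mode of the age posterior, t_ML = 1/(mu r) generations, converted to
#' calendar years under an assumed generation time. Longer matches imply
#' more recent events; the detection horizon of a 300-bp threshold at
#' mu = 1e-9 is of order a thousand years.
#'
#' @param r Match length (bp).
#' @param mu Substitution rate per bp per generation (default 1e-9).
#' @param generationTimeHours Assumed generation time (default 10 h).
#' @param hoursPerYear Hours per year (default 8766, i.e. 365.25 days).
#' @return An [AgeEstimate-class].
#' @examples
#' mostLikelyAge(19117, mu = 1e-9) # about 60 years
#' @export
mostLikelyAge <- function(r, mu = 1e-9, generationTimeHours = 10,
                          hoursPerYear = 8766) {
    stopifnot(r >= 1, mu > 0, generationTimeHours > 0, hoursPerYear > 0)
    gen <- 1 / (mu * r)
    new("AgeEstimate", tGenerations = gen,
        tYears = gen * generationTimeHours / hoursPerYear,
        generationTimeHours = generationTimeHours,
        hoursPerYear = hoursPerYear)
}

#' Chance probability of a long exact match between diverged orthologs
#'
#' For two orthologous regions with per-site identity p, the probability of
#' an exact match of length r at a given position is p^r; at the default
#' p = 0.9 (an upper bound on nucleotide identity of conserved orthologs
#' between genera) a 300-bp exact match has probability ~1e-14, which is
#' why matches above this threshold are attributed to transfer rather than
#' descent.
#'
#' @param r Match length (bp).
#' @param identity Per-site identity p (default 0.9).
#' @return Probability p^r.
#' @export
collisionProbability <- function(r, identity = 0.9) {
    stopifnot(r >= 1, identity > 0, identity < 1)
    identity^r
}
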