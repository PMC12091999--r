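#' @include utils.R
NULL

#' Quasi-steady-state moments of a metabolite under gamma enzyme noise
#'
#' For the two-enzyme motif 0 -> X -> 0 with production rate v p(t) and
#' consumption rate u q(t) x(t), the quasi-steady-state concentration is
#' x = v p / (u q).  With p and q independent gamma(a, b) distributed
#' (the stationary law of stochastic transcription/translation), the
#' moments are
#' \deqn{<x> = (v/u) a/(a-1), \quad <x^2> = (v^2/u^2) a(a+1)/((a-1)(a-2)).}
#' The scale parameter b cancels.  The shape parameter a is the ratio of
#' the transcription rate to the protein degradation rate.
#'
#' @param a gamma shape parameter (> 2 for a finite second moment).
#' @param b gamma scale parameter (cancels; kept for completeness).
#' @param v,u kinetic constants of the producing and consuming reactions.
#' @return list with \code{mean} and \code{secondMoment}.
#' @export
#' @examples
#' qssMoments(3, v = 1, u = 1)  # mean 1.5, second moment 6
qssMoments <- function(a, b = 1, v = 1, u = 1) {
    if (a <= 1) stop("mean diverges for a <= 1")
    if (a <= 2) stop("second moment diverges for a <= 2")
    list(mean = (v / u) * a / (a - 1),
         secondMoment = (v / u)^2 * a * (a + 1) / ((a - 1) * (a - 2)))
}

#' Coefficient of variation of the quasi-steady-state concentration
#'
#' CV = sqrt((2a - 1) / (a (a - 2))), strictly decreasing in a on (2, Inf)
#' and divergent as a -> 2+.  For E. coli essential genes the proteomic
#' estimate of the shape parameter is a ~= 6.82 +- 2.34, giving a relative
#' noise strength of about 62 percent; the default perturbation strength of
#' 40 percent used throughout this package is a deliberately smaller value
#' than this ceiling (irreversible-reaction assumptions in the estimate bias
#' it upward).  The link is configuration, not computation.
#'
#' @param a gamma shape parameter (> 2).
#' @return the coefficient of variation.
#' @export
#' @examples
#' cvEstimate(6.82)  # ~0.62
cvEstimate <- function(a) {
    if (any(a <= 2)) stop("coefficient of variation diverges for a <= 2")
    sqrt((2 * a - 1) / (a * (a - 2)))
}

#' Monte-Carlo oracle for the quasi-steady-state noise
#'
#' Empirical mean, second moment and CV of x = v p / (u q) from paired
#' independent gamma(a, b) draws; used to cross-check the closed forms.
#'
#' @param a gamma shape parameter.
#' @param n number of draws (default 1e6).
#' @param b,v,u as in \code{\link{qssMoments}}.
#' @param seed optional integer seed.
#' @return list with \code{mean}, \code{secondMoment}, \code{cv} and their
#'   standard errors \code{seMean}, \code{seCV}.
#' @export
mcQssNoise <- function(a, n = 1e6, b = 1, v = 1, u = 1, seed = NULL) {
    withSeed(seed, {
        p <- stats::rgamma(n, shape = a, scale = b)
        q <- stats::rgamma(n, shape = a, scale = b)
        x <- v * p / (u * q)
        m <- mean(x)
        s2 <- mean(x^2)
        cv <- stats::sd(x) / m
        ## delta-method standard error of the CV
        v4 <- stats::var((x - m)^2)
        seSd <- sqrt(v4 / n) / (2 * stats::sd(x))
        seCV <- cv * sqrt((seSd / stats::sd(x))^2 +
                          (stats::sd(x) / sqrt(n) / m)^2)
        list(mean = m, secondMoment = s2, cv = cv,
             seMean = stats::sd(x) / sqrt(n), seCV = seCV)
    })
}
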