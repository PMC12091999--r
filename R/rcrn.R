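#' @include dynamics.R
NULL

#' Build a random catalytic reaction network (RCRN) toy cell
#'
#' Generates a connected Erdos-Renyi-style random network among
#' \code{nSpecies} metabolites (edges drawn uniformly without replacement,
#' redrawn up to \code{maxRetry} times if disconnected), assigns one
#' uniformly chosen catalyst per reaction edge, and draws the forward and
#' backward rate constants from \code{ratePool}.  Every metabolite is both a
#' reactant and a catalyst.  Only the first metabolite is taken up from the
#' environment (D_1 = 1, external concentration 1) and the last metabolite
#' is its transporter; the growth rate equals the total uptake, which
#' dilutes all concentrations, so the total concentration relaxes to 1.
#'
#' @param nSpecies number of metabolites N.
#' @param nReactions number of reaction edges R (default 3.5 N, rounded;
#'   the ratio is chosen so a random graph of this size is likely connected).
#' @param ratePool positive rates to sample v_ijk from; default draws
#'   10^U(-3.66, 7.13), the minimal model's rate-constant distribution.
#' @param seed optional integer seed.
#' @param maxRetry connectivity retry cap (default 100).
#' @return an \linkS4class{RcrnModel}.
#' @export
#' @examples
#' m <- buildRcrn(16, seed = 5)
buildRcrn <- function(nSpecies, nReactions = NULL, ratePool = NULL,
                      seed = NULL, maxRetry = 100L) {
    nSpecies <- as.integer(nSpecies)
    if (is.null(nReactions))
        nReactions <- as.integer(roundHalf(3.5 * nSpecies))
    nReactions <- as.integer(nReactions)
    if (nReactions < nSpecies - 1L)
        stop("nReactions must be at least nSpecies - 1 for connectivity")
    if (nReactions > choose(nSpecies, 2))
        stop("nReactions exceeds the number of distinct pairs")
    withSeed(seed, {
        all1 <- rep(seq_len(nSpecies - 1L), times = (nSpecies - 1L):1L)
        all2 <- unlist(lapply(seq_len(nSpecies - 1L),
                              function(i) (i + 1L):nSpecies))
        edges <- NULL
        for (try in seq_len(maxRetry)) {
            pick <- sample(length(all1), nReactions)
            g <- igraph::graph_from_edgelist(
                cbind(all1[pick], all2[pick]), directed = FALSE)
            g <- igraph::add_vertices(
                g, max(0, nSpecies - igraph::vcount(g)))
            if (igraph::is_connected(g)) {
                edges <- cbind(all1[pick], all2[pick])
                break
            }
        }
        if (is.null(edges))
            stop("could not draw a connected network in ", maxRetry,
                 " attempts; increase nReactions")
        drawRates <- function(k) {
            if (is.null(ratePool))
                10^stats::runif(k, -3.66, 7.13)
            else
                sample(ratePool, k, replace = TRUE)
        }
        e <- data.frame(
            i = as.integer(edges[, 1]),
            j = as.integer(edges[, 2]),
            cat = as.integer(sample(nSpecies, nReactions, replace = TRUE)),
            vf = drawRates(nReactions),
            vb = drawRates(nReactions))
        uptake <- numeric(nSpecies); uptake[1L] <- 1
        xext <- numeric(nSpecies); xext[1L] <- 1
        transporter <- rep(1L, nSpecies)
        transporter[1L] <- nSpecies
        new("RcrnModel",
            nSpecies = nSpecies,
            edges = e,
            uptake = uptake,
            externalConc = xext,
            transporter = transporter)
    })
}

#' Full RCRN response protocol: screen, then measure chi
#'
#' Mirrors the perturbation-response protocol used for kinetic models: the
#' attractor is searched from \code{nScreen} random initial concentrations,
#' instances showing multistability or numerical failure are rejected, and
#' the response ensemble is computed around the unique attractor.
#'
#' @param model an \linkS4class{RcrnModel}.
#' @param nScreen initial conditions for the attractor search (default 32).
#' @param nIni response trajectories (default 128).
#' @param strength perturbation strength (default 0.4).
#' @param seed optional integer seed.
#' @param ... integrator settings passed on.
#' @return a \linkS4class{ResponseEnsemble}, or NA with attribute
#'   \code{reason} if the instance was rejected (multistable or failed).
#' @export
rcrnResponse <- function(model, nScreen = 32L, nIni = 128L, strength = 0.4,
                         seed = NULL, ...) {
    scr <- tryCatch(
        screenMultistability(model, nInit = nScreen,
                             seed = if (is.null(seed)) NULL
                                    else childSeed(seed, 1L)),
        error = function(e) NULL)
    reject <- function(reason) structure(NA, reason = reason)
    if (is.null(scr))
        return(reject("screening failure"))
    if (!scr$singleAttractor)
        return(reject("multistable"))
    xSt <- .polishSteady(model, scr$attractors[1, ])
    st <- .stabilityAt(model, xSt)
    if (is.na(st) || !.isStable(st))
        return(reject("unstable attractor"))
    tryCatch(
        responseDistribution(model, xSt, nIni = nIni, strength = strength,
                             seed = if (is.null(seed)) NULL
                                    else childSeed(seed, 2L), ...),
        error = function(e) reject(conditionMessage(e)))
}
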