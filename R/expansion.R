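#' @include response.R
NULL

#' Cofactor-coupling probability of a model
#'
#' The fraction of reactions coupled to the cofactor pool, used as the
#' coupling probability for randomly added reactions.
#'
#' @param model a \linkS4class{MassActionModel}.
#' @return a fraction in [0, 1].
#' @export
couplingProbability <- function(model) {
    rx <- model@network@reactions
    if (nrow(rx) == 0L) return(0)
    mean(rx$coupled)
}

#' Sample one random added reaction
#'
#' Draws a uni-uni reaction between two distinct, randomly chosen
#' non-cofactor metabolites; with probability \code{pCofactor} the reaction
#' is upgraded to a bi-bi reaction coupled to a random interconversion of two
#' cofactor forms (random direction).  The rate constant is resampled from
#' the base model's empirical per-scheme rate pool (bootstrap) and the
#' irreversibility factors follow from the base model's chemical potentials
#' through the detailed-balance rule, exactly as in the generator.
#'
#' @param base a \linkS4class{MassActionModel} built by the generators (the
#'   species potentials must be available).
#' @param pCofactor coupling probability; default
#'   \code{couplingProbability(base)}.
#' @param seed optional integer seed.
#' @return a one-row reaction data.frame in the network's reaction format.
#' @export
sampleAddedReaction <- function(base, pCofactor = couplingProbability(base),
                                seed = NULL) {
    net <- base@network
    n <- net@nSpecies
    if (n < 2L) stop("base model needs at least 2 non-cofactor species")
    if (pCofactor > 0 && length(net@cofactor) == 0L)
        stop("base model has no cofactor: pCofactor must be 0")
    withSeed(seed, {
        pair <- sample(n, 2L)
        rx <- .emptyReactions(1L)
        rx$sub1 <- pair[1L]; rx$prd1 <- pair[2L]
        coupled <- stats::runif(1) < pCofactor
        if (coupled) {
            forms <- sample(3L, 2L)
            rx$sub2 <- n + forms[1L]
            rx$prd2 <- n + forms[2L]
            rx$coupled <- TRUE
        }
        ## empirical per-scheme rate pool (bootstrap resample)
        pool <- net@reactions$vr[net@reactions$coupled == coupled]
        if (!length(pool)) pool <- net@reactions$vr
        rx$vr <- sample(pool, 1L)
        mu <- net@mu
        dmu <- sum(mu[c(rx$prd1, rx$prd2)], na.rm = TRUE) -
               sum(mu[c(rx$sub1, rx$sub2)], na.rm = TRUE)
        rx$deltaMu <- dmu
        rx$kplus <- min(1, exp(-net@beta * dmu))
        rx$kminus <- min(1, exp(net@beta * dmu))
        rx
    })
}

#' Add random reactions to a model (network expansion)
#'
#' Appends \code{nAdd} reactions drawn by \code{\link{sampleAddedReaction}};
#' no new species are introduced, so the reaction density increases.
#' Duplicate reactant pairs are permitted.
#'
#' @param base a generated \linkS4class{MassActionModel}.
#' @param nAdd number of reactions to add.
#' @param pCofactor coupling probability (default: the base model's
#'   coupled-reaction fraction).
#' @param seed optional integer seed.
#' @return the expanded \linkS4class{MassActionModel}.
#' @export
addRandomReactions <- function(base, nAdd,
                               pCofactor = couplingProbability(base),
                               seed = NULL) {
    if (nAdd == 0L) return(base)
    withSeed(seed, {
        net <- base@network
        newrx <- do.call(rbind, lapply(seq_len(nAdd), function(k)
            sampleAddedReaction(base, pCofactor)))
        rx <- rbind(net@reactions, newrx)
        net2 <- initialize(net, reactions = rx)
        m <- buildKineticModel(net2, beta = base@beta)
        if (length(base@clamped))
            m <- initialize(m, clamped = base@clamped,
                            clampValues = base@clampValues)
        m
    })
}

## ---- enzymatic rate-law templates ---------------------------------------

#' Reversible Michaelis-Menten rate law (uni-uni)
#'
#' v = (v+ [S1] - v- [P1]) / (1 + [S1]/KS1 + [P1]/KP1).
#'
#' @param S1,P1 substrate and product concentrations.
#' @param vplus,vminus limiting rate constants.
#' @param KS1,KP1 dissociation constants.
#' @return reaction rate.
#' @export
reversibleMM <- function(S1, P1, vplus, vminus, KS1, KP1) {
    (vplus * S1 - vminus * P1) / (1 + S1 / KS1 + P1 / KP1)
}

#' Ordered bi-bi rate law
#'
#' v = (v+ [S1][S2] - v- [P1][P2]) /
#'     (1 + [S1]/KS1 + [P1]/KP1 + [S1][S2]/(KS1 KS2) + [P1][P2]/(KP1 KP2)).
#'
#' @param S1,S2,P1,P2 substrate and product concentrations.
#' @param vplus,vminus limiting rate constants.
#' @param KS1,KS2,KP1,KP2 dissociation constants.
#' @return reaction rate.
#' @export
orderedBiBi <- function(S1, S2, P1, P2, vplus, vminus, KS1, KS2, KP1, KP2) {
    (vplus * S1 * S2 - vminus * P1 * P2) /
        (1 + S1 / KS1 + P1 / KP1 + S1 * S2 / (KS1 * KS2) +
         P1 * P2 / (KP1 * KP2))
}

#' Factorized bi-bi rate law
#'
#' v = (v+ [S1][S2] - v- [P1][P2]) /
#'     ((1 + [S1]/KS1 + [P1]/KP1)(1 + [S2]/KS2 + [P2]/KP2)) -- the ordered
#' bi-bi numerator over a factorized denominator.
#'
#' @inheritParams orderedBiBi
#' @return reaction rate.
#' @export
factorizedBiBi <- function(S1, S2, P1, P2, vplus, vminus,
                           KS1, KS2, KP1, KP2) {
    (vplus * S1 * S2 - vminus * P1 * P2) /
        ((1 + S1 / KS1 + P1 / KP1) * (1 + S2 / KS2 + P2 / KP2))
}

## ---- elementary reaction decomposition ----------------------------------

#' Elementary reaction decomposition (ERD)
#'
#' Rewrites an enzymatic reaction as elementary enzyme binding, conversion
#' and release steps, each modeled with mass-action kinetics and with the
#' forward and backward directions treated as separate reactions:
#' uni-uni A = B becomes E+A = EA, EA = EB, EB = E+B (3 steps, new species
#' E, EA, EB); bi-uni A+B = C becomes E+A = EA, EA+B = EAB, EAB = EC,
#' EC = E+C (4 steps); bi-bi A+B = C+D adds the second release EC = ECD ...
#' analogously (5 steps, ordered mechanism).  The enzyme moiety (the sum of
#' the enzyme and all complex species) is conserved with total
#' \code{enzymeTotal}.
#'
#' @param substrates character vector of 1 or 2 substrate names.
#' @param products character vector of 1 or 2 product names.
#' @param rateConstants numeric vector of forward/backward mass-action rate
#'   constants, in step order (kf1, kb1, kf2, kb2, ...); length 2 x steps.
#' @param enzymeTotal conserved total enzyme concentration.
#' @param enzyme name of the enzyme species (default "E").
#' @return list with \code{species} (new enzyme-complex species names),
#'   \code{reactions} (data.frame: sub1, sub2, prd1, prd2 as names,
#'   kf, kb), and \code{enzymeTotal}.
#' @export
erdDecompose <- function(substrates, products, rateConstants,
                         enzymeTotal = 1, enzyme = "E") {
    ns <- length(substrates); np <- length(products)
    if (!ns %in% 1:2 || !np %in% 1:2)
        stop("only uni-uni, bi-uni, uni-bi and bi-bi schemes are supported")
    cplx <- function(...) paste0(enzyme, paste0(..., collapse = ""))
    steps <- list()
    ## binding of substrates in order
    bound <- character(0)
    for (s in substrates) {
        prev <- if (length(bound)) cplx(bound) else enzyme
        bound <- c(bound, s)
        steps[[length(steps) + 1L]] <-
            list(sub = c(prev, s), prd = cplx(bound))
    }
    ## internal conversion: E<subs> -> E<prods>
    steps[[length(steps) + 1L]] <-
        list(sub = cplx(bound), prd = cplx(products))
    ## release of products in reverse order
    held <- products
    while (length(held) > 1L) {
        rel <- held[length(held)]
        held <- held[-length(held)]
        steps[[length(steps) + 1L]] <-
            list(sub = cplx(c(held, rel)), prd = c(cplx(held), rel))
    }
    steps[[length(steps) + 1L]] <-
        list(sub = cplx(held), prd = c(enzyme, held))
    nsteps <- length(steps)
    if (length(rateConstants) != 2L * nsteps)
        stop("need ", 2L * nsteps, " rate constants (", nsteps,
             " steps, forward and backward treated as separate reactions)")
    rxn <- do.call(rbind, lapply(seq_len(nsteps), function(k) {
        st <- steps[[k]]
        data.frame(
            sub1 = st$sub[1], sub2 = if (length(st$sub) > 1) st$sub[2]
                                     else NA_character_,
            prd1 = st$prd[1], prd2 = if (length(st$prd) > 1) st$prd[2]
                                     else NA_character_,
            kf = rateConstants[2 * k - 1], kb = rateConstants[2 * k])
    }))
    newSpecies <- unique(c(enzyme,
        unlist(lapply(steps, function(st) c(st$sub, st$prd)))))
    newSpecies <- setdiff(newSpecies, c(substrates, products))
    list(species = newSpecies, reactions = rxn, enzymeTotal = enzymeTotal)
}

#' Build a mass-action model from an ERD scheme with fixed reactants
#'
#' Turns the output of \code{\link{erdDecompose}} into a simulatable
#' \linkS4class{MassActionModel} in which the original substrates and
#' products are clamped at supplied concentrations; only the enzyme cycle is
#' dynamic.  Used to verify the quasi-steady-state flux against the
#' closed-form enzymatic rate law.
#'
#' @param erd result of \code{\link{erdDecompose}}.
#' @param reactantConc named concentrations of the clamped substrates and
#'   products.
#' @return a \linkS4class{MassActionModel} with the reactants clamped.
#' @export
erdModel <- function(erd, reactantConc) {
    spec <- c(names(reactantConc), erd$species)
    idx <- function(s) match(s, spec)
    rxn <- erd$reactions
    R <- nrow(rxn)
    rx <- .emptyReactions(R)
    rx$sub1 <- idx(rxn$sub1); rx$sub2 <- idx(rxn$sub2)
    rx$prd1 <- idx(rxn$prd1); rx$prd2 <- idx(rxn$prd2)
    ## fold each step's mass-action constants into (vr, k+, k-) with
    ## max(k+, k-) = 1, preserving vr k+ = kf and vr k- = kb
    rx$vr <- pmax(rxn$kf, rxn$kb)
    rx$kplus <- rxn$kf / rx$vr
    rx$kminus <- rxn$kb / rx$vr
    rx$deltaMu <- ifelse(rxn$kb > 0 & rxn$kf > 0,
                         -log(rxn$kf / rxn$kb), Inf)
    net <- new("ReactionNetwork",
               nSpecies = length(spec),
               species = spec,
               reactions = rx,
               exchange = rep(FALSE, length(spec)),
               externalConc = rep(0, length(spec)),
               cofactor = list(),
               mu = rep(NA_real_, length(spec)),
               beta = 1,
               variant = "custom")
    m <- buildKineticModel(net, beta = 1)
    clampMany(m, match(names(reactantConc), spec),
              as.numeric(reactantConc))
}

## ---- expansion driver ----------------------------------------------------

#' Expand a base model repeatedly and measure the change in mean chi
#'
#' For each of \code{nNetworks} random extensions of the base model by
#' \code{nAdd} reactions: screen for a unique attractor from
#' \code{nScreen} initial conditions generated by a 40 percent perturbation
#' of the base attractor; if a single stable attractor is found, run the
#' perturbation-response protocol with a fresh perturbation set around the
#' extended model's own attractor and record the mean response coefficient.
#' Multistable and numerically failing extensions are rejected and counted.
#'
#' @param base a monostable \linkS4class{MassActionModel} with certified
#'   attractor \code{xSt}.
#' @param xSt attractor of the base model.
#' @param nAdd reactions added per extension.
#' @param nNetworks number of random extensions (default 256).
#' @param nIni response trajectories per accepted network (default 128).
#' @param nScreen screening initial conditions (default 128).
#' @param strength perturbation strength (default 0.4).
#' @param seed integer root seed; extension k uses childSeed(seed, nAdd, k).
#' @param acceptHook optional function(model, xSt) returning TRUE to accept
#'   an extended model (e.g. a growth-rate criterion); disabled by default.
#' @param ... integrator settings.
#' @return list with \code{nAdd}, \code{meanChis} (per accepted network),
#'   \code{nRejectedMultistable}, \code{nRejectedFailed}, \code{nNetworks}.
#' @export
expandAndMeasure <- function(base, xSt, nAdd, nNetworks = 256L,
                             nIni = 128L, nScreen = 128L, strength = 0.4,
                             seed = 1L, acceptHook = NULL, ...) {
    if (is(xSt, "SteadyState")) xSt <- steadyConc(xSt)
    xSt <- unname(xSt)
    p <- couplingProbability(base)
    meanChis <- numeric(0)
    nMulti <- 0L; nFail <- 0L
    for (k in seq_len(nNetworks)) {
        sd <- childSeed(seed, nAdd, k)
        m <- addRandomReactions(base, nAdd, pCofactor = p, seed = sd)
        ## screening ICs: perturbations of the *base* attractor
        scr <- tryCatch({
            sampler <- function(n) {
                P <- conservedPools(m)
                withSeed(childSeed(sd, 1L), t(replicate(n,
                    perturbState(xSt, strength = strength, pools = P))))
            }
            screenMultistability(m, nInit = nScreen, sampler = sampler, ...)
        }, error = function(e) NULL)
        if (is.null(scr)) { nFail <- nFail + 1L; next }
        if (!scr$singleAttractor) { nMulti <- nMulti + 1L; next }
        xe <- .polishSteady(m, scr$attractors[1, ])
        if (any(xe <= 0) || !.isStable(.stabilityAt(m, xe))) {
            nFail <- nFail + 1L; next
        }
        if (!is.null(acceptHook) && !isTRUE(acceptHook(m, xe))) {
            nFail <- nFail + 1L; next
        }
        ens <- tryCatch(
            responseDistribution(m, xe, nIni = nIni, strength = strength,
                                 seed = childSeed(sd, 2L), ...),
            error = function(e) NULL)
        if (is.null(ens)) { nFail <- nFail + 1L; next }
        meanChis <- c(meanChis, meanChi(ens))
    }
    if (!length(meanChis))
        stop("all extended networks were rejected (",
             nMulti, " multistable, ", nFail, " failed)")
    list(nAdd = nAdd, meanChis = meanChis,
         nRejectedMultistable = nMulti, nRejectedFailed = nFail,
         nNetworks = nNetworks)
}
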