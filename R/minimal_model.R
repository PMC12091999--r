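#' @include AllClasses.R AllGenerics.R utils.R
NULL

.emptyReactions <- function(n = 0L) {
    data.frame(sub1 = integer(n), sub2 = NA_integer_ + integer(n),
               prd1 = integer(n), prd2 = NA_integer_ + integer(n),
               vr = NA_real_ + numeric(n), kplus = NA_real_ + numeric(n),
               kminus = NA_real_ + numeric(n), deltaMu = NA_real_ + numeric(n),
               coupled = logical(n))
}

#' Build a sparse backbone network of uni-uni reactions
#'
#' Connects \code{nSpecies} chemicals C1, ..., CN as a linear chain
#' (C1 = C2 = ... = CN, N - 1 reactions) and then adds
#' \code{nReactions - (N - 1)} extra uni-uni reactions drawn uniformly
#' without replacement from the unordered pairs that do not yet share a
#' reaction.  Exchange with the environment is switched on for
#' max(2, Round(0.05 N)) species: always the two chain endpoints (so the
#' network has no dead ends), plus randomly chosen others.  The endpoint C1
#' is the nutrient with external concentration 100; every other exchanged
#' species has external concentration 1.
#'
#' @param nSpecies number of backbone chemicals N (>= 2).
#' @param nReactions total number of reactions R, with
#'   N - 1 <= R <= choose(N, 2).
#' @param seed optional integer seed for reproducibility.
#' @param exchangeFraction fraction of species given an exchange reaction
#'   (default 0.05).
#' @param nutrientConc external concentration of the nutrient endpoint
#'   (default 100).
#' @return an unparameterized \linkS4class{ReactionNetwork}.
#' @export
#' @examples
#' net <- buildBackbone(16, 23, seed = 1)
#' nrow(reactions(net))  # 23
buildBackbone <- function(nSpecies, nReactions, seed = NULL,
                          exchangeFraction = 0.05, nutrientConc = 100) {
    nSpecies <- as.integer(nSpecies)
    nReactions <- as.integer(nReactions)
    if (nSpecies < 2L)
        stop("nSpecies must be at least 2")
    if (nReactions < nSpecies - 1L)
        stop("nReactions must be at least nSpecies - 1 (connected chain)")
    if (nReactions > choose(nSpecies, 2))
        stop("nReactions exceeds the number of distinct species pairs")
    withSeed(seed, {
        chain <- cbind(seq_len(nSpecies - 1L), 2:nSpecies)
        nExtra <- nReactions - (nSpecies - 1L)
        extra <- NULL
        if (nExtra > 0L) {
            ## complement enumeration: all unordered pairs minus chain edges
            all1 <- rep(seq_len(nSpecies - 1L),
                        times = (nSpecies - 1L):1L)
            all2 <- unlist(lapply(seq_len(nSpecies - 1L),
                                  function(i) (i + 1L):nSpecies))
            adj <- all2 - all1 == 1L
            pool <- which(!adj)
            pick <- if (length(pool) == 1L) pool else
                sample(pool, nExtra, replace = FALSE)
            extra <- cbind(all1[pick], all2[pick])
        }
        edges <- rbind(chain, extra)
        rx <- .emptyReactions(nReactions)
        rx$sub1 <- as.integer(edges[, 1])
        rx$prd1 <- as.integer(edges[, 2])

        nEx <- max(2L, as.integer(roundHalf(exchangeFraction * nSpecies)))
        exch <- logical(nSpecies)
        exch[c(1L, nSpecies)] <- TRUE
        if (nEx > 2L) {
            others <- setdiff(seq_len(nSpecies), c(1L, nSpecies))
            exch[sample(others, nEx - 2L)] <- TRUE
        }
        xext <- rep(1, nSpecies)
        xext[1L] <- nutrientConc

        new("ReactionNetwork",
            nSpecies = nSpecies,
            species = paste0("C", seq_len(nSpecies)),
            reactions = rx,
            exchange = exch,
            externalConc = xext,
            cofactor = list(),
            mu = rep(NA_real_, nSpecies),
            beta = NA_real_,
            variant = "custom")
    })
}

#' Couple a fraction of reactions to a 3-form cofactor
#'
#' Adds the cofactor triple (A**, A*, A; standard potentials 1.0, 0.5, 0.0;
#' conserved total 1) to the network and couples exactly Round(f R) randomly
#' chosen backbone reactions to an interconversion between two distinct,
#' randomly chosen cofactor forms.  The direction is random: the chosen
#' "from" form is consumed on the forward (substrate) side of the reaction.
#' Cofactors never appear as backbone species and carry no exchange.
#'
#' @param net a \linkS4class{ReactionNetwork} without existing couplings.
#' @param f coupling fraction in [0, 1].
#' @param seed optional integer seed.
#' @param cofactor cofactor specification (forms, potentials, total);
#'   defaults to the A**/A*/A triple with potentials 1.0/0.5/0.0 and total 1.
#' @return the coupled \linkS4class{ReactionNetwork}.
#' @export
coupleCofactors <- function(net, f, seed = NULL,
                            cofactor = .defaultCofactor()) {
    stopifnot(is(net, "ReactionNetwork"))
    if (!is.numeric(f) || f < 0 || f > 1)
        stop("coupling fraction f must lie in [0, 1]")
    if (any(net@reactions$coupled))
        stop("network already has cofactor couplings")
    if (length(net@cofactor) > 0L)
        stop("network already has a cofactor")
    ok <- .validCofactor(cofactor)
    if (!isTRUE(ok)) stop(ok)
    withSeed(seed, {
        rx <- net@reactions
        R <- nrow(rx)
        nC <- as.integer(roundHalf(f * R))
        n <- net@nSpecies
        if (nC > 0L) {
            which_r <- if (nC == R) seq_len(R) else sample(R, nC)
            for (r in which_r) {
                forms <- sample(3L, 2L)       # ordered: from, to
                rx$sub2[r] <- n + forms[1L]
                rx$prd2[r] <- n + forms[2L]
                rx$coupled[r] <- TRUE
            }
        }
        new("ReactionNetwork",
            nSpecies = n,
            species = c(net@species, cofactor$forms),
            reactions = rx,
            exchange = c(net@exchange, rep(FALSE, 3L)),
            externalConc = c(net@externalConc, rep(0, 3L)),
            cofactor = cofactor,
            mu = c(net@mu, cofactor$potentials),
            beta = net@beta,
            variant = "cofactor")
    })
}

#' Assign standard chemical potentials and detailed-balanced irreversibilities
#'
#' Draws a standard chemical potential mu_n ~ U(0, 1) for every backbone
#' chemical (cofactor potentials stay at their fixed values), computes the
#' per-reaction potential difference
#' dMu_r = sum_{n in Prd(r)} mu_n - sum_{n in Sub(r)} mu_n, and sets the
#' irreversibility factors by the Arrhenius-type detailed-balance rule
#' k_r^{+-} = min(1, exp(-+ beta dMu_r)), so that k+/k- = exp(-beta dMu_r)
#' exactly and the larger of the two equals 1.
#'
#' @param net a \linkS4class{ReactionNetwork}; couple cofactors first so that
#'   dMu includes the cofactor potentials.
#' @param beta inverse temperature.
#' @param seed optional integer seed.
#' @return the network with mu, deltaMu, kplus, kminus and beta filled in.
#' @export
assignThermodynamics <- function(net, beta, seed = NULL) {
    stopifnot(is(net, "ReactionNetwork"), is.numeric(beta), beta >= 0)
    withSeed(seed, {
        n <- net@nSpecies
        mu <- net@mu
        mu[seq_len(n)] <- stats::runif(n)
        if (length(net@cofactor) > 0L)
            mu[n + 1:3] <- net@cofactor$potentials
        rx <- net@reactions
        musum <- function(i1, i2)
            mu[i1] + ifelse(is.na(i2), 0, mu[ifelse(is.na(i2), 1L, i2)])
        dmu <- musum(rx$prd1, rx$prd2) - musum(rx$sub1, rx$sub2)
        rx$deltaMu <- dmu
        rx$kplus <- pmin(1, exp(-beta * dmu))
        rx$kminus <- pmin(1, exp(beta * dmu))
        initialize(net, reactions = rx, mu = mu, beta = beta)
    })
}

#' Assign random rate constants v_r = 10^u, u ~ U(-3.66, 7.13)
#'
#' The decade range of the rate constants reproduces the empirical spread of
#' kinetic constants in genome-scale E. coli kinetic modeling.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param seed optional integer seed.
#' @param logRange range of log10 v_r (default c(-3.66, 7.13)).
#' @return the network with vr filled in.
#' @export
assignRates <- function(net, seed = NULL, logRange = c(-3.66, 7.13)) {
    stopifnot(is(net, "ReactionNetwork"))
    withSeed(seed, {
        rx <- net@reactions
        rx$vr <- 10^stats::runif(nrow(rx), logRange[1], logRange[2])
        initialize(net, reactions = rx)
    })
}

## stoichiometric matrix from the substrate/product multisets
.stoichFromReactions <- function(rx, ntot) {
    S <- matrix(0L, ntot, nrow(rx))
    for (r in seq_len(nrow(rx))) {
        for (i in c(rx$sub1[r], rx$sub2[r]))
            if (!is.na(i)) S[i, r] <- S[i, r] - 1L
        for (i in c(rx$prd1[r], rx$prd2[r]))
            if (!is.na(i)) S[i, r] <- S[i, r] + 1L
    }
    S
}

#' Build a simulatable mass-action model from a parameterized network
#'
#' Assembles the stoichiometric matrix (state vector: backbone species first,
#' then the three cofactor forms when present) and returns the kinetic model
#' dx_n/dt = sum_r S_nr J_r(x) + D_n (X_n - x_n) with mass-action fluxes
#' J_r = v_r (k_r^+ prod_{Sub(r)} x - k_r^- prod_{Prd(r)} x).  Cofactors
#' carry no exchange term.
#'
#' @param net a fully parameterized \linkS4class{ReactionNetwork}.
#' @param beta inverse temperature; defaults to the value stored during
#'   thermodynamic assignment.
#' @return a \linkS4class{MassActionModel}.
#' @export
buildKineticModel <- function(net, beta = net@beta) {
    stopifnot(is(net, "ReactionNetwork"))
    rx <- net@reactions
    if (nrow(rx) > 0 &&
        any(is.na(rx$vr) | is.na(rx$kplus) | is.na(rx$kminus)))
        stop("network is not fully parameterized; ",
             "run assignThermodynamics() and assignRates() first")
    ntot <- length(net@species)
    new("MassActionModel",
        network = net,
        stoich = .stoichFromReactions(rx, ntot),
        beta = if (is.na(beta)) NA_real_ else as.numeric(beta),
        clamped = integer(0),
        clampValues = numeric(0))
}

#' Generate a complete minimal cofactor model in one call
#'
#' Chains \code{\link{buildBackbone}}, \code{\link{coupleCofactors}},
#' \code{\link{assignThermodynamics}}, \code{\link{assignRates}} and
#' \code{\link{buildKineticModel}} under one seed.
#'
#' @param nSpecies backbone size N (default 64).
#' @param nReactions reaction count R (default 96).
#' @param f cofactor coupling fraction (default 0.5).
#' @param beta inverse temperature (default 10; the maximum standard
#'   potential difference of a cofactor-coupled reaction is 2.0, so
#'   beta = 10 caps the irreversibility at exp(-20)).
#' @param seed optional integer seed.
#' @return a \linkS4class{MassActionModel}.
#' @export
#' @examples
#' m <- generateMinimalModel(16, 23, f = 0.75, beta = 10, seed = 7)
generateMinimalModel <- function(nSpecies = 64, nReactions = 96, f = 0.5,
                                 beta = 10, seed = NULL) {
    withSeed(seed, {
        net <- buildBackbone(nSpecies, nReactions)
        net <- coupleCofactors(net, f)
        net <- assignThermodynamics(net, beta)
        net <- assignRates(net)
        buildKineticModel(net)
    })
}

#' Generate the catalytic variant (no cofactors, enzyme-like catalysts)
#'
#' Same backbone construction and thermodynamics as the minimal model, but
#' every reaction C_n = C_m proceeds with the catalytic help of a uniformly
#' chosen species C_l: C_n + C_l = C_m + C_l (autocatalysis l = n or l = m is
#' permitted).  The catalyst cancels from the stoichiometry and from the
#' potential difference, so dMu spans at most 1.0 (hence the default
#' beta = 20, matching the effective maximal beta*dMu of the cofactor model).
#'
#' @param nSpecies number of chemicals (default 67, comparable to a 64 + 3
#'   cofactor model).
#' @param nReactions reaction count R.
#' @param beta inverse temperature (default 20).
#' @param seed optional integer seed.
#' @return a \linkS4class{MassActionModel} with variant "catalytic".
#' @export
buildCatalyticVariant <- function(nSpecies = 67, nReactions, beta = 20,
                                  seed = NULL) {
    withSeed(seed, {
        net <- buildBackbone(nSpecies, nReactions)
        rx <- net@reactions
        cat <- sample(nSpecies, nrow(rx), replace = TRUE)
        rx$sub2 <- as.integer(cat)
        rx$prd2 <- as.integer(cat)
        net <- initialize(net, reactions = rx, variant = "catalytic")
        net <- assignThermodynamics(net, beta)
        net <- assignRates(net)
        buildKineticModel(net)
    })
}

#' Supremum of |dMu_r| over admissible reactions
#'
#' For the cofactor model, backbone potentials range over [0, 1] and the
#' cofactor potentials are {1.0, 0.5, 0.0}, so a coupled reaction can reach
#' |dMu| = 1 (backbone) + 1 (cofactor pair) = 2.  The catalytic variant has
#' no cofactor contribution (the catalyst cancels), giving 1.  Computed by
#' enumeration over the interval endpoints and all ordered cofactor pairs.
#'
#' @param variant "cofactor" or "catalytic".
#' @param muRange backbone potential range (default c(0, 1)).
#' @param cofactorPotentials the fixed cofactor potentials.
#' @return the supremum of |dMu_r|.
#' @export
maxPotentialDifference <- function(variant = c("cofactor", "catalytic"),
                                   muRange = c(0, 1),
                                   cofactorPotentials = c(1.0, 0.5, 0.0)) {
    variant <- match.arg(variant)
    backbone <- abs(outer(muRange, muRange, "-"))
    best <- max(backbone)
    if (variant == "cofactor") {
        cof <- abs(outer(cofactorPotentials, cofactorPotentials, "-"))
        best <- max(outer(backbone, cof, "+"))
    }
    best
}

#' Close a model (remove all exchange)
#'
#' Returns a copy with every exchange flag off.  A closed generated model is
#' detailed balanced and relaxes to the Boltzmann equilibrium
#' x_n = c exp(-beta mu_n) (one scale constant c per conserved pool), where
#' every individual reaction flux vanishes -- the package's thermodynamic
#' consistency oracle.
#'
#' @param model a \linkS4class{MassActionModel}.
#' @return the closed model.
#' @export
closeExchange <- function(model) {
    net <- model@network
    initialize(model,
               network = initialize(net,
                   exchange = rep(FALSE, length(net@species))))
}
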