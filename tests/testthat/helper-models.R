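# Fixtures are built in code; no data files.

# Hand-built mass-action model from a reaction table (lists of index
# vectors), optionally with exchange and clamping.
makeCustomModel <- function(species, sub1, sub2, prd1, prd2, vr,
                            kplus = 1, kminus = 0, exchange = NULL,
                            externalConc = NULL, clamp = integer(0),
                            clampValues = numeric(0)) {
    n <- length(species)
    R <- length(sub1)
    rx <- kinresponse:::.emptyReactions(R)
    rx$sub1 <- as.integer(sub1); rx$sub2 <- as.integer(sub2)
    rx$prd1 <- as.integer(prd1); rx$prd2 <- as.integer(prd2)
    rx$vr <- vr
    rx$kplus <- rep_len(kplus, R)
    rx$kminus <- rep_len(kminus, R)
    rx$deltaMu <- ifelse(rx$kplus > 0 & rx$kminus > 0,
                         -log(rx$kplus / rx$kminus), Inf)
    if (is.null(exchange)) exchange <- rep(FALSE, n)
    if (is.null(externalConc)) externalConc <- rep(0, n)
    net <- new("ReactionNetwork", nSpecies = as.integer(n),
               species = species, reactions = rx,
               exchange = exchange, externalConc = externalConc,
               cofactor = list(), mu = rep(NA_real_, n),
               beta = 1, variant = "custom")
    m <- buildKineticModel(net, beta = 1)
    if (length(clamp)) m <- clampMany(m, clamp, clampValues)
    m
}

# Two-species closed reversible reaction C1 <-> C2 with detailed-balanced
# irreversibilities for inverse temperature beta and potential gap dmu.
makeTwoSpecies <- function(beta = 2, dmu = 0.5, v = 1) {
    makeCustomModel(c("C1", "C2"), sub1 = 1, sub2 = NA, prd1 = 2, prd2 = NA,
                    vr = v, kplus = min(1, exp(-beta * dmu)),
                    kminus = min(1, exp(beta * dmu)))
}

# Smallest bistable mass-action network (autocatalytic production of X with
# first-order loss), in the package's |Sub| = |Prd| reaction form, with S, P
# clamped and weak exchange realized by scaling the reaction rates (exchange
# flags are binary).  Its positive steady states solve a cubic (polyroot
# oracle); the reduced (time-rescaled) parameters are D = c = 0.01, k4 = 0.2.
makeBistable <- function() {
    makeCustomModel(c("X", "Y", "S", "P"),
                    sub1 = c(3, 1, 1, 1), sub2 = c(2, 1, 2, NA),
                    prd1 = c(1, 1, 2, 4), prd2 = c(1, 2, 4, NA),
                    vr = c(100, 100, 100, 20),
                    exchange = c(TRUE, TRUE, FALSE, FALSE),
                    externalConc = c(0.01, 0.01, 0, 0),
                    clamp = c(3, 4), clampValues = c(1, 1e-6))
}

# Positive roots of the bistable fixture's reduced steady-state cubic,
# independent of the dynamics code.
bistableRoots <- function(D = 0.01, cc = 0.01, k4 = 0.2) {
    a3 <- -1 / (1 + D); a2 <- 2 / (1 + D) - 1
    a1 <- -D * cc / (1 + D) - k4 - D
    a0 <- 2 * D * cc / (1 + D) + D * cc
    r <- polyroot(c(a0, a1, a2, a3))
    sort(Re(r[abs(Im(r)) < 1e-9]))
}

# Mean chi of a generated minimal model, NA on any failure.
measureMeanChi <- function(model, seed, nIni = 32L) {
    ss <- tryCatch(findAttractor(model), error = function(e) NULL)
    if (is.null(ss) || !kinresponse:::.isStable(ss@maxReEig)) return(NA_real_)
    ens <- tryCatch(responseDistribution(model, ss, nIni = nIni, seed = seed),
                    error = function(e) NULL)
    if (is.null(ens)) return(NA_real_)
    meanChi(ens)
}
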