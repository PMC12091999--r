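test_that("added reactions respect the coupling probability and empirical rate pool", {
    base <- generateMinimalModel(16, 23, f = 0.75, beta = 10, seed = 71)
    expect_equal(couplingProbability(base),
                 roundHalf(0.75 * 23) / 23)
    ## p = 0: all additions uni-uni between non-cofactor species
    set.seed(72)
    for (k in 1:20) {
        rx <- sampleAddedReaction(base, pCofactor = 0)
        expect_true(is.na(rx$sub2) && is.na(rx$prd2))
        expect_true(rx$sub1 <= 16 && rx$prd1 <= 16 && rx$sub1 != rx$prd1)
        expect_true(rx$vr %in% reactions(base)$vr)    # bootstrap resample
        ## detailed balance against the base model's potentials
        mu <- base@network@mu
        expect_equal(log(rx$kplus / rx$kminus),
                     -10 * (mu[rx$prd1] - mu[rx$sub1]), tolerance = 1e-9)
    }
    ## p = 1: every addition is cofactor-coupled bi-bi
    for (k in 1:10) {
        rx <- sampleAddedReaction(base, pCofactor = 1)
        expect_true(rx$coupled && rx$sub2 > 16 && rx$prd2 > 16)
    }
    ## a cofactor-free base cannot take coupled additions
    mcat <- buildCatalyticVariant(8, 10, seed = 73)
    expect_error(sampleAddedReaction(mcat, pCofactor = 0.5), "no cofactor")
})

test_that("expansion adds reactions but never species", {
    base <- generateMinimalModel(12, 18, f = 0.5, beta = 10, seed = 74)
    ex <- addRandomReactions(base, 16, seed = 75)
    expect_identical(nStates(ex), nStates(base))
    expect_identical(speciesNames(ex), speciesNames(base))
    expect_identical(nrow(reactions(ex)), 18L + 16L)
    expect_identical(dim(ex@stoich), c(15L, 34L))
    expect_true(validObject(ex))
})

test_that("rate-law templates match their printed forms", {
    ## reversible MM: linear regime v ~ v+ S when P = 0 and S << KS
    expect_equal(reversibleMM(1e-6, 0, 2, 1, 1, 1), 2e-6, tolerance = 1e-5)
    ## and exact saturation algebra on a generic operand set
    expect_equal(reversibleMM(2, 3, 5, 7, 11, 13),
                 (5 * 2 - 7 * 3) / (1 + 2 / 11 + 3 / 13))
    ## ordered bi-bi vanishes at thermodynamic equilibrium
    expect_equal(orderedBiBi(2, 3, 1.5, 4, vplus = 1, vminus = 1,
                             KS1 = 1, KS2 = 2, KP1 = 3, KP2 = 4), 0)
    ## factorized = ordered numerator over the factorized denominator
    op <- list(S1 = 2, S2 = 0.5, P1 = 1.2, P2 = 0.3, vplus = 3, vminus = 0.7,
               KS1 = 1.1, KS2 = 0.9, KP1 = 2.2, KP2 = 0.4)
    num <- op$vplus * op$S1 * op$S2 - op$vminus * op$P1 * op$P2
    denO <- 1 + op$S1 / op$KS1 + op$P1 / op$KP1 +
        op$S1 * op$S2 / (op$KS1 * op$KS2) + op$P1 * op$P2 / (op$KP1 * op$KP2)
    denF <- (1 + op$S1 / op$KS1 + op$P1 / op$KP1) *
        (1 + op$S2 / op$KS2 + op$P2 / op$KP2)
    expect_equal(do.call(orderedBiBi, op), num / denO)
    expect_equal(do.call(factorizedBiBi, op), num / denF)
})

test_that("ERD produces the canonical step counts and conserves the enzyme moiety", {
    ## uni-uni: 3 elementary steps, new species E, EA, EB
    erd <- erdDecompose("A", "B", rateConstants = c(2, 1, 3, 0.5, 4, 0.25))
    expect_identical(nrow(erd$reactions), 3L)
    expect_identical(sort(erd$species), c("E", "EA", "EB"))
    expect_identical(erd$reactions$sub1[1], "E")
    ## bi-uni: 4 steps as E+A, EA+B, EAB = EC, EC = E+C
    erd2 <- erdDecompose(c("A", "B"), "C", rateConstants = rep(1, 8))
    expect_identical(nrow(erd2$reactions), 4L)
    expect_identical(sort(erd2$species), c("E", "EA", "EAB", "EC"))
    ## bi-bi ordered mechanism: 5 steps
    erd3 <- erdDecompose(c("A", "B"), c("C", "D"), rateConstants = rep(1, 10))
    expect_identical(nrow(erd3$reactions), 5L)
    expect_error(erdDecompose(c("A", "B", "C"), "D", rep(1, 10)), "scheme")

    ## the enzyme moiety is an exact conserved pool of the clamped model
    m <- erdModel(erd, c(A = 2, B = 0.5))
    P <- conservedPools(m)
    expect_identical(nrow(P), 1L)
    enz <- match(c("E", "EA", "EB"), speciesNames(m))
    expect_true(all(P[1, enz] == P[1, enz[1]]))
    expect_true(all(P[1, -enz] == 0))
    ## ... and it is constant along an integrated trajectory
    x0 <- c(2, 0.5, 0.6, 0.25, 0.15)
    tr <- integrateModel(m, x0, horizon = 1e3)
    tot <- colSums(concMatrix(tr)[enz, ])
    expect_lt(diff(range(tot)) / tot[1], 1e-8)
})

test_that("ERD quasi-steady-state flux matches the King-Altman closed form", {
    kf <- c(2.0, 3.5, 1.2); kb <- c(0.8, 0.6, 1.5)
    A <- 1.7; B <- 0.4; ET <- 1
    erd <- erdDecompose("A", "B",
                        rateConstants = c(kf[1], kb[1], kf[2], kb[2],
                                          kf[3], kb[3]))
    m <- erdModel(erd, c(A = A, B = B))
    enz <- match(c("E", "EA", "EB"), speciesNames(m))
    x0 <- numeric(5); x0[match(c("A", "B"), speciesNames(m))] <- c(A, B)
    x0[enz] <- ET / 3
    ss <- findAttractor(m, rbind(x0))
    x <- steadyConc(ss)
    ## flux through the release step EB = E + B at steady state
    J <- kf[3] * x[["EB"]] - kb[3] * x[["E"]] * B
    ## King-Altman directed-tree oracle for the 3-state cycle
    a <- kf[1] * A; b <- kb[1]; cc <- kf[2]; d <- kb[2]
    e <- kf[3]; f <- kb[3] * B
    w1 <- b * e + d * b + cc * e
    w2 <- a * d + a * e + f * d
    w3 <- f * cc + f * b + a * cc
    Joracle <- ET * (a * cc * e - b * d * f) / (w1 + w2 + w3)
    expect_equal(J, Joracle, tolerance = 1e-4)
})

test_that("a zero-reaction expansion reproduces the base ensemble exactly", {
    base <- generateMinimalModel(10, 15, f = 0.5, beta = 10, seed = 76)
    ss <- findAttractor(base)
    ex <- expandAndMeasure(base, ss, nAdd = 0, nNetworks = 1, nIni = 8,
                           nScreen = 4, seed = 77)
    sd <- childSeed(77, 0, 1)
    ref <- responseDistribution(base, ss, nIni = 8, seed = childSeed(sd, 2))
    expect_equal(ex$meanChis, meanChi(ref), tolerance = 1e-6)
    expect_equal(ex$nNetworks,
                 length(ex$meanChis) + ex$nRejectedMultistable +
                 ex$nRejectedFailed)
})
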