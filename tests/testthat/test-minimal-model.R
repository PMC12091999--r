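test_that("backbone construction gives a connected chain plus distinct extras", {
    ## minimum network: one reaction, both endpoints exchanged
    net <- buildBackbone(2, 1, seed = 1)
    expect_identical(nrow(reactions(net)), 1L)
    expect_true(all(net@exchange))

    ## with zero extras the edge set is exactly the path (oracle: the only
    ## connected 3-edge graph on 4 nodes reachable by this construction)
    for (s in 1:20) {
        net <- buildBackbone(4, 3, seed = s)
        rx <- reactions(net)
        edges <- sort(paste(pmin(rx$sub1, rx$prd1), pmax(rx$sub1, rx$prd1)))
        expect_identical(edges, c("1 2", "2 3", "3 4"))
    }

    ## paper-scale configuration: 63 chain + 33 extra reactions, connected
    net <- buildBackbone(64, 96, seed = 7)
    rx <- reactions(net)
    expect_identical(nrow(rx), 96L)
    pairs <- paste(pmin(rx$sub1, rx$prd1), pmax(rx$sub1, rx$prd1))
    expect_false(any(duplicated(pairs)))          # no duplicate reactant pairs
    expect_false(any(rx$sub1 == rx$prd1))         # no self-loops
    g <- igraph::graph_from_edgelist(cbind(rx$sub1, rx$prd1), directed = FALSE)
    expect_true(igraph::is_connected(g))
    ## exchange: Round(0.05 * 64) = 3 species, endpoints always included
    expect_identical(sum(net@exchange), 3L)
    expect_true(all(net@exchange[c(1, 64)]))
    expect_identical(net@externalConc[1], 100)
    expect_true(all(net@externalConc[net@exchange][-1] == 1))

    ## infeasible sizes rejected
    expect_error(buildBackbone(4, 2), "at least")
    expect_error(buildBackbone(4, 7), "exceeds")
})

test_that("backbones are connected across many seeds", {
    for (s in 1:100) {
        net <- buildBackbone(12, 17, seed = s)
        rx <- reactions(net)
        g <- igraph::graph_from_edgelist(cbind(rx$sub1, rx$prd1),
                                         directed = FALSE)
        expect_true(igraph::is_connected(g))
    }
})

test_that("cofactor coupling count equals Round(f R) on the (f, R) grid", {
    for (R in c(63L, 96L, 128L)) {
        for (f in c(0, 0.25, 0.5, 0.75, 1)) {
            net <- buildBackbone(64, R, seed = R + round(100 * f))
            cp <- coupleCofactors(net, f, seed = 11)
            expect_identical(sum(reactions(cp)$coupled),
                             as.integer(roundHalf(f * R)))
        }
    }
    ## rounding is half away from zero, so f = 0.5, R = 63 gives 32
    net <- buildBackbone(64, 63, seed = 3)
    expect_identical(sum(reactions(coupleCofactors(net, 0.5, seed = 1))$coupled),
                     32L)
    expect_error(coupleCofactors(buildBackbone(8, 10, seed = 1), 1.2), "0, 1")
})

test_that("coupled reactions interconvert two distinct cofactor forms", {
    net <- coupleCofactors(buildBackbone(16, 23, seed = 2), 1, seed = 3)
    rx <- reactions(net)
    expect_true(all(rx$coupled))
    expect_true(all(rx$sub2 > 16 & rx$prd2 > 16))
    expect_true(all(rx$sub2 != rx$prd2))
    ## cofactors never appear as backbone reactants and carry no exchange
    expect_true(all(rx$sub1 <= 16 & rx$prd1 <= 16))
    expect_false(any(net@exchange[17:19]))
})

test_that("thermodynamic assignment obeys the detailed-balance rule", {
    net <- coupleCofactors(buildBackbone(16, 23, seed = 4), 0.5, seed = 5)
    net <- assignThermodynamics(net, beta = 10, seed = 6)
    rx <- reactions(net)
    mu <- net@mu
    ## cofactor potentials read back as fixed constants
    expect_identical(mu[17:19], c(1.0, 0.5, 0.0))
    expect_true(all(mu[1:16] >= 0 & mu[1:16] <= 1))
    ## deltaMu recomputed independently from mu
    s2 <- ifelse(is.na(rx$sub2), 0, mu[ifelse(is.na(rx$sub2), 1, rx$sub2)])
    p2 <- ifelse(is.na(rx$prd2), 0, mu[ifelse(is.na(rx$prd2), 1, rx$prd2)])
    dmu <- (mu[rx$prd1] + p2) - (mu[rx$sub1] + s2)
    expect_equal(rx$deltaMu, dmu, tolerance = 1e-12)
    ## k+- = min(1, exp(-+ beta dMu)); ratio exp(-beta dMu) to machine precision
    expect_equal(rx$kplus, pmin(1, exp(-10 * dmu)), tolerance = 1e-14)
    expect_equal(rx$kminus, pmin(1, exp(10 * dmu)), tolerance = 1e-14)
    expect_equal(log(rx$kplus / rx$kminus), -10 * dmu, tolerance = 1e-9)
    expect_true(all(abs(pmax(rx$kplus, rx$kminus) - 1) < 1e-14))
    ## direct evaluation example: beta = 10, dMu = 0.3
    expect_equal(min(1, exp(-10 * 0.3)), exp(-3))
})

test_that("rate constants are log-uniform on [-3.66, 7.13]", {
    net <- assignRates(buildBackbone(500, 100000, seed = 8), seed = 9)
    v <- reactions(net)$vr
    expect_true(all(v > 0))
    lv <- log10(v)
    expect_true(all(lv >= -3.66 & lv <= 7.13))
    ## Kolmogorov-Smirnov against the uniform CDF at the 1% level
    ks <- suppressWarnings(ks.test(lv, "punif", -3.66, 7.13))
    expect_gt(ks$p.value, 0.01)
    ## u = 0 maps to v = 1 (trivial anchor of the parameterization)
    expect_equal(10^0, 1)
})

test_that("built models satisfy mass balance and stack cofactors last", {
    m <- generateMinimalModel(16, 23, f = 0.75, beta = 10, seed = 10)
    S <- m@stoich
    expect_identical(dim(S), c(19L, 23L))
    expect_true(all(colSums(S) == 0))                   # total mass balance
    expect_true(all(colSums(S[1:16, , drop = FALSE]) %in% c(0)))
    cofRows <- S[17:19, , drop = FALSE]
    cp <- reactions(m)$coupled
    for (j in seq_len(ncol(S))) {
        if (cp[j]) {
            expect_identical(sort(cofRows[, j]), c(-1L, 0L, 1L))
        } else {
            expect_true(all(cofRows[, j] == 0))
        }
    }
    expect_identical(speciesNames(m)[17:19], c("A**", "A*", "A"))
    ## unparameterized networks are rejected
    expect_error(buildKineticModel(buildBackbone(8, 10, seed = 1)),
                 "parameterized")
})

test_that("symmetric single-reaction model sits at equilibrium at x = (1, 1)", {
    m <- makeCustomModel(c("C1", "C2"), 1, NA, 2, NA, vr = 1,
                         kplus = 1, kminus = 1)
    expect_equal(modelRHS(m, c(1, 1)), c(0, 0))
})

test_that("catalytic variant cancels the catalyst from stoichiometry and dMu", {
    m <- buildCatalyticVariant(19, 23, beta = 20, seed = 12)
    rx <- reactions(m)
    expect_identical(rx$sub2, rx$prd2)              # catalyst on both sides
    expect_true(length(m@network@cofactor) == 0L)
    ## catalyst row of S is zero for non-autocatalytic reactions: column sums
    ## of S are zero and only sub1/prd1 have net stoichiometry
    for (j in seq_len(nrow(rx))) {
        col <- m@stoich[, j]
        expect_identical(sum(col), 0L)
        l <- rx$sub2[j]
        if (!l %in% c(rx$sub1[j], rx$prd1[j]))
            expect_identical(col[l], 0L)
    }
    ## dMu only sees the backbone pair, so |dMu| <= 1
    expect_true(all(abs(rx$deltaMu) <= 1))
    ## a zero-concentration catalyst silences its reactions
    x <- rep(1, 19); x[rx$sub2[1]] <- 0
    expect_equal(modelFluxes(m, x)[1], 0)
})

test_that("the admissible potential difference tops out at 2 (cofactor) and 1 (catalytic)", {
    expect_identical(maxPotentialDifference("cofactor"), 2)
    expect_identical(maxPotentialDifference("catalytic"), 1)
    ## sampling oracle: realized |dMu| never exceeds the enumerated supremum
    set.seed(13)
    for (k in 1:10) {
        m <- generateMinimalModel(8, 12, f = runif(1), beta = 10,
                                  seed = 100 + k)
        expect_true(all(abs(reactions(m)$deltaMu) <=
                        maxPotentialDifference("cofactor") + 1e-12))
    }
})
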