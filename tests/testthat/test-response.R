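# mirrors perturbState's internal factor draw, for the proportional check
withSeed_factors <- function(seed, n, strength) {
    kinresponse:::withSeed(seed, runif(n, 1 - strength, 1 + strength))
}

test_that("perturbations stay within bounds and restore pool totals exactly", {
    set.seed(1)
    xst <- 10^runif(19, -2, 2)
    ## no pools: output is exactly r * xst with r in [0.6, 1.4]
    x <- perturbState(xst, strength = 0.4, seed = 2)
    r <- x / xst
    expect_true(all(r >= 0.6 & r <= 1.4))

    ## disjoint pools (the cofactor triple): uniform per-pool rescale,
    ## total restored exactly
    P <- matrix(0, 1, 19); P[1, 17:19] <- 1
    xst2 <- xst; xst2[17:19] <- c(0.2, 0.3, 0.5)   # pool total 1
    x2 <- perturbState(xst2, strength = 0.4, pools = P, seed = 3)
    expect_equal(sum(x2[17:19]), 1, tolerance = 1e-13)
    ## within the pool the three factors are proportional to one common scale
    rr <- x2[17:19] / xst2[17:19]
    base <- rr / withSeed_factors(3, 19, 0.4)[17:19]
    expect_lt(diff(range(base)), 1e-12)

    ## overlapping mixed-sign pools (chain moiety): multiplicative Newton
    ## projection, totals restored to cancellation precision, all positive
    P2 <- rbind(P[1, ], c(rep(c(1, -1), length.out = 16), 2, 1, 0))
    x3 <- perturbState(xst2, strength = 0.4, pools = P2, seed = 4)
    expect_true(all(x3 > 0))
    tgt <- as.numeric(P2 %*% xst2)
    got <- as.numeric(P2 %*% x3)
    expect_lt(max(abs(got - tgt) / as.numeric(abs(P2) %*% x3)), 1e-11)

    expect_error(perturbState(xst, strength = 1.2), "strength")
})

test_that("the response coefficient is a normalized peak log-excursion", {
    ## monotone decay gives chi = 1 exactly (max at t = 0)
    tgrid <- seq(0, 5, length.out = 50)
    xst <- c(1, 1)
    states <- rbind(exp(0.1 * exp(-tgrid)), exp(-0.05 * exp(-tgrid)))
    tr <- new("Trajectory", times = tgrid, states = states,
              converged = TRUE, failureReason = "")
    expect_identical(responseCoefficient(tr, xst), 1)

    ## direct ratio: initial deviation (0.1, 0), peak (0.2, 0) -> chi = 2
    states2 <- rbind(exp(c(0.1, 0.2, 0.05, 0.0)), rep(1, 4))
    tr2 <- new("Trajectory", times = 0:3, states = states2,
               converged = TRUE, failureReason = "")
    expect_equal(responseCoefficient(tr2, xst), 2)

    ## permutation invariance of the norm
    m <- generateMinimalModel(10, 15, f = 0.5, beta = 10, seed = 55)
    ss <- findAttractor(m)
    x0 <- perturbState(steadyConc(ss), pools = conservedPools(m), seed = 6)
    tr3 <- integrateModel(m, x0, horizon = 1e5)
    chi <- responseCoefficient(tr3, steadyConc(ss))
    perm <- sample(13)
    tr3p <- new("Trajectory", times = timeGrid(tr3),
                states = concMatrix(tr3)[perm, ], converged = TRUE,
                failureReason = "")
    expect_equal(responseCoefficient(tr3p, steadyConc(ss)[perm]), chi)

    ## zero initial displacement is a contract violation
    flat <- new("Trajectory", times = 0:1, states = cbind(xst, xst),
                converged = TRUE, failureReason = "")
    expect_error(responseCoefficient(flat, xst), "undefined")
})

test_that("adaptive-grid chi matches a dense brute-force sweep on a non-normal system", {
    ## dx/dt = A x with A = [[-1, 10], [0, -1]]: e^{At} = e^-t [[1, 10t], [0, 1]]
    A <- rbind(c(-1, 10), c(0, -1))
    d0 <- c(0.05, 0.03)
    ## package path: stiff integration of x = exp(delta) on the log grid used
    ## by the response protocol, chi from the Trajectory
    rhs <- function(t, y, p) list(as.numeric(y * (A %*% log(y))))
    tt <- kinresponse:::logTimes(50, 512L)
    out <- deSolve::lsoda(y = exp(d0), times = tt, func = rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-13)
    tr <- new("Trajectory", times = tt, states = t(unclass(out)[, -1]),
              converged = TRUE, failureReason = "")
    chiGrid <- responseCoefficient(tr, c(1, 1))
    ## oracle: closed-form matrix exponential on 1e5 uniform time samples
    ts <- seq(0, 50, length.out = 1e5)
    nrm <- sqrt((exp(-ts) * (d0[1] + 10 * ts * d0[2]))^2 +
                (exp(-ts) * d0[2])^2)
    chiBrute <- max(nrm) / sqrt(sum(d0^2))
    expect_gt(chiBrute, 1.5)            # genuinely non-normal amplification
    expect_equal(chiGrid, chiBrute, tolerance = 1e-3)
})

test_that("response ensembles are deterministic under a seed and report failures", {
    m <- generateMinimalModel(12, 18, f = 0.75, beta = 10, seed = 77)
    ss <- findAttractor(m)
    e1 <- responseDistribution(m, ss, nIni = 12, seed = 5)
    e2 <- responseDistribution(m, ss, nIni = 12, seed = 5)
    expect_identical(chis(e1), chis(e2))
    expect_true(all(chis(e1) >= 1))
    expect_identical(length(chis(e1)) + nFailed(e1), 12L)
    expect_equal(meanChi(e1), mean(chis(e1)))
})

test_that("a strongly stable near-linear model concentrates at chi = 1", {
    ## f = 0 minimal model: linear uni-uni network, monotone log-space decay
    m <- generateMinimalModel(12, 18, f = 0, beta = 10, seed = 88)
    ss <- findAttractor(m)
    ens <- responseDistribution(m, ss, nIni = 24, seed = 6)
    expect_lt(meanChi(ens), 1.2)
    expect_gte(min(chis(ens)), 1)
})

test_that("linearized response shares displacements and is exact for linear dynamics", {
    m <- generateMinimalModel(12, 18, f = 0.75, beta = 10, seed = 99)
    ss <- findAttractor(m)
    ## shared seed -> identical perturbation factors, hence identical x(0)
    f1 <- kinresponse:::withSeed(41, matrix(runif(6 * 15, 0.6, 1.4), 6, 15))
    e1 <- linearizedResponseDistribution(m, ss, nIni = 6, seed = 41)
    e2 <- linearizedResponseDistribution(m, ss, nIni = 6, factors = f1)
    expect_equal(chis(e1), chis(e2), tolerance = 1e-12)
    expect_true(all(chis(e1) >= 1))

    ## symmetric negative-definite Jacobian: deviation norm decays
    ## monotonically, so every linearized chi is 1 (pure-exchange model)
    mlin <- makeCustomModel(paste0("X", 1:3), integer(0), integer(0),
                            integer(0), integer(0), vr = numeric(0),
                            exchange = rep(TRUE, 3),
                            externalConc = c(2, 1, 0.5))
    xst <- c(2, 1, 0.5)
    el <- linearizedResponseDistribution(mlin, xst, nIni = 8, seed = 42)
    expect_equal(chis(el), rep(1, 8), tolerance = 1e-9)
})
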