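test_that("compiled integration matches the R-level RHS and a closed form", {
    ## closed form: C1 -> C2 irreversible linear decay, x1(t) = e^{-t}
    m <- makeCustomModel(c("C1", "C2"), 1, NA, 2, NA, vr = 1)
    tr <- integrateModel(m, c(1, 1e-8), horizon = 10, reltol = 1e-10,
                         abstol = 1e-14)
    expect_true(isConverged(tr))
    i10 <- which.min(abs(timeGrid(tr) - 10))
    expect_equal(unname(concMatrix(tr)["C1", i10]), exp(-timeGrid(tr)[i10]),
                 tolerance = 1e-7)

    ## compiled core vs reference R implementation on a random minimal model
    m2 <- generateMinimalModel(12, 20, f = 0.6, beta = 10, seed = 3)
    set.seed(4)
    x0 <- 10^runif(15, -1, 1)
    x0 <- kinresponse:::.restorePools(x0, defaultInitialState(m2),
                                      conservedPools(m2))
    tt <- kinresponse:::logTimes(1e4, 150)
    rc <- kinresponse:::.odeRun(m2, x0, tt, reltol = 1e-9, abstol = 1e-14)
    rr <- deSolve::lsoda(y = x0, times = tt,
                         func = function(t, y, p) list(modelRHS(m2, y)),
                         parms = NULL, rtol = 1e-9, atol = 1e-14)
    expect_lt(max(abs(rc$states - t(unclass(rr)[, -1])) /
                  pmax(abs(t(unclass(rr)[, -1])), 1e-10)), 1e-5)
})

test_that("two-species equilibrium ratio equals exp(beta dMu)", {
    beta <- 2; dmu <- 0.5
    m <- makeTwoSpecies(beta = beta, dmu = dmu)
    for (x0 in list(c(1, 1), c(3, 0.2))) {
        ss <- findAttractor(m, rbind(x0))
        x <- steadyConc(ss)
        expect_equal(x[["C1"]] / x[["C2"]], exp(beta * dmu), tolerance = 1e-8)
        expect_equal(sum(x), sum(x0), tolerance = 1e-8)  # closed: mass kept
    }
})

test_that("attractor search certifies a tight residual and is idempotent", {
    m <- generateMinimalModel(16, 23, f = 0.75, beta = 10, seed = 42)
    ss <- findAttractor(m)
    x <- steadyConc(ss)
    ## independent residual evaluation at the returned point, against the
    ## net-flux bound or the double-precision cancellation floor of the RHS
    ## (gross flux terms can sit 8 orders above the net fluxes), whichever
    ## is larger
    rx <- reactions(m)
    s2 <- ifelse(is.na(rx$sub2), 1, x[ifelse(is.na(rx$sub2), 1, rx$sub2)])
    p2 <- ifelse(is.na(rx$prd2), 1, x[ifelse(is.na(rx$prd2), 1, rx$prd2)])
    gross <- max(rx$vr * (rx$kplus * x[rx$sub1] * s2 +
                          rx$kminus * x[rx$prd1] * p2))
    expect_lt(max(abs(modelRHS(m, x))),
              max(1e-10 * max(abs(modelFluxes(m, x))), 1e-15 * gross))
    expect_lt(as.numeric(maxReEig(ss)), 0)
    ## idempotence: restarting from the attractor returns the same point
    ss2 <- findAttractor(m, rbind(unname(x)))
    expect_lt(max(abs(log(steadyConc(ss2)) - log(x))), 1e-10)
    ## starting the integrator at the attractor stays there
    tr <- integrateModel(m, x, horizon = 100)
    dev <- abs(log(concMatrix(tr)) - log(as.numeric(x)))
    expect_lt(max(dev), 1e-4)
})

test_that("conserved pools are exact left-null vectors", {
    m <- generateMinimalModel(16, 23, f = 0.75, beta = 10, seed = 42)
    P <- conservedPools(m)
    expect_gte(nrow(P), 1L)
    ## every pool vector annihilates S exactly and avoids exchanged species
    expect_true(all(P %*% m@stoich == 0))
    expect_true(all(P[, m@network@exchange] == 0))
    ## the unit cofactor-total vector lies in the span
    cof <- c(rep(0, 16), 1, 1, 1)
    sol <- qr.solve(t(P), cof)
    expect_lt(max(abs(as.numeric(t(P) %*% sol) - cof)), 1e-9)

    ## fully exchanged network has no conservation
    net <- m@network
    mAll <- buildKineticModel(initialize(net,
        exchange = rep(TRUE, 19)), beta = 10)
    expect_identical(nrow(conservedPools(mAll)), 0L)

    ## random small integer matrices: exact annihilation
    set.seed(7)
    for (k in 1:20) {
        A <- matrix(sample(-2:2, 20, replace = TRUE), 4, 5)
        B <- kinresponse:::intLeftNull(A)
        if (nrow(B)) expect_true(all(B %*% A == 0))
        ## rank check: dim(left null) = nrow - rank
        expect_identical(nrow(B), 4L - qr(A)$rank)
    }
})

test_that("pools are constant along integrated trajectories", {
    m <- generateMinimalModel(12, 18, f = 0.75, beta = 10, seed = 21)
    P <- conservedPools(m)
    ss <- findAttractor(m)
    x0 <- perturbState(steadyConc(ss), pools = P, seed = 9)
    tr <- integrateModel(m, x0, horizon = 1e6)
    vals <- P %*% concMatrix(tr)
    for (p in seq_len(nrow(vals))) {
        drift <- diff(range(vals[p, ])) / max(abs(vals[p, 1]), 1e-300)
        expect_lt(drift, 1e-6)
    }
    ## the cofactor total stays at 1
    cofTotal <- colSums(concMatrix(tr)[13:15, ])
    expect_lt(max(abs(cofTotal - 1)), 1e-6)
})

test_that("multistability screening separates the bistable fixture's basins", {
    ## monostable system first
    m1 <- makeTwoSpecies()
    scr1 <- screenMultistability(m1, nInit = 16, seed = 2,
        sampler = function(n) {
            X <- matrix(10^runif(n * 2, -2, 2), n, 2)
            X / rowSums(X) * 2      # fix the conserved total
        })
    expect_true(scr1$singleAttractor)

    ## bistable fixture: attractors match the polyroot oracle
    m2 <- makeBistable()
    rts <- bistableRoots()
    expect_identical(length(rts), 3L)
    scr2 <- screenMultistability(m2, nInit = 48, seed = 5,
        sampler = function(n) {
            X <- matrix(10^runif(n * 4, -3, 1), n, 4)
            X[, 3] <- 1; X[, 4] <- 1e-6
            X
        })
    expect_false(scr2$singleAttractor)
    expect_identical(nrow(scr2$attractors), 2L)
    found <- sort(scr2$attractors[, 1])
    expect_equal(found, rts[c(1, 3)], tolerance = 1e-4)
    ## the middle root is the saddle separating the basins
    D <- 0.01
    ymid <- (rts[2]^2 + D * 0.01) / (1 + D)
    expect_gt(as.numeric(
        kinresponse:::.stabilityAt(m2, c(rts[2], ymid, 1, 1e-6))), 0)
    expect_error(screenMultistability(m2, nInit = 1), "nInit")
})

test_that("linearization is exact for mass action and certifies stability", {
    ## scalar decay dx/dt = -x (pure exchange toward zero): Jacobian is -1
    m <- makeCustomModel("X", integer(0), integer(0), integer(0), integer(0),
                         vr = numeric(0), exchange = TRUE, externalConc = 0)
    expect_equal(modelJacobian(m, 1)[1, 1], -1)

    m2 <- generateMinimalModel(10, 15, f = 0.5, beta = 10, seed = 31)
    set.seed(32)
    x <- 10^runif(13, -1, 1)
    J <- modelJacobian(m2, x)
    ## finite-difference cross-check, entrywise relative 1e-6
    h <- 1e-7
    Jfd <- sapply(seq_along(x), function(j) {
        xp <- x; xm <- x
        xp[j] <- x[j] * (1 + h); xm[j] <- x[j] * (1 - h)
        (modelRHS(m2, xp) - modelRHS(m2, xm)) / (xp[j] - xm[j])
    })
    scale <- max(abs(J))
    expect_lt(max(abs(J - Jfd)) / scale, 1e-6)

    ss <- findAttractor(m2)
    expect_lt(as.numeric(maxReEig(ss)), 0)
    lin <- linearizeModel(m2, steadyConc(ss))
    expect_false(lin$illConditioned)
    ## linear simulator decays to zero for pool-preserving displacements
    ## (components along conserved pools sit on exact zero modes and persist)
    xst <- unname(steadyConc(ss))
    d0 <- perturbState(xst, pools = conservedPools(m2), seed = 33) - xst
    dT <- lin$simulate(d0, c(0, 10^seq(-2, 7, length.out = 60)))
    expect_lt(sqrt(sum(dT[, ncol(dT)]^2)), 1e-5 * sqrt(sum(d0^2)))
})
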