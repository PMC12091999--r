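#' @include dynamics.R
NULL

#' Multiplicative perturbation preserving conserved pools
#'
#' Each concentration is multiplied by an independent uniform factor
#' r_n ~ U(1 - strength, 1 + strength) (so strength = 0.4 gives factors in
#' [0.6, 1.4]); afterwards the species within each conserved pool are
#' rescaled by a common factor so that every pool total is restored exactly
#' to its value at \code{xSt}.  The result is strictly positive.
#'
#' @param xSt positive steady-state concentrations.
#' @param strength maximal relative perturbation, in (0, 1) (default 0.4).
#' @param pools conserved-pool matrix (pools x species), e.g. from
#'   \code{\link{conservedPools}}; pool supports must not overlap.
#' @param seed optional integer seed.
#' @param factors optional pre-drawn perturbation factors (for paired
#'   designs); overrides the random draw.
#' @return perturbed concentration vector.
#' @export
perturbState <- function(xSt, strength = 0.4,
                         pools = matrix(0, 0, length(xSt)),
                         seed = NULL, factors = NULL) {
    stopifnot(all(xSt > 0))
    if (!is.numeric(strength) || strength <= 0 || strength >= 1)
        stop("strength must lie in (0, 1): larger values would allow zero ",
             "or negative concentrations")
    withSeed(seed, {
        r <- if (is.null(factors))
            stats::runif(length(xSt), 1 - strength, 1 + strength)
        else factors
        x <- .restorePools(r * xSt, xSt, pools)
        if (is.null(x))
            stop("could not restore conserved pools while keeping all ",
                 "concentrations positive")
        x
    })
}

## Restore pool totals of x to those of xSt exactly.  Disjoint pool supports
## (the generic case: one cofactor pool, possibly a closed-system mass pool)
## are rescaled per pool by a common factor; overlapping supports (which
## arise in very sparse networks with effectively blocked reactions) fall
## back to the minimal-norm additive projection onto the affine constraint
## set, with the perturbation damped towards xSt until the projected state is
## strictly positive.  Returns NULL if positivity cannot be restored.
.restorePools <- function(x, xSt, pools) {
    if (!nrow(pools)) return(x)
    supp <- lapply(seq_len(nrow(pools)), function(p) which(pools[p, ] != 0))
    if (!any(duplicated(unlist(supp)))) {
        for (p in seq_len(nrow(pools))) {
            s <- supp[[p]]
            tgt <- sum(pools[p, s] * xSt[s])
            cur <- sum(pools[p, s] * x[s])
            x[s] <- x[s] * (tgt / cur)
        }
        return(x)
    }
    ## overlapping supports: multiplicative projection x * exp(t(P) lambda),
    ## strictly positive by construction; Newton on the (few) multipliers
    ## lambda, with the Jacobian P diag(x) t(P) positive definite.
    ## This solves the strictly convex problem
    ##   min_lambda  sum_i x_i exp((t(P) lambda)_i) - t(target) lambda,
    ## whose optimum satisfies P y = target; damped Newton with a
    ## backtracking line search therefore converges globally.
    target <- as.numeric(pools %*% xSt)
    lambda <- numeric(nrow(pools))
    phi <- function(l) {
        e <- as.numeric(t(pools) %*% l)
        if (max(e) > 500) return(Inf)
        sum(x * exp(e)) - sum(target * l)
    }
    f0 <- phi(lambda)
    for (it in 1:200) {
        y <- x * exp(as.numeric(t(pools) %*% lambda))
        g <- as.numeric(pools %*% y) - target
        ## per-pool tolerance relative to the cancellation scale sum(|P| y):
        ## mixed-sign pools cannot be balanced more accurately in doubles
        gscale <- as.numeric(abs(pools) %*% y) + 1e-300
        if (all(abs(g) <= 1e-12 * gscale)) return(y)
        H <- pools %*% (y * t(pools))
        step <- tryCatch(solve(H, g), error = function(e) NULL)
        if (is.null(step)) step <- g / max(diag(H))
        gn0 <- max(abs(g))
        a <- 1
        repeat {
            l1 <- lambda - a * step
            f1 <- phi(l1)
            y1 <- x * exp(as.numeric(t(pools) %*% l1))
            gn1 <- max(abs(as.numeric(pools %*% y1) - target))
            ## accept on potential decrease or (near the optimum, where phi
            ## differences fall below double precision) on gradient decrease
            if (f1 < f0 || gn1 < 0.9 * gn0 || a < 1e-12) break
            a <- a / 2
        }
        if (a < 1e-12) return(NULL)
        lambda <- l1
        f0 <- f1
    }
    NULL
}

#' Response coefficient chi of a relaxation trajectory
#'
#' chi = max_t ||ln x(t) - ln x_st|| / ||ln x(0) - ln x_st|| with the
#' Euclidean norm; the maximum runs over the trajectory's dense output
#' including t = 0, so chi >= 1 always.  chi = 1 means the log-space distance
#' to the attractor decays monotonically from its initial value; chi >> 1
#' means the perturbation is transiently amplified.
#'
#' @param traj a converged \linkS4class{Trajectory}.
#' @param xSt the steady state the trajectory relaxes to.
#' @return chi (a scalar >= 1).
#' @export
responseCoefficient <- function(traj, xSt) {
    stopifnot(is(traj, "Trajectory"), all(xSt > 0))
    dev <- log(traj@states) - log(as.numeric(xSt))
    norms <- sqrt(colSums(dev^2))
    if (norms[1] == 0)
        stop("x(0) equals the steady state: response coefficient undefined")
    max(norms) / norms[1]
}

## Integrate one perturbed state and return its chi, stopping early once the
## log-distance to the attractor has fallen below a small fraction of its
## initial value or the derivative-residual criterion flags a numerically
## steady point.  chi is the maximum over the integrated window (including
## t = 0) in either case: trajectories that have not yet returned by the
## time cap still carry a well-defined chi, as in a fixed-horizon protocol;
## only hard numerical failures are reported as such.
.chiTrajectory <- function(model, x0, xst, reltol = 1e-7, abstol = 1e-12,
                           tcap = 1e10, npts = 512L,
                           distFraction = 1e-3) {
    ln0 <- log(x0) - log(xst)
    d0 <- sqrt(sum(ln0^2))
    if (d0 == 0)
        return(list(ok = FALSE, reason = "zero initial displacement"))
    disttol <- max(1e-9, distFraction * d0)
    run <- .odeRun(model, unname(x0), logTimes(tcap, npts),
                   rootmode = 3L, xst = unname(xst), disttol = disttol,
                   epsabs = 1e-13, epsrel = 1e-10,
                   reltol = reltol, abstol = abstol)
    if (!run$ok)
        return(list(ok = FALSE, reason = run$reason))
    dev <- log(run$states) - log(as.numeric(xst))
    norms <- sqrt(colSums(dev^2))
    dEnd <- norms[length(norms)]
    list(ok = TRUE, chi = max(norms) / d0,
         returned = dEnd <= max(disttol * 1.01, 0.01 * d0))
}

#' Perturbation-response ensemble of a model around its attractor
#'
#' Draws \code{nIni} conserved-pool-preserving multiplicative perturbations
#' of the attractor, integrates each relaxation, and collects the response
#' coefficients.  Trajectories that fail numerically or do not return to the
#' attractor are excluded from the distribution and counted in
#' \code{nFailed}; more than 50 percent failures raises an error.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param xSt certified stable attractor (a \linkS4class{SteadyState} or a
#'   concentration vector).
#' @param nIni number of perturbation trials (default 128).
#' @param strength perturbation strength (default 0.4).
#' @param seed optional integer seed (determinism contract: equal seeds give
#'   identical chi vectors).
#' @param factors optional nIni x nStates matrix of pre-drawn perturbation
#'   factors for paired designs (overrides the seed-driven draw).
#' @param reltol,abstol,tcap integrator settings.
#' @return a \linkS4class{ResponseEnsemble}.
#' @export
responseDistribution <- function(model, xSt, nIni = 128L, strength = 0.4,
                                 seed = NULL, factors = NULL,
                                 reltol = 1e-7, abstol = 1e-12,
                                 tcap = 1e10) {
    if (is(xSt, "SteadyState")) xSt <- steadyConc(xSt)
    xSt <- unname(xSt)
    P <- conservedPools(model)
    clamped <- if (is(model, "MassActionModel")) model@clamped else integer(0)
    if (is.null(factors)) {
        factors <- withSeed(seed,
            matrix(stats::runif(nIni * length(xSt), 1 - strength,
                                1 + strength), nIni, length(xSt)))
    }
    chisv <- rep(NA_real_, nIni)
    fails <- 0L
    for (k in seq_len(nIni)) {
        fk <- factors[k, ]
        if (length(clamped)) fk[clamped] <- 1   # clamped coordinates stay put
        x0 <- perturbState(xSt, strength = strength, pools = P, factors = fk)
        res <- .chiTrajectory(model, x0, xSt, reltol = reltol,
                              abstol = abstol, tcap = tcap)
        if (res$ok) chisv[k] <- res$chi else fails <- fails + 1L
    }
    if (fails > nIni / 2)
        stop("more than half of the response trajectories failed; ",
             "the model is unsuitable for response statistics")
    new("ResponseEnsemble",
        chis = chisv[!is.na(chisv)],
        nFailed = fails,
        settings = list(strength = strength, nIni = nIni, seed = seed))
}

#' Response ensemble of the linearized dynamics, with shared perturbations
#'
#' Propagates the same perturbations as \code{\link{responseDistribution}}
#' (shared seed => identical initial displacement vectors) under the
#' linearized dynamics d(delta)/dt = J delta around the attractor, enabling
#' a paired nonlinear-versus-linear comparison of chi.  The linear state
#' x_st + delta(t) is floored at a tiny positive value before taking logs.
#'
#' @inheritParams responseDistribution
#' @return a \linkS4class{ResponseEnsemble}.
#' @export
linearizedResponseDistribution <- function(model, xSt, nIni = 128L,
                                           strength = 0.4, seed = NULL,
                                           factors = NULL, tcap = 1e6) {
    if (is(xSt, "SteadyState")) xSt <- steadyConc(xSt)
    xSt <- unname(xSt)
    P <- conservedPools(model)
    lin <- linearizeModel(model, xSt)
    if (is.null(factors)) {
        factors <- withSeed(seed,
            matrix(stats::runif(nIni * length(xSt), 1 - strength,
                                1 + strength), nIni, length(xSt)))
    }
    times <- logTimes(tcap, 512L)
    chisv <- rep(NA_real_, nIni)
    fails <- 0L
    for (k in seq_len(nIni)) {
        x0 <- perturbState(xSt, strength = strength, pools = P,
                           factors = factors[k, ])
        delta <- lin$simulate(x0 - xSt, times)
        if (any(!is.finite(delta))) { fails <- fails + 1L; next }
        xs <- pmax(as.numeric(xSt) + delta, 1e-300)
        dev <- log(xs) - log(as.numeric(xSt))
        dim(dev) <- dim(delta)
        norms <- sqrt(colSums(dev^2))
        if (norms[1] == 0) { fails <- fails + 1L; next }
        chisv[k] <- max(norms) / norms[1]
    }
    if (fails > nIni / 2)
        stop("more than half of the linearized trajectories failed")
    new("ResponseEnsemble",
        chis = chisv[!is.na(chisv)],
        nFailed = fails,
        settings = list(strength = strength, nIni = nIni, seed = seed,
                        linearized = TRUE))
}
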