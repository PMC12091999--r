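#' @include AllClasses.R AllGenerics.R model-methods.R
NULL

## ---- low-level compiled integration -------------------------------------

## One lsoda/lsodar call against the compiled mass-action core.
## rootmode: 0 plain, 1 log-distance stop, 2 derivative-residual stop, 3 both.
.odeRun <- function(model, x0, times, rootmode = 0L, xst = NULL,
                    disttol = 0, epsabs = 0, epsrel = 0,
                    reltol = 1e-7, abstol = 1e-12) {
    parms <- packModel(model, rootmode = rootmode, xst = xst,
                       disttol = disttol, epsabs = epsabs, epsrel = epsrel)
    out <- tryCatch(suppressWarnings({
        if (rootmode == 0L)
            deSolve::lsoda(y = x0, times = times, func = "kr_derivs",
                           parms = parms, rtol = reltol, atol = abstol,
                           jacfunc = "kr_jac", jactype = "fullusr",
                           dllname = "kinresponse", initfunc = "kr_init")
        else
            deSolve::lsodar(y = x0, times = times, func = "kr_derivs",
                            parms = parms, rtol = reltol, atol = abstol,
                            jacfunc = "kr_jac", jactype = "fullusr",
                            rootfunc = "kr_root", nroot = 1L,
                            dllname = "kinresponse", initfunc = "kr_init")
    }), error = function(e) e)
    if (inherits(out, "condition"))
        return(list(ok = FALSE, reason = conditionMessage(out)))
    istate <- attributes(out)$istate[1]
    if (is.na(istate) || istate < 0)
        return(list(ok = FALSE,
                    reason = paste0("solver failure (istate ", istate, ")")))
    m <- unclass(out)
    states <- t(m[, -1, drop = FALSE])
    tt <- m[, 1]
    if (any(!is.finite(states)))
        return(list(ok = FALSE, reason = "non-finite state"))
    if (min(states) < -1e3 * abstol)
        return(list(ok = FALSE, reason = "positivity violation"))
    states[states < abstol * 1e-3] <- abstol * 1e-3
    troot <- attributes(out)$troot
    list(ok = TRUE, times = tt, states = states,
         rootHit = rootmode > 0L &&
             (length(troot) > 0 || max(tt) < max(times) - 1e-300),
         istate = istate)
}

#' Default initial state of a model
#'
#' Unit concentrations for every species; when a cofactor pool is present its
#' three forms share the conserved total equally (total/3 each) so the pool
#' constraint is satisfied from the start.
#'
#' @param model a \linkS4class{KineticModel}.
#' @return a positive concentration vector.
#' @export
defaultInitialState <- function(model) {
    n <- nStates(model)
    x0 <- rep(1, n)
    if (is(model, "MassActionModel")) {
        net <- model@network
        if (length(net@cofactor) > 0L)
            x0[net@nSpecies + 1:3] <- net@cofactor$total / 3
        if (length(model@clamped))
            x0[model@clamped] <- model@clampValues
    }
    names(x0) <- speciesNames(model)
    x0
}

#' Integrate a kinetic model over a dense log-spaced time grid
#'
#' Adaptive stiff integration (lsoda with the analytic Jacobian) over a grid
#' of \code{npts} log-spaced output times, dense enough that the peak of the
#' log-space excursion is resolved.  Integration failures (step-size
#' collapse, non-finite or negative states) are reported in the returned
#' object, never silently dropped.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param x0 positive initial concentrations.
#' @param horizon final time.
#' @param reltol,abstol solver tolerances.
#' @param npts number of output points (default 512).
#' @return a \linkS4class{Trajectory}.
#' @export
#' @examples
#' m <- generateMinimalModel(8, 10, f = 0.5, seed = 3)
#' tr <- integrateModel(m, defaultInitialState(m), horizon = 100)
integrateModel <- function(model, x0, horizon, reltol = 1e-7,
                           abstol = 1e-12, npts = 512L) {
    stopifnot(all(x0 > 0), horizon > 0)
    run <- .odeRun(model, unname(x0), logTimes(horizon, npts),
                   reltol = reltol, abstol = abstol)
    if (!run$ok)
        return(new("Trajectory", times = 0, states = cbind(unname(x0)),
                   converged = FALSE, failureReason = run$reason))
    rownames(run$states) <- speciesNames(model)
    new("Trajectory", times = run$times, states = run$states,
        converged = TRUE, failureReason = "")
}

## Relax toward a steady state: integrate with the derivative-residual root
## until max|dx/dt| < epsabs + epsrel * max|J_r|, up to a hard time cap.
.relaxToSteady <- function(model, x0, tcap = 1e10, npts = 400L,
                           epsabs = 1e-12, epsrel = 1e-9,
                           reltol = 1e-7, abstol = 1e-12) {
    run <- .odeRun(model, unname(x0), logTimes(tcap, npts),
                   rootmode = 2L, epsabs = epsabs, epsrel = epsrel,
                   reltol = reltol, abstol = abstol)
    if (!run$ok)
        return(list(ok = FALSE, reason = run$reason))
    xEnd <- run$states[, ncol(run$states)]
    list(ok = TRUE, x = xEnd, rootHit = isTRUE(run$rootHit),
         times = run$times, states = run$states)
}

## Newton polish of the steady-state residual with conserved pools (and
## clamped coordinates) held fixed; damped to stay in the positive orthant.
.polishSteady <- function(model, x, maxit = 60L, tol = NULL) {
    n <- length(x)
    clamped <- if (is(model, "MassActionModel")) model@clamped else integer(0)
    free <- setdiff(seq_len(n), clamped)
    P <- conservedPools(model)
    target <- if (nrow(P)) as.numeric(P %*% x) else numeric(0)
    for (it in seq_len(maxit)) {
        f <- modelRHS(model, x)
        flux <- modelFluxes(model, x)
        scale <- max(1e-300, max(abs(flux), 0))
        if (is.null(tol)) tolc <- 1e-13 * max(1, scale) else tolc <- tol
        if (max(abs(f[free])) < tolc) break
        J <- modelJacobian(model, x)
        A <- J[free, free, drop = FALSE]
        b <- -f[free]
        if (nrow(P)) {
            Pf <- P[, free, drop = FALSE]
            A <- rbind(A, Pf)
            b <- c(b, target - as.numeric(P %*% x))
        }
        step <- tryCatch(qr.solve(A, b), error = function(e) NULL)
        if (is.null(step)) {
            ## ultra-slow modes can make the Jacobian numerically rank
            ## deficient beyond the pool zero modes; fall back to the
            ## SVD pseudoinverse
            sv <- svd(A)
            keep <- sv$d > 1e-13 * sv$d[1]
            step <- sv$v[, keep, drop = FALSE] %*%
                ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
            step <- as.numeric(step)
        }
        lam <- 1
        while (any(x[free] + lam * step <= 0) && lam > 1e-8)
            lam <- lam / 2
        if (lam <= 1e-8) break
        xNew <- x
        xNew[free] <- x[free] + lam * step
        if (max(abs(modelRHS(model, xNew)[free])) >= max(abs(f[free])))
            break                      # at the evaluation noise floor
        x <- xNew
    }
    x
}

## Stability spectrum at a steady state: eigenvalues of the Jacobian on the
## free (unclamped) coordinates, with one zero mode removed per conserved
## pool before taking the leading real part.
.stabilityAt <- function(model, x) {
    n <- length(x)
    clamped <- if (is(model, "MassActionModel")) model@clamped else integer(0)
    free <- setdiff(seq_len(n), clamped)
    J <- modelJacobian(model, x)[free, free, drop = FALSE]
    ev <- eigen(J, only.values = TRUE)$values
    scale <- max(abs(ev), 1e-300)
    P <- conservedPools(model)
    npool <- if (nrow(P)) qr(P[, free, drop = FALSE])$rank else 0L
    if (npool > 0L) {
        ord <- order(abs(ev))
        ev <- ev[ord][-seq_len(npool)]
    }
    if (!length(ev)) return(-Inf)
    structure(max(Re(ev)), eigScale = scale)
}

## Stability decision with the spectral resolution of eigen() in mind:
## eigenvalues of a stiff Jacobian carry an absolute error of order
## 1e-15 * spectral radius, so a real part below that resolution cannot be
## distinguished from zero and is treated as marginal (stable).
.isStable <- function(maxRe, tol = 1e-9) {
    sc <- attr(maxRe, "eigScale")
    if (is.null(sc)) sc <- 1
    as.numeric(maxRe) <= tol * sc
}

#' Find and certify a steady-state attractor
#'
#' Integrates from each supplied initial state until the residual criterion
#' max|dx/dt| < epsabs + epsrel * max|J_r| is met (or a hard time cap of
#' 1e10 is reached), then refines the endpoint by a damped Newton iteration
#' that holds the conserved-pool totals of the initial state fixed, and
#' certifies stability from the Jacobian spectrum (conserved-pool zero modes
#' removed).  With several initial states, all must relax to the same point
#' (within a max log-distance of \code{clusterTol}); otherwise an error asks
#' for \code{\link{screenMultistability}}.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param x0Set matrix of initial states (one per row), or NULL for the
#'   default initial state.
#' @param epsabs,epsrel residual convergence thresholds (absolute, and
#'   relative to the largest reaction flux).
#' @param reltol,abstol solver tolerances.
#' @param tcap hard cap on integration time.
#' @param clusterTol attractor identity tolerance in max log-distance.
#' @return a \linkS4class{SteadyState}.
#' @export
findAttractor <- function(model, x0Set = NULL, epsabs = 1e-12,
                          epsrel = 1e-9, reltol = 1e-7, abstol = 1e-12,
                          tcap = 1e10, clusterTol = 1e-4) {
    if (is.null(x0Set))
        x0Set <- rbind(defaultInitialState(model))
    if (!is.matrix(x0Set))
        x0Set <- rbind(x0Set)
    ends <- vector("list", nrow(x0Set))
    for (k in seq_len(nrow(x0Set))) {
        rl <- .relaxToSteady(model, x0Set[k, ], tcap = tcap,
                             epsabs = epsabs, epsrel = epsrel,
                             reltol = reltol, abstol = abstol)
        if (rl$ok)
            ends[[k]] <- .polishSteady(model, rl$x)
    }
    ends <- ends[!vapply(ends, is.null, logical(1))]
    if (!length(ends))
        stop("attractor not found: no initial state relaxed to steady state")
    if (length(ends) > 1L) {
        E <- do.call(rbind, ends)
        d <- apply(abs(sweep(log(E), 2, log(ends[[1]]))), 1, max)
        if (any(d > clusterTol))
            stop("initial states relaxed to distinct attractors; ",
                 "use screenMultistability()")
    }
    x <- ends[[1]]
    if (any(x <= 0))
        stop("polished steady state left the positive orthant")
    P <- conservedPools(model)
    res <- max(abs(modelRHS(model, x)))
    names(x) <- speciesNames(model)
    new("SteadyState", xSt = x,
        maxReEig = .stabilityAt(model, x),
        pools = P,
        poolValues = if (nrow(P)) as.numeric(P %*% x) else numeric(0),
        residual = res)
}

#' @describeIn conservedPools exact pools of a mass-action model: integer
#'   left-null vectors of the stoichiometry restricted to species without
#'   exchange and not clamped.
#' @export
setMethod("conservedPools", "MassActionModel", function(model) {
    net <- model@network
    n <- length(net@species)
    eligible <- which(!net@exchange)
    eligible <- setdiff(eligible, model@clamped)
    if (!length(eligible) || nrow(net@reactions) == 0L) {
        out <- matrix(0, 0, n)
        colnames(out) <- net@species
        return(out)
    }
    Ssub <- model@stoich[eligible, , drop = FALSE]
    B <- intLeftNull(Ssub)
    out <- matrix(0, nrow(B), n)
    if (nrow(B)) out[, eligible] <- B
    colnames(out) <- net@species
    out
})

#' @describeIn conservedPools the RCRN model has no conserved pools (growth
#'   dilution breaks every mass conservation; the total concentration relaxes
#'   to 1 instead of being conserved).
#' @export
setMethod("conservedPools", "RcrnModel", function(model) {
    matrix(0, 0, model@nSpecies)
})

#' Sample random initial concentrations
#'
#' Log-uniform concentrations in (10^-3, 10^3) per species, with conserved
#' pools rescaled to reference totals so that trajectories of a model with
#' pools stay comparable (the attractor of such a model depends on the pool
#' totals, which are set by the initial condition).
#'
#' @param model a \linkS4class{KineticModel}.
#' @param n number of initial states.
#' @param seed optional integer seed.
#' @param logRange range of log10 concentration (default c(-3, 3)).
#' @param poolReference state whose pool totals are imposed (default
#'   \code{defaultInitialState(model)}).
#' @return matrix with one initial state per row.
#' @export
sampleInitialStates <- function(model, n, seed = NULL, logRange = c(-3, 3),
                                poolReference = defaultInitialState(model)) {
    withSeed(seed, {
        ns <- nStates(model)
        X <- matrix(10^stats::runif(n * ns, logRange[1], logRange[2]), n, ns)
        P <- conservedPools(model)
        if (nrow(P)) {
            targets <- as.numeric(P %*% poolReference)
            for (p in seq_len(nrow(P))) {
                supp <- which(P[p, ] != 0)
                cur <- X[, supp, drop = FALSE] %*% P[p, supp]
                X[, supp] <- X[, supp, drop = FALSE] * (targets[p] / as.numeric(cur))
            }
        }
        if (is(model, "MassActionModel") && length(model@clamped))
            X[, model@clamped] <- rep(model@clampValues, each = n)
        X
    })
}

#' Screen a model for multistability
#'
#' Relaxes the model from \code{nInit} random initial states (log-uniform in
#' (10^-3, 10^3) by default, pool totals held at the reference values),
#' polishes each endpoint, and clusters the endpoints: two endpoints belong
#' to the same attractor when their max log-distance is below
#' \code{clusterTol}.  Failed integrations are reported separately.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param nInit number of initial states (>= 2).
#' @param sampler optional function(n) returning a matrix of initial states;
#'   defaults to \code{\link{sampleInitialStates}}.
#' @param seed optional integer seed.
#' @param clusterTol attractor identity tolerance in max log-distance.
#' @param tcap hard cap on integration time.
#' @param ... further arguments to the integrator.
#' @return list with elements \code{attractors} (matrix, one attractor per
#'   row), \code{assignment} (per-initial-state attractor index, NA if
#'   failed), \code{nFailed}, and \code{singleAttractor} (logical).
#' @export
screenMultistability <- function(model, nInit = 32L, sampler = NULL,
                                 seed = NULL, clusterTol = 1e-4,
                                 tcap = 1e10, ...) {
    stopifnot(nInit >= 2L)
    X <- if (is.null(sampler)) sampleInitialStates(model, nInit, seed = seed)
         else sampler(nInit)
    ends <- matrix(NA_real_, nInit, nStates(model))
    for (k in seq_len(nInit)) {
        rl <- .relaxToSteady(model, X[k, ], tcap = tcap, ...)
        if (rl$ok)
            ends[k, ] <- .polishSteady(model, rl$x)
    }
    okrow <- which(stats::complete.cases(ends) & apply(ends > 0, 1, all))
    if (!length(okrow))
        stop("multistability screening failed: no integration converged")
    attractors <- NULL
    assignment <- rep(NA_integer_, nInit)
    for (k in okrow) {
        y <- log(ends[k, ])
        hit <- NA_integer_
        if (!is.null(attractors)) {
            d <- apply(abs(sweep(log(attractors), 2, y)), 1, max)
            if (min(d) < clusterTol) hit <- which.min(d)
        }
        if (is.na(hit)) {
            attractors <- rbind(attractors, ends[k, ])
            hit <- nrow(attractors)
        }
        assignment[k] <- hit
    }
    list(attractors = attractors,
         assignment = assignment,
         nFailed = nInit - length(okrow),
         singleAttractor = nrow(attractors) == 1L)
}

#' Linearize a model at a steady state
#'
#' Returns the analytic Jacobian at \code{xSt} together with a simulator for
#' the linearized deviation dynamics d(delta)/dt = J delta, used for the
#' paired nonlinear-versus-linear response comparison.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param xSt steady-state concentrations (certified attractor).
#' @return list with \code{jacobian} and \code{simulate(delta0, times)}
#'   returning a deviation matrix (species x timepoints); a
#'   \code{illConditioned} flag is set when the Jacobian is numerically
#'   singular.
#' @export
linearizeModel <- function(model, xSt) {
    J <- modelJacobian(model, unname(xSt))
    ## singularity beyond the structural conserved-pool zero modes: compare
    ## the (n - npools)-th singular value against the spectral scale
    npool <- nrow(conservedPools(model))
    sv <- tryCatch(svd(J, nu = 0, nv = 0)$d, error = function(e) NA_real_)
    ill <- anyNA(sv) || !all(is.finite(J)) ||
        (length(sv) > npool && sv[length(sv) - npool] < 1e-13 * sv[1])
    sim <- function(delta0, times) {
        out <- deSolve::lsoda(y = unname(delta0), times = times,
                              func = function(t, y, p) list(as.numeric(J %*% y)),
                              parms = NULL, rtol = 1e-9, atol = 1e-14)
        t(unclass(out)[, -1, drop = FALSE])
    }
    list(jacobian = J, simulate = sim, illConditioned = ill)
}
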