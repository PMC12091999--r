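#' @include AllClasses.R AllGenerics.R minimal_model.R
NULL

## ---- reference (R-level) evaluators -------------------------------------

.maFluxes <- function(model, x) {
    rx <- model@network@reactions
    if (nrow(rx) == 0L) return(numeric(0))
    s2 <- ifelse(is.na(rx$sub2), 1, x[ifelse(is.na(rx$sub2), 1L, rx$sub2)])
    p2 <- ifelse(is.na(rx$prd2), 1, x[ifelse(is.na(rx$prd2), 1L, rx$prd2)])
    xs <- x[rx$sub1] * s2
    xp <- x[rx$prd1] * p2
    rx$vr * (rx$kplus * xs - rx$kminus * xp)
}

#' @describeIn modelFluxes mass-action fluxes
#' @export
setMethod("modelFluxes", "MassActionModel", function(model, x) {
    .maFluxes(model, x)
})

#' @describeIn modelRHS mass-action model with linear exchange
#' @export
setMethod("modelRHS", "MassActionModel", function(model, x) {
    net <- model@network
    J <- .maFluxes(model, x)
    dx <- as.numeric(model@stoich %*% J)
    D <- as.numeric(net@exchange)
    dx <- dx + D * (net@externalConc - x)
    dx[model@clamped] <- 0
    dx
})

#' @describeIn modelJacobian analytic mass-action Jacobian
#' @export
setMethod("modelJacobian", "MassActionModel", function(model, x) {
    net <- model@network
    rx <- net@reactions
    n <- length(x)
    Jm <- matrix(0, n, n)
    for (r in seq_len(nrow(rx))) {
        s1 <- rx$sub1[r]; s2 <- rx$sub2[r]
        p1 <- rx$prd1[r]; p2 <- rx$prd2[r]
        a <- rx$vr[r] * rx$kplus[r]
        b <- rx$vr[r] * rx$kminus[r]
        var <- c(s1, if (!is.na(s2)) s2, p1, if (!is.na(p2)) p2)
        coef <- c(a * (if (!is.na(s2)) x[s2] else 1),
                  if (!is.na(s2)) a * x[s1],
                  -b * (if (!is.na(p2)) x[p2] else 1),
                  if (!is.na(p2)) -b * x[p1])
        Srow <- model@stoich[, r]
        for (q in seq_along(var))
            Jm[, var[q]] <- Jm[, var[q]] + Srow * coef[q]
    }
    D <- as.numeric(net@exchange)
    diag(Jm) <- diag(Jm) - D
    Jm[model@clamped, ] <- 0
    Jm
})

.rcrnMu <- function(model, x) {
    sum(model@uptake * x[model@transporter] * model@externalConc)
}

#' @describeIn modelFluxes RCRN per-edge net fluxes x_k (vf x_j - vb x_i)
#' @export
setMethod("modelFluxes", "RcrnModel", function(model, x) {
    e <- model@edges
    x[e$cat] * (e$vf * x[e$j] - e$vb * x[e$i])
})

#' @describeIn modelRHS RCRN model with uptake and growth dilution
#' @export
setMethod("modelRHS", "RcrnModel", function(model, x) {
    e <- model@edges
    J <- modelFluxes(model, x)
    dx <- numeric(model@nSpecies)
    for (r in seq_len(nrow(e))) {
        dx[e$i[r]] <- dx[e$i[r]] + J[r]
        dx[e$j[r]] <- dx[e$j[r]] - J[r]
    }
    up <- model@uptake * x[model@transporter] * model@externalConc
    mu <- sum(up)
    dx + up - mu * x
})

#' @describeIn modelJacobian analytic RCRN Jacobian
#' @export
setMethod("modelJacobian", "RcrnModel", function(model, x) {
    n <- model@nSpecies
    e <- model@edges
    Jm <- matrix(0, n, n)
    for (r in seq_len(nrow(e))) {
        i <- e$i[r]; j <- e$j[r]; k <- e$cat[r]
        dJ <- numeric(n)
        dJ[j] <- dJ[j] + x[k] * e$vf[r]
        dJ[i] <- dJ[i] - x[k] * e$vb[r]
        dJ[k] <- dJ[k] + (e$vf[r] * x[j] - e$vb[r] * x[i])
        Jm[i, ] <- Jm[i, ] + dJ
        Jm[j, ] <- Jm[j, ] - dJ
    }
    mu <- .rcrnMu(model, x)
    dmu <- numeric(n)
    sel <- which(model@uptake != 0)
    for (i in sel) {
        Jm[i, model@transporter[i]] <- Jm[i, model@transporter[i]] +
            model@uptake[i] * model@externalConc[i]
        dmu[model@transporter[i]] <- dmu[model@transporter[i]] +
            model@uptake[i] * model@externalConc[i]
    }
    Jm - outer(x, dmu) - diag(mu, n)
})

## ---- packing for the compiled core --------------------------------------

## Serializes a model into the double vector consumed by src/massaction.c.
## rootmode: 0 none, 1 log-distance stop (needs xst/disttol), 2 residual stop,
## 3 both.
packModel <- function(model, rootmode = 0L, xst = NULL, disttol = 0,
                      epsabs = 0, epsrel = 0) {
    if (is(model, "MassActionModel")) {
        net <- model@network
        rx <- net@reactions
        n <- length(net@species)
        R <- nrow(rx)
        mode <- 0
        D <- as.numeric(net@exchange)
        X <- net@externalConc
        Tv <- rep(0, n)
        sub1 <- rx$sub1; sub2 <- rx$sub2
        prd1 <- rx$prd1; prd2 <- rx$prd2
        a <- rx$vr * rx$kplus
        b <- rx$vr * rx$kminus
    } else if (is(model, "RcrnModel")) {
        e <- model@edges
        n <- model@nSpecies
        R <- nrow(e)
        mode <- 1
        D <- model@uptake
        X <- model@externalConc
        Tv <- as.numeric(model@transporter)
        sub1 <- e$j; sub2 <- e$cat
        prd1 <- e$i; prd2 <- e$cat
        a <- e$vf; b <- e$vb
    } else stop("unsupported model class")
    clamp <- rep(0, n)
    if (is(model, "MassActionModel") && length(model@clamped))
        clamp[model@clamped] <- 1
    if (is.null(xst)) xst <- rep(1, n)
    z <- function(v) ifelse(is.na(v), 0, as.numeric(v))
    p <- c(0, mode, n, R,
           as.numeric(rootmode),
           z(sub1), z(sub2), z(prd1), z(prd2), z(a), z(b),
           D, X, Tv, clamp, xst,
           disttol, epsabs, epsrel)
    p[1] <- length(p)
    p
}

## ---- accessors and show methods -----------------------------------------

#' @describeIn nStates network state dimension
#' @export
setMethod("nStates", "ReactionNetwork", function(object) length(object@species))

#' @describeIn nStates model state dimension
#' @export
setMethod("nStates", "MassActionModel",
          function(object) length(object@network@species))

#' @describeIn nStates RCRN state dimension
#' @export
setMethod("nStates", "RcrnModel", function(object) object@nSpecies)

#' @describeIn speciesNames network species names
#' @export
setMethod("speciesNames", "ReactionNetwork", function(object) object@species)

#' @describeIn speciesNames model species names
#' @export
setMethod("speciesNames", "MassActionModel",
          function(object) object@network@species)

#' @describeIn speciesNames RCRN species names
#' @export
setMethod("speciesNames", "RcrnModel",
          function(object) paste0("C", seq_len(object@nSpecies)))

#' @describeIn reactions network reaction table
#' @export
setMethod("reactions", "ReactionNetwork", function(object) object@reactions)

#' @describeIn reactions model reaction table
#' @export
setMethod("reactions", "MassActionModel",
          function(object) object@network@reactions)

#' @describeIn reactions RCRN edge table
#' @export
setMethod("reactions", "RcrnModel", function(object) object@edges)

#' @describeIn chis ensemble chi values
#' @export
setMethod("chis", "ResponseEnsemble", function(object) object@chis)

#' @describeIn meanChi arithmetic mean of the chi values
#' @export
setMethod("meanChi", "ResponseEnsemble",
          function(object) mean(object@chis))

#' @describeIn nFailed excluded trajectory count
#' @export
setMethod("nFailed", "ResponseEnsemble", function(object) object@nFailed)

#' @describeIn timeGrid trajectory time grid
#' @export
setMethod("timeGrid", "Trajectory", function(object) object@times)

#' @describeIn concMatrix trajectory concentrations
#' @export
setMethod("concMatrix", "Trajectory", function(object) object@states)

#' @describeIn isConverged convergence flag
#' @export
setMethod("isConverged", "Trajectory", function(object) object@converged)

#' @describeIn steadyConc steady-state concentrations
#' @export
setMethod("steadyConc", "SteadyState", function(object) object@xSt)

#' @describeIn maxReEig stability margin
#' @export
setMethod("maxReEig", "SteadyState", function(object) object@maxReEig)

setMethod("show", "ReactionNetwork", function(object) {
    cat("ReactionNetwork:", object@nSpecies, "backbone species,",
        nrow(object@reactions), "reactions",
        if (length(object@cofactor)) "(+ 3-form cofactor)" else "", "\n")
    cat("  coupled reactions:", sum(object@reactions$coupled),
        "| exchanged species:", sum(object@exchange), "\n")
    cat("  parameterized:",
        !anyNA(object@reactions$vr) && !anyNA(object@reactions$kplus), "\n")
})

setMethod("show", "MassActionModel", function(object) {
    net <- object@network
    cat("MassActionModel (", net@variant, "): ", length(net@species),
        " states, ", nrow(net@reactions), " reactions, beta = ",
        object@beta, "\n", sep = "")
    if (length(object@clamped))
        cat("  clamped:",
            paste(net@species[object@clamped], collapse = ", "), "\n")
})

setMethod("show", "RcrnModel", function(object) {
    cat("RcrnModel:", object@nSpecies, "metabolites,",
        nrow(object@edges), "catalysed reversible reactions\n")
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory:", nrow(object@states), "species x",
        length(object@times), "timepoints; converged:",
        object@converged,
        if (nzchar(object@failureReason))
            paste0("(", object@failureReason, ")") else "", "\n")
})

setMethod("show", "SteadyState", function(object) {
    cat("SteadyState: residual", format(object@residual, digits = 3),
        "| max Re(eig)", format(object@maxReEig, digits = 4),
        "|", nrow(object@pools), "conserved pool(s)\n")
})

setMethod("show", "ResponseEnsemble", function(object) {
    cat("ResponseEnsemble:", length(object@chis), "trajectories,",
        object@nFailed, "failed; mean chi =",
        format(mean(object@chis), digits = 5), "\n")
})
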