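#' @import methods
NULL

## Cofactor triple used throughout: three interconverting forms of one carrier
## (modeling ATP/ADP/AMP), with fixed standard chemical potentials and a
## conserved total concentration.
.defaultCofactor <- function() {
    list(forms = c("A**", "A*", "A"),
         potentials = c(1.0, 0.5, 0.0),
         total = 1.0)
}

.validCofactor <- function(cof) {
    if (length(cof) == 0L) return(TRUE)
    if (!all(c("forms", "potentials", "total") %in% names(cof)))
        return("cofactor must have elements 'forms', 'potentials', 'total'")
    if (length(cof$forms) != 3L || length(cof$potentials) != 3L)
        return("cofactor must have exactly 3 forms")
    if (any(diff(cof$potentials) >= 0))
        return("cofactor potentials must be strictly decreasing")
    if (!is.numeric(cof$total) || cof$total <= 0)
        return("cofactor total must be > 0")
    TRUE
}

#' ReactionNetwork: a random metabolic reaction network
#'
#' Holds the backbone network of \code{nSpecies} chemicals, its reactions
#' (with up to two substrates and two products each, stored as multisets of
#' state-vector indices), exchange flags and external concentrations, and an
#' optional 3-form cofactor (modeling the adenylate pool).  The state vector
#' stacks the backbone species first and, when a cofactor is present, the
#' three cofactor forms at positions \code{nSpecies + 1:3}.
#'
#' The \code{reactions} data frame has columns \code{sub1}, \code{sub2},
#' \code{prd1}, \code{prd2} (integer indices, \code{NA} for an absent slot),
#' \code{vr} (rate constant), \code{kplus}, \code{kminus} (irreversibility
#' factors in [0,1]), \code{deltaMu} (standard chemical potential difference,
#' products minus substrates) and \code{coupled} (logical, cofactor-coupled).
#' Parameter columns are \code{NA} until assigned.
#'
#' @slot nSpecies integer, number of backbone chemicals.
#' @slot species character, names of all state variables.
#' @slot reactions data.frame, see Details.
#' @slot exchange logical, per-state-variable exchange flag (D_n).
#' @slot externalConc numeric, per-state-variable external concentration (X_n).
#' @slot cofactor list, either empty or with elements \code{forms},
#'   \code{potentials}, \code{total}.
#' @slot mu numeric, standard chemical potentials of all state variables
#'   (NA before thermodynamic assignment).
#' @slot beta numeric, inverse temperature used for the k+- assignment
#'   (NA before assignment).
#' @slot variant character, \code{"cofactor"}, \code{"catalytic"} or
#'   \code{"custom"}.
#' @exportClass ReactionNetwork
setClass("ReactionNetwork",
    representation(
        nSpecies = "integer",
        species = "character",
        reactions = "data.frame",
        exchange = "logical",
        externalConc = "numeric",
        cofactor = "list",
        mu = "numeric",
        beta = "numeric",
        variant = "character"
    ))

setValidity("ReactionNetwork", function(object) {
    n <- object@nSpecies
    ntot <- length(object@species)
    rx <- object@reactions
    msgs <- character()
    ok <- .validCofactor(object@cofactor)
    if (!isTRUE(ok)) msgs <- c(msgs, ok)
    hasCof <- length(object@cofactor) > 0L
    if (ntot != n + if (hasCof) 3L else 0L)
        msgs <- c(msgs, "species length must be nSpecies (+3 with cofactor)")
    if (length(object@exchange) != ntot || length(object@externalConc) != ntot)
        msgs <- c(msgs, "exchange/externalConc must match state dimension")
    need <- c("sub1", "sub2", "prd1", "prd2", "vr", "kplus", "kminus",
              "deltaMu", "coupled")
    if (!all(need %in% names(rx)))
        msgs <- c(msgs, "reactions is missing required columns")
    if (nrow(rx) > 0 && all(need %in% names(rx))) {
        idx <- c(rx$sub1, rx$sub2, rx$prd1, rx$prd2)
        idx <- idx[!is.na(idx)]
        if (length(idx) && (min(idx) < 1L || max(idx) > ntot))
            msgs <- c(msgs, "reaction species indices out of range")
        uni <- is.na(rx$sub2) & is.na(rx$prd2)
        if (any(uni & rx$sub1 == rx$prd1))
            msgs <- c(msgs, "self-loop uni-uni reaction C_n <-> C_n")
        if (hasCof && any(!rx$coupled &
                (rx$sub1 > n | rx$prd1 > n), na.rm = TRUE))
            msgs <- c(msgs, "cofactors may not appear as backbone reactants")
        par <- !is.na(rx$kplus) & !is.na(rx$kminus)
        if (any(par & (rx$kplus < 0 | rx$kplus > 1 |
                       rx$kminus < 0 | rx$kminus > 1)))
            msgs <- c(msgs, "k+/k- must lie in [0, 1]")
        if (any(par & abs(pmax(rx$kplus, rx$kminus) - 1) > 1e-12))
            msgs <- c(msgs, "max(k+, k-) must equal 1")
        ## detailed balance, checked where deltaMu is finite and both k > 0
        db <- par & is.finite(rx$deltaMu) & !is.na(object@beta) &
            rx$kplus > 0 & rx$kminus > 0
        if (any(db)) {
            lr <- log(rx$kplus[db]) - log(rx$kminus[db])
            if (any(abs(lr + object@beta * rx$deltaMu[db]) >
                    1e-8 * pmax(1, abs(object@beta * rx$deltaMu[db]))))
                msgs <- c(msgs, "k+/k- violates detailed balance exp(-beta dMu)")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' KineticModel: virtual parent of simulatable kinetic models
#'
#' @exportClass KineticModel
setClass("KineticModel", representation("VIRTUAL"))

#' MassActionModel: a fully parameterized mass-action kinetic model
#'
#' dx_n/dt = sum_r S_nr J_r(x) + D_n (X_n - x_n), with mass-action flux
#' J_r = v_r (k_r^+ prod_{n in Sub(r)} x_n - k_r^- prod_{n in Prd(r)} x_n).
#'
#' @slot network a \linkS4class{ReactionNetwork}, fully parameterized.
#' @slot stoich integer stoichiometric matrix, species x reactions.
#' @slot beta numeric inverse temperature.
#' @slot clamped integer indices of clamped (frozen) state variables.
#' @slot clampValues numeric frozen concentrations, parallel to \code{clamped}.
#' @exportClass MassActionModel
setClass("MassActionModel", contains = "KineticModel",
    representation(
        network = "ReactionNetwork",
        stoich = "matrix",
        beta = "numeric",
        clamped = "integer",
        clampValues = "numeric"
    ))

setValidity("MassActionModel", function(object) {
    net <- object@network
    rx <- net@reactions
    msgs <- character()
    if (nrow(rx) > 0 && any(is.na(rx$vr) | is.na(rx$kplus) | is.na(rx$kminus)))
        msgs <- c(msgs, "all reactions must be parameterized (vr, k+, k-)")
    ntot <- length(net@species)
    if (!all(dim(object@stoich) == c(ntot, nrow(rx))))
        msgs <- c(msgs, "stoichiometry must be species x reactions")
    if (length(object@clamped) != length(object@clampValues))
        msgs <- c(msgs, "clamped and clampValues must be parallel")
    if (nrow(rx) > 0) {
        ## column sums track the molecularity change (0 for the generated
        ## uni-uni / bi-bi reactions; +-1 for elementary binding steps)
        ns <- 1L + !is.na(rx$sub2)
        np <- 1L + !is.na(rx$prd2)
        if (any(colSums(object@stoich) != np - ns))
            msgs <- c(msgs, "stoichiometry columns disagree with the reaction table")
        if (length(net@cofactor) > 0L) {
            cofRows <- object@stoich[net@nSpecies + 1:3, , drop = FALSE]
            cp <- rx$coupled
            bad <- vapply(seq_len(ncol(cofRows)), function(j) {
                v <- cofRows[, j]
                if (cp[j]) !(sum(v == 1) == 1 && sum(v == -1) == 1 &&
                             sum(v == 0) == 1) else any(v != 0)
            }, logical(1))
            if (any(bad))
                msgs <- c(msgs, "coupled reactions must interconvert exactly one cofactor pair")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' RcrnModel: random catalytic reaction network toy cell
#'
#' dx_i/dt = sum_{j,k} x_k (v_ijk x_j - v_jik x_i) + D_i x_T(i) X_i - mu x_i
#' with growth rate mu = sum_i D_i x_T(i) X_i.  Every metabolite doubles as a
#' catalyst; one catalyst is assigned to each reaction edge.
#'
#' @slot nSpecies integer, number of metabolites.
#' @slot edges data.frame with columns \code{i}, \code{j} (reactant pair),
#'   \code{cat} (catalyst index), \code{vf} (rate j -> i), \code{vb}
#'   (rate i -> j).
#' @slot uptake numeric, D_i per species (1 for the nutrient, else 0).
#' @slot externalConc numeric, X_i per species.
#' @slot transporter integer, T(i) per species.
#' @exportClass RcrnModel
setClass("RcrnModel", contains = "KineticModel",
    representation(
        nSpecies = "integer",
        edges = "data.frame",
        uptake = "numeric",
        externalConc = "numeric",
        transporter = "integer"
    ))

setValidity("RcrnModel", function(object) {
    n <- object@nSpecies
    e <- object@edges
    msgs <- character()
    if (!all(c("i", "j", "cat", "vf", "vb") %in% names(e)))
        msgs <- c(msgs, "edges needs columns i, j, cat, vf, vb")
    else {
        if (nrow(e) && (min(c(e$i, e$j, e$cat)) < 1 || max(c(e$i, e$j, e$cat)) > n))
            msgs <- c(msgs, "edge indices out of range")
        if (nrow(e) && any(e$i == e$j))
            msgs <- c(msgs, "self-edges are not allowed")
        if (nrow(e) && any(e$vf <= 0 | e$vb <= 0))
            msgs <- c(msgs, "rate constants must be positive (reversibility)")
    }
    if (length(object@uptake) != n || length(object@externalConc) != n ||
        length(object@transporter) != n)
        msgs <- c(msgs, "uptake/externalConc/transporter must have length nSpecies")
    if (length(msgs)) msgs else TRUE
})

#' Trajectory: one ODE integration
#'
#' @slot times numeric, strictly increasing time grid (first element 0).
#' @slot states numeric matrix, species x timepoints.
#' @slot converged logical, TRUE if the stopping criterion was met.
#' @slot failureReason character, empty string if none.
#' @exportClass Trajectory
setClass("Trajectory",
    representation(
        times = "numeric",
        states = "matrix",
        converged = "logical",
        failureReason = "character"
    ))

setValidity("Trajectory", function(object) {
    msgs <- character()
    if (length(object@times) != ncol(object@states))
        msgs <- c(msgs, "times must match state columns")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
        msgs <- c(msgs, "times must be strictly increasing")
    if (length(msgs)) msgs else TRUE
})

#' SteadyState: a certified attractor
#'
#' @slot xSt numeric steady-state concentrations.
#' @slot maxReEig numeric, largest real part of the Jacobian spectrum after
#'   removing conserved-pool zero modes.
#' @slot pools numeric matrix of conserved-pool vectors (pools x species).
#' @slot poolValues numeric conserved totals at \code{xSt}.
#' @slot residual numeric, max-norm of dx/dt at \code{xSt}.
#' @exportClass SteadyState
setClass("SteadyState",
    representation(
        xSt = "numeric",
        maxReEig = "numeric",
        pools = "matrix",
        poolValues = "numeric",
        residual = "numeric"
    ))

#' ResponseEnsemble: chi values for one model
#'
#' @slot chis numeric per-trajectory response coefficients (each >= 1).
#' @slot nFailed integer count of excluded (failed) trajectories.
#' @slot settings list with at least \code{strength}, \code{nIni}, \code{seed}.
#' @exportClass ResponseEnsemble
setClass("ResponseEnsemble",
    representation(
        chis = "numeric",
        nFailed = "integer",
        settings = "list"
    ))

setValidity("ResponseEnsemble", function(object) {
    if (length(object@chis) && any(object@chis < 1 - 1e-12))
        "every response coefficient must be >= 1" else TRUE
})
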