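#' @include AllClasses.R
NULL

#' Evaluate the right-hand side dx/dt of a kinetic model
#'
#' Reference (R-level) evaluation of the model ODE at a state vector.  The
#' compiled evaluator used by the integrator is cross-checked against this.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param x positive concentration vector.
#' @return numeric vector dx/dt.
#' @export
setGeneric("modelRHS", function(model, x) standardGeneric("modelRHS"))

#' Per-reaction fluxes J_r(x) of a kinetic model
#'
#' @param model a \linkS4class{KineticModel}.
#' @param x positive concentration vector.
#' @return numeric vector of reaction fluxes.
#' @export
setGeneric("modelFluxes", function(model, x) standardGeneric("modelFluxes"))

#' Analytic Jacobian of the model RHS
#'
#' @param model a \linkS4class{KineticModel}.
#' @param x concentration vector at which to evaluate.
#' @return numeric matrix d(dx/dt)/dx.
#' @export
setGeneric("modelJacobian", function(model, x) standardGeneric("modelJacobian"))

#' Number of state variables of a model or network
#'
#' @param object a network or model.
#' @return integer.
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))

#' Species (state variable) names
#'
#' @param object a network or model.
#' @return character vector.
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' Reaction table of a network or model
#'
#' @param object a network or model.
#' @return data.frame of reactions.
#' @export
setGeneric("reactions", function(object) standardGeneric("reactions"))

#' Conserved pools (left null space of the effective stoichiometry)
#'
#' Returns an exact integer basis of left null vectors of the stoichiometric
#' matrix restricted to species without exchange terms (and not clamped);
#' each returned vector y satisfies t(y) %*% S = 0 exactly and is supported
#' only on conserved species.
#'
#' @param model a \linkS4class{KineticModel}.
#' @return numeric matrix, one pool vector per row (0 rows if none).
#' @export
setGeneric("conservedPools", function(model) standardGeneric("conservedPools"))

#' Freeze one species at a fixed concentration
#'
#' Returns a model in which the chosen species has identically zero dynamics
#' and its concentration is frozen at the supplied value (by default, meant to
#' be the steady-state value); all fluxes still read the frozen value.
#'
#' @param model a \linkS4class{KineticModel}.
#' @param species species index or name.
#' @param value frozen concentration.
#' @return the clamped model.
#' @export
setGeneric("clampSpecies",
           function(model, species, value) standardGeneric("clampSpecies"))

## accessors for result objects -------------------------------------------

#' Per-trajectory response coefficients of an ensemble
#' @param object a \linkS4class{ResponseEnsemble}.
#' @return numeric vector.
#' @export
setGeneric("chis", function(object) standardGeneric("chis"))

#' Mean response coefficient of an ensemble
#' @param object a \linkS4class{ResponseEnsemble}.
#' @return numeric scalar.
#' @export
setGeneric("meanChi", function(object) standardGeneric("meanChi"))

#' Number of failed (excluded) trajectories
#' @param object a \linkS4class{ResponseEnsemble}.
#' @return integer.
#' @export
setGeneric("nFailed", function(object) standardGeneric("nFailed"))

#' Time grid of a trajectory
#' @param object a \linkS4class{Trajectory}.
#' @return numeric vector.
#' @export
setGeneric("timeGrid", function(object) standardGeneric("timeGrid"))

#' Concentration matrix (species x timepoints) of a trajectory
#' @param object a \linkS4class{Trajectory}.
#' @return numeric matrix.
#' @export
setGeneric("concMatrix", function(object) standardGeneric("concMatrix"))

#' Whether a trajectory reached its stopping criterion
#' @param object a \linkS4class{Trajectory}.
#' @return logical.
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' Steady-state concentrations
#' @param object a \linkS4class{SteadyState}.
#' @return numeric vector.
#' @export
setGeneric("steadyConc", function(object) standardGeneric("steadyConc"))

#' Largest real part of the Jacobian spectrum (pool modes removed)
#' @param object a \linkS4class{SteadyState}.
#' @return numeric scalar.
#' @export
setGeneric("maxReEig", function(object) standardGeneric("maxReEig"))
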