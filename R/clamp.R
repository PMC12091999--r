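#' @include response.R
NULL

#' @describeIn clampSpecies freeze one species of a mass-action model; its
#'   derivative becomes identically zero, its concentration is frozen at
#'   \code{value}, and all fluxes keep reading the frozen value.  Conserved
#'   pools are recomputed downstream with the clamped species removed.
#' @export
setMethod("clampSpecies", "MassActionModel", function(model, species, value) {
    net <- model@network
    if (is.character(species))
        species <- match(species, net@species)
    species <- as.integer(species)
    if (is.na(species) || species < 1L || species > length(net@species))
        stop("unknown species")
    if (species %in% model@clamped) {
        warning("species is already clamped; no-op")
        return(model)
    }
    ## no-op warning for species that are constants anyway
    if (all(model@stoich[species, ] == 0) && !net@exchange[species])
        warning("species has no dynamics; clamping is a no-op")
    initialize(model,
               clamped = c(model@clamped, species),
               clampValues = c(model@clampValues, as.numeric(value)))
})

#' Relative change in mean responsiveness under clamping
#'
#' rho+ = (<chi_x> - <chi_ori>) / <chi_ori> when the clamped model responds
#' at least as strongly as the original; otherwise
#' rho- = (<chi_ori> - <chi_x>) / <chi_ori>.  Exactly one sign is reported;
#' a tie is reported as "plus" with rho = 0.
#'
#' @param meanChiClamped mean response coefficient of the clamped model.
#' @param meanChiOriginal mean response coefficient of the original model.
#' @return list with \code{rho} (>= 0) and \code{sign} ("plus" or "minus").
#' @export
#' @examples
#' rhoStatistic(1.5, 1.0)  # rho = 0.5, plus
#' rhoStatistic(1.0, 2.0)  # rho = 0.5, minus
rhoStatistic <- function(meanChiClamped, meanChiOriginal) {
    if (meanChiClamped < 1 - 1e-9 || meanChiOriginal < 1 - 1e-9)
        stop("mean response coefficients must be >= 1")
    if (meanChiClamped >= meanChiOriginal)
        list(rho = (meanChiClamped - meanChiOriginal) / meanChiOriginal,
             sign = "plus")
    else
        list(rho = (meanChiOriginal - meanChiClamped) / meanChiOriginal,
             sign = "minus")
}

#' Metabolite-clamping scan
#'
#' For each dynamic species: clamp it at its steady-state value, re-certify
#' the stability of the attractor under the clamped dynamics (species whose
#' clamping destabilizes the attractor are flagged and excluded from the rho
#' ranking, the cross symbol of the original analysis), and otherwise rerun
#' the response ensemble with the identical perturbation draws as the
#' unclamped model (paired-seed design; the clamped coordinate is not
#' displaced) and report rho.
#'
#' @param model an unclamped \linkS4class{MassActionModel}.
#' @param xSt certified attractor of \code{model} (vector or
#'   \linkS4class{SteadyState}).
#' @param nIni trajectories per ensemble (default 128).
#' @param strength perturbation strength (default 0.4).
#' @param seed integer seed shared by the original and all clamped ensembles.
#' @param species indices to scan (default: all dynamic species).
#' @param stabilityTol relative threshold on max Re(eig) above which the
#'   clamped attractor counts as destabilized (default 1e-8).
#' @param ... integrator settings.
#' @return data.frame with one row per species: \code{species},
#'   \code{meanChiClamped}, \code{rho}, \code{sign}, \code{destabilized},
#'   \code{failed}; sorted by decreasing |rho| (destabilized and failed rows
#'   last, with NA rho).  The unclamped mean chi is attached as attribute
#'   \code{meanChiOriginal}.
#' @export
clampScan <- function(model, xSt, nIni = 128L, strength = 0.4, seed = 1L,
                      species = NULL, stabilityTol = 1e-8, ...) {
    stopifnot(is(model, "MassActionModel"))
    if (is(xSt, "SteadyState")) xSt <- steadyConc(xSt)
    xSt <- unname(xSt)
    n <- nStates(model)
    if (is.null(species)) {
        dyn <- vapply(seq_len(n), function(i)
            any(model@stoich[i, ] != 0) || model@network@exchange[i],
            logical(1))
        species <- which(dyn)
    }
    ## shared perturbation factors: one draw reused for every model variant
    factors <- withSeed(seed,
        matrix(stats::runif(nIni * n, 1 - strength, 1 + strength), nIni, n))
    oriEns <- responseDistribution(model, xSt, nIni = nIni,
                                   strength = strength, factors = factors,
                                   ...)
    chiOri <- meanChi(oriEns)
    rows <- lapply(species, function(s) {
        cm <- suppressWarnings(clampSpecies(model, s, xSt[s]))
        eigScale <- max(abs(eigen(modelJacobian(model, xSt),
                                  only.values = TRUE)$values))
        st <- .stabilityAt(cm, xSt)
        if (is.finite(st) && st > stabilityTol * eigScale)
            return(data.frame(species = model@network@species[s],
                              meanChiClamped = NA_real_, rho = NA_real_,
                              sign = NA_character_, destabilized = TRUE,
                              failed = FALSE))
        ens <- tryCatch(
            responseDistribution(cm, xSt, nIni = nIni, strength = strength,
                                 factors = factors, ...),
            error = function(e) NULL)
        if (is.null(ens))
            return(data.frame(species = model@network@species[s],
                              meanChiClamped = NA_real_, rho = NA_real_,
                              sign = NA_character_, destabilized = FALSE,
                              failed = TRUE))
        rs <- rhoStatistic(meanChi(ens), chiOri)
        data.frame(species = model@network@species[s],
                   meanChiClamped = meanChi(ens), rho = rs$rho,
                   sign = rs$sign, destabilized = FALSE, failed = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(is.na(out$rho), -abs(ifelse(is.na(out$rho), 0, out$rho))), ]
    rownames(out) <- NULL
    attr(out, "meanChiOriginal") <- chiOri
    out
}

#' Clamp several species at once
#'
#' Convenience wrapper used, for example, to freeze all three cofactor forms
#' simultaneously.
#'
#' @param model a \linkS4class{MassActionModel}.
#' @param species indices or names.
#' @param values frozen concentrations (parallel to \code{species}).
#' @return the clamped model.
#' @export
clampMany <- function(model, species, values) {
    for (k in seq_along(species))
        model <- suppressWarnings(
            clampSpecies(model, species[k], values[k]))
    model
}
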