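#' @include minimal_model.R rcrn.R response.R
NULL

.SCHEMA_VERSION <- 1L

#' Serialize a kinetic model to JSON
#'
#' Lossless round trip: \code{loadModel(serializeModel(m, path))} reproduces
#' RHS evaluations bit for bit (numbers are written with 17 significant
#' digits).  The file carries a schema version; mismatched files raise an
#' explicit schema error on load.
#'
#' @param model a \linkS4class{MassActionModel} or \linkS4class{RcrnModel}.
#' @param path output file; NULL returns the JSON string.
#' @return invisibly, the path (or the JSON string when path is NULL).
#' @export
serializeModel <- function(model, path = NULL) {
    if (is(model, "MassActionModel")) {
        net <- model@network
        obj <- list(schema = "kinresponse-model",
                    version = .SCHEMA_VERSION,
                    class = "MassActionModel",
                    nSpecies = net@nSpecies,
                    species = net@species,
                    reactions = net@reactions,
                    exchange = net@exchange,
                    externalConc = net@externalConc,
                    cofactor = net@cofactor,
                    mu = net@mu,
                    beta = model@beta,
                    variant = net@variant,
                    clamped = model@clamped,
                    clampValues = model@clampValues)
    } else if (is(model, "RcrnModel")) {
        obj <- list(schema = "kinresponse-model",
                    version = .SCHEMA_VERSION,
                    class = "RcrnModel",
                    nSpecies = model@nSpecies,
                    edges = model@edges,
                    uptake = model@uptake,
                    externalConc = model@externalConc,
                    transporter = model@transporter)
    } else stop("unsupported model class")
    js <- jsonlite::toJSON(obj, digits = I(17), na = "null",
                           auto_unbox = TRUE, null = "null")
    if (is.null(path)) return(as.character(js))
    writeLines(js, path)
    invisible(path)
}

#' Load a kinetic model from JSON
#'
#' @param path file written by \code{\link{serializeModel}} (or a JSON
#'   string).
#' @return the reconstructed model.
#' @export
loadModel <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(obj$schema) || obj$schema != "kinresponse-model")
        stop("not a kinresponse model file")
    if (is.null(obj$version) || obj$version != .SCHEMA_VERSION)
        stop("schema version mismatch: file has ", obj$version,
             ", this package reads ", .SCHEMA_VERSION)
    if (obj$class == "MassActionModel") {
        rx <- as.data.frame(obj$reactions)
        for (cc in c("sub1", "sub2", "prd1", "prd2"))
            rx[[cc]] <- as.integer(rx[[cc]])
        rx$coupled <- as.logical(rx$coupled)
        cof <- obj$cofactor
        if (length(cof)) cof <- list(forms = cof$forms,
                                     potentials = cof$potentials,
                                     total = cof$total)
        else cof <- list()
        net <- new("ReactionNetwork",
                   nSpecies = as.integer(obj$nSpecies),
                   species = obj$species,
                   reactions = rx,
                   exchange = as.logical(obj$exchange),
                   externalConc = as.numeric(obj$externalConc),
                   cofactor = cof,
                   mu = as.numeric(obj$mu),
                   beta = as.numeric(obj$beta),
                   variant = obj$variant)
        m <- buildKineticModel(net, beta = as.numeric(obj$beta))
        if (length(obj$clamped))
            m <- initialize(m, clamped = as.integer(obj$clamped),
                            clampValues = as.numeric(obj$clampValues))
        m
    } else if (obj$class == "RcrnModel") {
        e <- as.data.frame(obj$edges)
        for (cc in c("i", "j", "cat")) e[[cc]] <- as.integer(e[[cc]])
        new("RcrnModel",
            nSpecies = as.integer(obj$nSpecies),
            edges = e,
            uptake = as.numeric(obj$uptake),
            externalConc = as.numeric(obj$externalConc),
            transporter = as.integer(obj$transporter))
    } else stop("unknown model class in file: ", obj$class)
}

#' Export the reaction graph to GraphML
#'
#' Backbone graph: one node per backbone species (cofactors are attributes,
#' not nodes), one edge per reaction (substrate to product), with rate
#' constant and coupling flag as edge attributes.  For RCRN models the
#' catalyst index is stored as an edge attribute.
#'
#' @param model a \linkS4class{MassActionModel} or \linkS4class{RcrnModel}.
#' @param path output .graphml file.
#' @return invisibly, the path.
#' @export
exportGraphML <- function(model, path) {
    if (is(model, "MassActionModel")) {
        net <- model@network
        rx <- net@reactions
        g <- igraph::make_empty_graph(n = net@nSpecies, directed = FALSE)
        igraph::V(g)$name <- net@species[seq_len(net@nSpecies)]
        g <- igraph::add_edges(g, rbind(rx$sub1, rx$prd1))
        igraph::E(g)$vr <- rx$vr
        igraph::E(g)$coupled <- rx$coupled
        igraph::V(g)$exchange <- net@exchange[seq_len(net@nSpecies)]
    } else if (is(model, "RcrnModel")) {
        e <- model@edges
        g <- igraph::make_empty_graph(n = model@nSpecies, directed = FALSE)
        igraph::V(g)$name <- paste0("C", seq_len(model@nSpecies))
        g <- igraph::add_edges(g, rbind(e$i, e$j))
        igraph::E(g)$catalyst <- e$cat
        igraph::E(g)$vf <- e$vf
        igraph::E(g)$vb <- e$vb
    } else stop("unsupported model class")
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' Ensemble sweep over network density and coupling fraction
#'
#' For every (R, f) cell of the grid, generates \code{nNetworks} independent
#' minimal cofactor models, finds each network's attractor, runs the
#' perturbation-response protocol, and records the mean response
#' coefficient.  Networks whose attractor search fails, whose attractor is
#' unstable, or whose response ensemble fails are recorded with
#' \code{NA} mean chi and a status label, never silently dropped.
#'
#' @param cells data.frame with columns \code{R} and \code{f} (one row per
#'   grid cell).
#' @param nSpecies backbone size N (default 16).
#' @param nNetworks networks per cell (default 64).
#' @param nIni trajectories per network (default 32).
#' @param strength perturbation strength (default 0.4).
#' @param beta inverse temperature (default 10).
#' @param seed integer root seed; network k of cell c uses
#'   childSeed(seed, c, k).
#' @param outDir optional output directory: writes \code{sweep.csv} (one row
#'   per network) and \code{manifest.json} (full provenance: seed, config,
#'   package version, exclusion counts).
#' @param ... integrator settings.
#' @return tidy data.frame: R, f, network, seed, meanChi, nFailed, status.
#' @export
runSweep <- function(cells, nSpecies = 16, nNetworks = 64L, nIni = 32L,
                     strength = 0.4, beta = 10, seed = 1L, outDir = NULL,
                     ...) {
    stopifnot(is.data.frame(cells), all(c("R", "f") %in% names(cells)))
    rows <- vector("list", nrow(cells) * nNetworks)
    ii <- 0L
    for (ci in seq_len(nrow(cells))) {
        R <- cells$R[ci]; f <- cells$f[ci]
        for (k in seq_len(nNetworks)) {
            sd <- childSeed(seed, ci, k)
            ii <- ii + 1L
            status <- "ok"; mc <- NA_real_; nf <- NA_integer_
            m <- generateMinimalModel(nSpecies, R, f = f, beta = beta,
                                      seed = sd)
            ss <- tryCatch(findAttractor(m, ...), error = function(e) NULL)
            if (is.null(ss)) status <- "attractor-failed"
            else if (!.isStable(ss@maxReEig)) status <- "unstable-attractor"
            else {
                ens <- tryCatch(
                    responseDistribution(m, ss, nIni = nIni,
                                         strength = strength,
                                         seed = childSeed(sd, 9L), ...),
                    error = function(e) NULL)
                if (is.null(ens)) status <- "ensemble-failed"
                else { mc <- meanChi(ens); nf <- nFailed(ens) }
            }
            rows[[ii]] <- data.frame(R = R, f = f, network = k, seed = sd,
                                     meanChi = mc, nFailed = nf,
                                     status = status)
        }
    }
    out <- do.call(rbind, rows)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(out, file.path(outDir, "sweep.csv"),
                         row.names = FALSE)
        cfg <- list(nSpecies = nSpecies, nNetworks = nNetworks,
                    nIni = nIni, strength = strength, beta = beta,
                    cells = cells)
        manifest <- list(
            seed = seed,
            config = cfg,
            configHash = .cheapHash(cfg),
            package = as.character(utils::packageVersion("kinresponse")),
            excluded = as.list(table(out$status)))
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = I(17))
    }
    out
}

## order-sensitive polynomial hash of a serialized R object, for manifests
.cheapHash <- function(obj) {
    b <- as.double(serialize(obj, NULL, version = 2)[-(1:14)])  # skip header
    h <- 0
    for (x in b) h <- (h * 257 + x + 1) %% 2147483647
    sprintf("%08x", as.integer(h))
}
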