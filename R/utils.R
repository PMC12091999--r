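#' Round half away from zero
#'
#' Deterministic rounding used everywhere a count is derived from a fraction
#' (cofactor couplings Round(f R), exchange count Round(0.05 N)).  Base R's
#' \code{round()} rounds half to even, which would make tied counts (for
#' example f = 0.5 with R = 63) depend on the parity of the neighbour; half
#' away from zero keeps them deterministic and monotone in the fraction.
#'
#' @param x numeric.
#' @return integer-valued numeric.
#' @export
#' @examples
#' roundHalf(31.5)  # 32, where round(31.5) would give 32 but round(30.5) 30
roundHalf <- function(x) {
    sign(x) * floor(abs(x) + 0.5)
}

## Evaluate expr with the RNG seeded at `seed` (restoring the caller's RNG
## state), or with the current RNG stream when seed is NULL.  All stochastic
## functions in the package funnel through this.
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(force(expr))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())))
    }
    set.seed(seed)
    force(expr)
}

#' Derive a child seed from a root seed
#'
#' Deterministic splitting rule used by the ensemble drivers so that every
#' network / trajectory batch gets an independent, reproducible stream:
#' the root seed and the index path are hashed by a multiplicative-linear
#' rule modulo the Mersenne prime 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param ... one or more non-negative integer indices (e.g. cell, network).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, ...) {
    idx <- c(...)
    h <- as.double(seed %% 2147483647)
    for (k in idx) {
        h <- (h * 48271 + as.double(k) + 1) %% 2147483647
    }
    as.integer(h + 1)
}

## log-spaced output grid for stiff relaxations: 0, then npts points from
## tmin to tmax (log-uniform).  Dense enough that the chi maximum is resolved
## (validated against a brute-force oracle in the tests).
logTimes <- function(tmax, npts = 512L, tmin = NULL) {
    if (is.null(tmin))
        tmin <- min(1e-9, tmax * 1e-10)   # resolve the fastest transients
    c(0, exp(seq(log(tmin), log(tmax), length.out = npts)))
}

## Exact integer left-null-space of an integer matrix.
##
## Returns an integer matrix whose rows y satisfy y %*% A == 0 exactly.
## Fraction-free Gauss-Jordan on the transpose: we row-reduce t(A) augmented
## implicitly by tracking the combination, or more simply compute the null
## space of t(A) (vectors y with t(A) y = 0).  Entries stay small for the
## stoichiometries handled here (all in {-2,...,2}).
intLeftNull <- function(A) {
    if (!is.matrix(A)) A <- as.matrix(A)
    M <- t(A) * 1.0                 # solve M y = 0; exact small integers
    nr <- nrow(M); nc <- ncol(M)
    if (nc == 0L) return(matrix(0, 0, 0))
    if (nr == 0L) return(diag(nc))
    pivcol <- integer(0)
    r <- 1L
    for (j in seq_len(nc)) {
        if (r > nr) break
        p <- which(M[r:nr, j] != 0)
        if (!length(p)) next
        p <- p[1] + r - 1L
        if (p != r) M[c(p, r), ] <- M[c(r, p), ]
        ## fraction-free elimination: integer row combinations, then divide
        ## each row by the gcd of its entries to keep values small
        for (i in seq_len(nr)) {
            if (i == r || M[i, j] == 0) next
            g <- .gcd(M[i, j], M[r, j])
            a <- M[r, j] / g; b <- M[i, j] / g
            M[i, ] <- a * M[i, ] - b * M[r, ]
            nz <- abs(M[i, M[i, ] != 0])
            if (length(nz)) {
                g2 <- Reduce(.gcd, nz)
                if (g2 > 1) M[i, ] <- M[i, ] / g2
            }
        }
        pivcol <- c(pivcol, j)
        r <- r + 1L
    }
    freecol <- setdiff(seq_len(nc), pivcol)
    if (!length(freecol)) return(matrix(0, 0, nc))
    basis <- matrix(0, length(freecol), nc)
    for (k in seq_along(freecol)) {
        fc <- freecol[k]
        y <- numeric(nc)
        y[fc] <- 1
        ## back-substitute pivots: row i has pivot at pivcol[i]
        for (i in rev(seq_along(pivcol))) {
            pc <- pivcol[i]
            rhs <- -sum(M[i, -pc] * y[-pc])
            y[pc] <- rhs / M[i, pc]
        }
        ## clear denominators to an integer vector
        den <- y[y != 0]
        if (length(den)) {
            f <- .lcmDen(y)
            y <- y * f
            g <- Reduce(.gcd, abs(y[y != 0]))
            if (g > 1) y <- y / g
        }
        basis[k, ] <- y
    }
    basis
}

.gcd <- function(a, b) {
    a <- abs(a); b <- abs(b)
    while (b > 1e-9) {
        t <- b; b <- a %% b; a <- t
    }
    a
}

## smallest multiplier making all entries integral (entries are exact
## ratios of small integers, so denominators are bounded)
.lcmDen <- function(y) {
    f <- 1
    for (v in y[y != 0]) {
        w <- v * f
        k <- 1
        while (abs(w * k - round(w * k)) > 1e-9 && k < 1e6) k <- k + 1
        f <- f * k
    }
    f
}
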