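#' @useDynLib BrainAgeMI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# TRUE if vector a precedes b lexicographically (first differing element).
# Used to assign the two seeded jitter streams to variables canonically, so
# that ksgMI(x, y) and ksgMI(y, x) see the identical jittered point cloud.
.vecPrecedes <- function(a, b) {
    i <- which(a != b)
    if (!length(i)) TRUE else a[i[1]] < b[i[1]]
}

#' Kraskov (KSG) mutual-information estimate
#'
#' Nearest-neighbour estimator of I(X;Y) for continuous variables (Kraskov
#' family, variant 1):
#' `I = psi(k) - < psi(n_x + 1) + psi(n_y + 1) > + psi(N)` in nats, where
#' the k-th neighbour ball uses the Chebyshev (maximum-coordinate) metric in
#' the joint space and the marginal counts `n_x`, `n_y` use strict
#' inequality within that k-th neighbour distance. A seeded uniform jitter
#' of amplitude `1e-10 * sd` breaks ties (morphometry values can collide
#' after rounding; the estimator assumes continuous distributions); the
#' estimate is deterministic given (data, k, seed) and exactly symmetric in
#' its arguments at a fixed seed. Negative raw estimates (possible for
#' weakly dependent data) are clipped to zero; the raw value is kept in the
#' returned object.
#'
#' @param x,y equal-length finite numeric vectors, n > k.
#' @param k neighbour count (default 3).
#' @param seed integer seed for the tie-breaking jitter only.
#' @param jitterAmplitude relative jitter amplitude (times each variable's
#'   sd); set 0 to disable.
#' @return An [MIEstimate-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- x + rnorm(500)
#' miValue(ksgMI(x, y))
#' @export
ksgMI <- function(x, y, k = 3L, seed = 1L, jitterAmplitude = 1e-10) {
    n <- length(x)
    if (length(y) != n) stop("x and y must have equal length")
    if (!n || anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
        stop("inputs must be finite and non-empty")
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (n <= k) stop("need more samples than neighbours (n > k)")
    # z-score each marginal before the max-norm neighbour search: the
    # Chebyshev ball couples the two coordinates, so wildly different scales
    # (e.g. mm^3 against years) would otherwise dominate the neighbourhoods.
    # The transform is affine and leaves the population MI unchanged.
    sx0 <- stats::sd(x); sy0 <- stats::sd(y)
    if (sx0 > 0) x <- (x - mean(x)) / sx0
    if (sy0 > 0) y <- (y - mean(y)) / sy0
    if (jitterAmplitude > 0) {
        u <- withSeed(seed, matrix(stats::runif(2L * n, -1, 1), ncol = 2L))
        sx <- stats::sd(x); sy <- stats::sd(y)
        ax <- jitterAmplitude * if (sx > 0) sx else 1
        ay <- jitterAmplitude * if (sy > 0) sy else 1
        if (.vecPrecedes(x, y)) {
            x <- x + ax * u[, 1L]; y <- y + ay * u[, 2L]
        } else {
            x <- x + ax * u[, 2L]; y <- y + ay * u[, 1L]
        }
    }
    cnt <- .ksgCounts(as.numeric(x), as.numeric(y), k)
    raw <- digamma(k) - mean(digamma(cnt$nx + 1) + digamma(cnt$ny + 1)) +
        digamma(n)
    new("MIEstimate", value = max(raw, 0), raw = raw, k = k, n = as.integer(n))
}

#' @describeIn ksgMI The clipped MI value in nats.
#' @param est an [MIEstimate-class].
#' @export
miValue <- function(est) est@value

#' @describeIn ksgMI The unclipped raw estimate in nats.
#' @export
miRaw <- function(est) est@raw

#' Plug-in mutual information of a discrete joint distribution
#'
#' Exact MI of a known joint probability table via the entropy identity
#' `I(x;y) = H(x) + H(y) - H(x,y)` with `H = -sum p log p` (natural log).
#' Serves as the exact small-instance oracle for the continuous estimator.
#'
#' @param joint numeric matrix of joint probabilities; entries >= 0 and
#'   summing to 1 (within 1e-9).
#' @return MI in nats.
#' @export
pluginDiscreteMI <- function(joint) {
    joint <- as.matrix(joint)
    if (any(joint < 0)) stop("probabilities must be non-negative")
    if (abs(sum(joint) - 1) > 1e-9)
        stop("joint probabilities must sum to 1 (within 1e-9)")
    H <- function(p) {
        p <- p[p > 0]
        -sum(p * log(p))
    }
    H(rowSums(joint)) + H(colSums(joint)) - H(joint)
}

setMethod("show", "MIEstimate", function(object) {
    cat(sprintf("MIEstimate: %.4f nats (raw %.4f; k = %d, n = %d)\n",
                object@value, object@raw, object@k, object@n))
})
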