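# Core per-locus statistics.
#
# Everything funnels through .flipStats(), which evaluates the PC and Z^2
# statistics at every locus for an arbitrary stack of trio-level sign
# flips in one shot: the flipped means need only three (B x n) %*% (n x q)
# matrix products because sums of squares are flip-invariant, and the
# 2 x 2 eigenproblem is solved in closed form elementwise. The observed
# statistics are the special case of a single all-(+1) flip row, so the
# permutation path and the data path share every convention by
# construction.

.TRACE_EPS <- 1e-12

# Closed-form eigen decomposition of symmetric 2x2 matrices [[a, b], [b, c]]
# given elementwise; eigenvectors canonicalized so the first nonzero
# component is positive (multiplied by `sgn` to flip the convention
# globally). Isotropic matrices (a == c, b == 0) fall back to the
# coordinate axes.
.eigen2 <- function(a, b, c, sgn = 1) {
    tr <- a + c
    disc <- sqrt(((a - c) / 2)^2 + b^2)
    l1 <- tr / 2 + disc
    l2 <- tr / 2 - disc
    # two algebraically equivalent eigenvector forms; pick the
    # numerically larger one per entry
    big <- a >= c
    v1 <- ifelse(big, l1 - c, b)
    v2 <- ifelse(big, b, l1 - a)
    nrm <- sqrt(v1^2 + v2^2)
    iso <- nrm == 0
    v1 <- ifelse(iso, 1, v1)
    v2 <- ifelse(iso, 0, v2)
    nrm <- ifelse(iso, 1, nrm)
    v1 <- v1 / nrm
    v2 <- v2 / nrm
    s1 <- ifelse(v1 != 0, sign(v1), sign(v2))
    e11 <- sgn * s1 * v1
    e12 <- sgn * s1 * v2
    # e2 is e1 rotated by 90 degrees, then canonicalized
    w1 <- -e12
    w2 <- e11
    s2 <- ifelse(w1 != 0, sign(w1), sign(w2))
    e21 <- sgn * s2 * w1
    e22 <- sgn * s2 * w2
    list(l1 = l1, l2 = l2, e11 = e11, e12 = e12, e21 = e21, e22 = e22,
         tr = tr)
}

# PC and Z^2 at every locus under a stack of B trio-level sign flips.
# Returns B x q matrices `pc`, `z2x`, `z2y`, plus per-locus complete
# counts and flip-invariant usability masks.
.flipStats <- function(diffs, flipX, flipY, signConvention = c("positive", "negative")) {
    signConvention <- match.arg(signConvention)
    sgn <- if (signConvention == "positive") 1 else -1
    X <- diffs@X
    Y <- diffs@Y
    q <- ncol(X)
    B <- nrow(flipX)
    n <- colSums(diffs@complete)
    sxx <- colSums(X * X)
    syy <- colSums(Y * Y)
    SX <- flipX %*% X
    SY <- flipY %*% Y
    SXY <- (flipX * flipY) %*% (X * Y)

    nm <- matrix(n, B, q, byrow = TRUE)
    mx <- SX / nm
    my <- SY / nm
    # sample covariance entries (denominator n - 1) of the flipped data;
    # sums of squares are unchanged by sign flips
    den <- nm - 1
    a <- (matrix(sxx, B, q, byrow = TRUE) - nm * mx^2) / den
    cc <- (matrix(syy, B, q, byrow = TRUE) - nm * my^2) / den
    b <- (SXY - nm * mx * my) / den
    eg <- .eigen2(a, b, cc, sgn = sgn)
    u1 <- eg$e11 + eg$e21
    u2 <- eg$e12 + eg$e22
    pc <- nm * (u1 * mx + u2 * my)^2 / eg$tr
    pc[!(eg$tr > .TRACE_EPS)] <- 0

    z2x <- SX^2 / matrix(sxx, B, q, byrow = TRUE)
    z2x[, sxx == 0] <- 0
    z2y <- SY^2 / matrix(syy, B, q, byrow = TRUE)
    z2y[, syy == 0] <- 0

    list(pc = pc, z2x = z2x, z2y = z2y, n = n,
         usablePC = n >= 2L & (sxx + syy) > 0,
         usableZ = n >= 1L)
}

.identityFlips <- function(nTrios) matrix(1, 1L, nTrios)

.rowMax <- function(m) as.numeric(Reduce(pmax, asplit(m, 2L)))

.newMaxStat <- function(statistic, perLocus, n, usable) {
    vals <- perLocus[usable]
    if (!length(vals))
        stop("no usable locus: every locus has fewer than 2 complete trios or no variation")
    new("MaxStatResult", statistic = statistic,
        perLocus = ifelse(usable, perLocus, NA_real_),
        nComplete = as.integer(n),
        maxStat = max(vals),
        argmax = which(usable)[which.max(vals)],
        pValue = NA_real_, nullStats = numeric(),
        nPermutations = 0L, seed = NA_integer_)
}

#' PC statistic at a single locus
#'
#' Forms the sample covariance matrix S of the paired observations
#' Z_i = (x_i, y_i)', extracts its eigenpairs (lambda_1 >= lambda_2,
#' unit eigenvectors with first nonzero component positive), projects the
#' sample mean onto them (zetaBar_k = e_k' Zbar), and evaluates
#' PC = n (zetaBar_1 + zetaBar_2)^2 / (lambda_1 + lambda_2). Under the
#' joint null of no association and no maternal effect, PC is
#' asymptotically central chi-square with 1 degree of freedom.
#'
#' @param x,y numeric vectors of equal length n >= 2: the X = 2C - F - M
#'   and Y = M - F values of the complete trios at one locus.
#' @param signConvention global eigenvector sign convention; the PC value
#'   (and any permutation p-value) is identical under either, because the
#'   same convention is applied everywhere and the numerator is squared.
#' @return A [LocusPC-class] object. When lambda_1 + lambda_2 = 0 (no
#'   variation at all), the locus is flagged degenerate and PC = 0.
#' @examples
#' locusPC(c(1, -1, 1, 1), c(0, 1, -1, 0))
#' @export
locusPC <- function(x, y, signConvention = c("positive", "negative")) {
    signConvention <- match.arg(signConvention)
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (n < 2L)
        stop("locusPC needs at least 2 complete trios")
    diffs <- new("DiffVectors", X = cbind(as.numeric(x)),
                 Y = cbind(as.numeric(y)),
                 complete = cbind(rep(TRUE, n)), snpId = "locus")
    st <- .flipStats(diffs, .identityFlips(n), .identityFlips(n),
                     signConvention = signConvention)
    sgn <- if (signConvention == "positive") 1 else -1
    mx <- mean(x)
    my <- mean(y)
    S <- matrix(c(sum((x - mx)^2), sum((x - mx) * (y - my)),
                  sum((x - mx) * (y - my)), sum((y - my)^2)) / (n - 1), 2L)
    eg <- .eigen2(S[1L, 1L], S[1L, 2L], S[2L, 2L], sgn = sgn)
    vecs <- matrix(c(eg$e11, eg$e12, eg$e21, eg$e22), 2L)
    zbar <- drop(crossprod(vecs, c(mx, my)))
    new("LocusPC", nComplete = as.integer(n), S = S,
        lambda = c(eg$l1, eg$l2), vectors = vecs, zetaBar = zbar,
        pc = st$pc[1L, 1L], degenerate = !(eg$tr > .TRACE_EPS))
}

#' @export
setMethod("show", "LocusPC", function(object) {
    cat("LocusPC: n =", object@nComplete,
        if (object@degenerate) "(degenerate)" else "", "\n")
    cat("  eigenvalues:", format(object@lambda, digits = 4), "\n")
    cat("  PC =", format(object@pc, digits = 6), "\n")
})

#' Z^2 statistic at a single locus
#'
#' The squared standardized transmission sum Z^2 = (sum d_i)^2 / sum d_i^2
#' for the per-trio differences d at one locus (d = X for association,
#' d = Y for maternal effects); 0 when all d_i = 0.
#'
#' @param d numeric vector of per-trio differences (complete trios only).
#' @return The Z^2 value.
#' @examples
#' locusZ2(c(1, 1, 1))       # 3
#' locusZ2(c(2, 0, -1, 1))   # 4/6
#' @export
locusZ2 <- function(d) {
    if (!length(d))
        stop("locusZ2 needs at least one complete trio")
    ss <- sum(d * d)
    if (ss == 0) 0 else sum(d)^2 / ss
}

#' Maximum PC statistic across loci
#'
#' Evaluates the PC statistic at every usable locus (at least 2 complete
#' trios and some variation in (X, Y)) and returns the maximum,
#' max_PC = max_l PC^(l). Per-locus complete-case analysis means the
#' trio count may differ across loci; loci that are unusable are dropped
#' from the maximum with a message. Significance across the correlated
#' loci is assessed by permutation (see [permuteStat()]).
#'
#' @param diffs a [DiffVectors-class] object from [computeDiffVectors()].
#' @return A [MaxStatResult-class] object (p-value unset).
#' @export
maxPC <- function(diffs) {
    stopifnot(is(diffs, "DiffVectors"))
    n <- nrow(diffs@X)
    st <- .flipStats(diffs, .identityFlips(n), .identityFlips(n))
    if (any(!st$usablePC))
        message(sum(!st$usablePC),
                " locus/loci unusable (fewer than 2 complete trios or monomorphic); excluded from the max")
    .newMaxStat("maxPC", drop(st$pc), st$n, st$usablePC)
}

#' Maximum Z^2 statistic across loci
#'
#' The max_Z^2 comparator: per-locus Z^2 on the association differences
#' X = 2C - F - M (`channel = "association"`) or the maternal differences
#' Y = M - F (`channel = "maternal"`), maximized over loci under the same
#' per-locus complete-case contract as [maxPC()].
#'
#' @param diffs a [DiffVectors-class] object.
#' @param channel which difference vector to test.
#' @return A [MaxStatResult-class] object (p-value unset).
#' @export
maxZ2 <- function(diffs, channel = c("association", "maternal")) {
    stopifnot(is(diffs, "DiffVectors"))
    channel <- match.arg(channel)
    n <- nrow(diffs@X)
    st <- .flipStats(diffs, .identityFlips(n), .identityFlips(n))
    if (any(!st$usableZ))
        message(sum(!st$usableZ),
                " locus/loci with no complete trios; excluded from the max")
    if (channel == "association")
        .newMaxStat("maxZ2assoc", drop(st$z2x), st$n, st$usableZ)
    else
        .newMaxStat("maxZ2maternal", drop(st$z2y), st$n, st$usableZ)
}

#' @export
setMethod("show", "MaxStatResult", function(object) {
    cat("MaxStatResult [", object@statistic, "]\n", sep = "")
    cat("  usable loci:", sum(!is.na(object@perLocus)), "of",
        length(object@perLocus), "\n")
    cat("  max =", format(object@maxStat, digits = 6),
        "at locus", object@argmax, "\n")
    if (!is.na(object@pValue))
        cat("  permutation p =", format(object@pValue, digits = 4),
            "(", object@nPermutations, "permutations, seed",
            object@seed, ")\n")
})
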