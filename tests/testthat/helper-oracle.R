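# Brute-force oracles, written independently of the package internals:
# covariance via stats::cov, eigen decomposition via LAPACK (base eigen),
# statistics evaluated directly from their defining formulas, explicit
# per-locus complete-case loops. Shared only: the eigenvector
# canonicalization rule (first nonzero component positive), which is part
# of the statistic's definition here.

canonVec <- function(v) {
    s <- if (v[1] != 0) sign(v[1]) else sign(v[2])
    if (s == 0) s <- 1
    v * s
}

oraclePC <- function(x, y) {
    n <- length(x)
    S <- stats::cov(cbind(x, y))
    if (sum(diag(S)) <= 1e-12) return(0)
    ee <- eigen(S, symmetric = TRUE)
    e1 <- canonVec(ee$vectors[, 1])
    e2 <- canonVec(ee$vectors[, 2])
    zbar <- c(sum(e1 * c(mean(x), mean(y))), sum(e2 * c(mean(x), mean(y))))
    n * sum(zbar)^2 / sum(ee$values)
}

oracleZ2 <- function(d) {
    if (sum(d^2) == 0) 0 else sum(d)^2 / sum(d^2)
}

# Per-locus statistics from raw difference matrices with a completeness
# mask; NA for unusable loci.
oraclePerLocus <- function(X, Y, complete, stat = c("pc", "z2x", "z2y")) {
    stat <- match.arg(stat)
    q <- ncol(X)
    out <- rep(NA_real_, q)
    for (l in seq_len(q)) {
        ok <- complete[, l]
        x <- X[ok, l]
        y <- Y[ok, l]
        if (stat == "pc") {
            if (sum(ok) >= 2 && sum(x^2) + sum(y^2) > 0)
                out[l] <- oraclePC(x, y)
        } else if (sum(ok) >= 1) {
            out[l] <- oracleZ2(if (stat == "z2x") x else y)
        }
    }
    out
}

oracleMax <- function(X, Y, complete, stat) {
    max(oraclePerLocus(X, Y, complete, stat), na.rm = TRUE)
}

# Permutation p-value recomputed by looping over the plan's flip rows
# and re-running the oracle on explicitly flipped data.
oraclePermP <- function(X, Y, complete, plan, stat) {
    obs <- oracleMax(X, Y, complete, stat)
    B <- plan@nPermutations
    nulls <- numeric(B)
    for (b in seq_len(B)) {
        Xb <- X * plan@flipX[b, ]
        Yb <- Y * plan@flipY[b, ]
        nulls[b] <- oracleMax(Xb, Yb, complete, stat)
    }
    mean(nulls > obs)
}

# Mendelian-consistent random trios: parents as independent Bernoulli
# allele pairs, child inherits one random allele from each parent.
randomTrios <- function(nTrios, nLoci, freq = NULL, missRate = 0) {
    if (is.null(freq)) freq <- runif(nLoci, 0.2, 0.8)
    m1 <- matrix(rbinom(nTrios * nLoci, 1, rep(freq, each = nTrios)), nTrios)
    m2 <- matrix(rbinom(nTrios * nLoci, 1, rep(freq, each = nTrios)), nTrios)
    f1 <- matrix(rbinom(nTrios * nLoci, 1, rep(freq, each = nTrios)), nTrios)
    f2 <- matrix(rbinom(nTrios * nLoci, 1, rep(freq, each = nTrios)), nTrios)
    pickm <- matrix(runif(nTrios * nLoci) < 0.5, nTrios)
    pickf <- matrix(runif(nTrios * nLoci) < 0.5, nTrios)
    C <- ifelse(pickm, m1, m2) + ifelse(pickf, f1, f2)
    tg <- trioGenotypes(m1 + m2, f1 + f2, C)
    if (missRate > 0) tg <- maskGenotypes(tg, missRate)
    tg
}
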