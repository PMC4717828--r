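test_that("degenerate and zero-mean loci give PC = 0", {
    r <- locusPC(rep(0, 6), rep(0, 6))
    expect_true(r@degenerate)
    expect_equal(r@pc, 0)

    # zero means but positive variance: numerator vanishes
    r <- locusPC(c(1, -1, 1, -1), c(0, 0, 0, 0))
    expect_false(r@degenerate)
    expect_equal(r@pc, 0)
})

test_that("locusPC matches the brute-force oracle on a fixed 10-trio fixture", {
    x <- c(2, 0, -1, 1, 0, 1, -2, 0, 1, 1)
    y <- c(1, -1, 0, 0, 1, 1, 0, -1, 2, 0)
    r <- locusPC(x, y)
    expect_equal(r@pc, oraclePC(x, y), tolerance = 1e-12)
    # closed form: pc = n ((e1 + e2)' zbar)^2 / (l1 + l2)
    u <- rowSums(r@vectors)
    expect_equal(r@pc,
                 10 * sum(u * c(mean(x), mean(y)))^2 / sum(r@lambda),
                 tolerance = 1e-12)
})

test_that("eigenpairs are orthonormal, ordered, and sum to the trace", {
    set.seed(42)
    for (i in 1:50) {
        n <- sample(5:40, 1)
        x <- sample(-2:2, n, TRUE)
        y <- sample(-2:2, n, TRUE)
        r <- locusPC(x, y)
        if (r@degenerate) next
        V <- r@vectors
        expect_lt(max(abs(crossprod(V) - diag(2))), 1e-10)
        expect_gte(r@lambda[1], r@lambda[2])
        expect_gte(r@lambda[2], -1e-12)
        expect_lt(abs(sum(r@lambda) - sum(diag(r@S))), 1e-10)
        expect_gte(r@pc, 0)
        # canonical sign: first nonzero component positive
        for (k in 1:2) {
            v <- V[, k]
            expect_gt(if (v[1] != 0) v[1] else v[2], 0)
        }
    }
})

test_that("locusZ2 evaluates the standardized-sum ratio", {
    expect_equal(locusZ2(c(1, 1, 1)), 3)
    expect_equal(locusZ2(c(1, -1)), 0)
    expect_equal(locusZ2(c(2, 0, -1, 1)), 4 / 6)
    expect_equal(locusZ2(c(0, 0)), 0)
    expect_error(locusZ2(numeric()), "at least one")
})

test_that("max statistics agree with the oracle on 100 random fixtures with missing data", {
    set.seed(2024)
    for (i in 1:100) {
        n <- sample(4:20, 1)
        q <- sample(1:5, 1)
        tg <- randomTrios(n, q, missRate = if (i %% 2) 0.1 else 0)
        d <- computeDiffVectors(tg)
        opc <- oraclePerLocus(d@X, d@Y, d@complete, "pc")
        if (all(is.na(opc))) next
        r <- suppressMessages(maxPC(d))
        expect_equal(r@perLocus, opc, tolerance = 1e-10)
        expect_equal(r@maxStat, max(opc, na.rm = TRUE), tolerance = 1e-10)
        rz <- suppressMessages(maxZ2(d, "association"))
        expect_equal(rz@maxStat,
                     oracleMax(d@X, d@Y, d@complete, "z2x"),
                     tolerance = 1e-10)
        rz <- suppressMessages(maxZ2(d, "maternal"))
        expect_equal(rz@maxStat,
                     oracleMax(d@X, d@Y, d@complete, "z2y"),
                     tolerance = 1e-10)
    }
})

test_that("argmax takes the maximum with lowest-index ties and matches per-locus values", {
    set.seed(77)
    tg <- randomTrios(30, 8)
    d <- computeDiffVectors(tg)
    r <- maxPC(d)
    expect_equal(r@maxStat, max(r@perLocus, na.rm = TRUE))
    expect_equal(r@argmax, which(r@perLocus == r@maxStat)[1])
})

test_that("masking one trio at one locus changes only that locus's statistics", {
    set.seed(8)
    tg <- randomTrios(25, 6)
    before <- suppressMessages(maxPC(computeDiffVectors(tg)))@perLocus
    tg@C[3, 4] <- NA_integer_
    after <- suppressMessages(maxPC(computeDiffVectors(tg)))@perLocus
    expect_identical(before[-4], after[-4])
    expect_false(identical(before[4], after[4]))
})

test_that("maxPC refuses data with no usable locus", {
    tg <- trioGenotypes(M = cbind(c(1, 1)), F = cbind(c(1, 1)),
                        C = cbind(c(1, 1)))
    expect_error(suppressMessages(maxPC(computeDiffVectors(tg))),
                 "no usable locus")
})
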