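test_that("difference vectors follow X = 2C - F - M, Y = M - F with a complete-case mask", {
    tg <- trioGenotypes(M = rbind(c(2, 1, 2)),
                        F = rbind(c(0, 1, 2)),
                        C = rbind(c(1, 1, NA)))
    d <- computeDiffVectors(tg)
    expect_equal(d@X[1, 1:2], c(0, 0))
    expect_equal(d@Y[1, 1:2], c(2, 0))
    expect_equal(d@complete[1, ], c(TRUE, TRUE, FALSE))

    set.seed(5)
    tg <- randomTrios(40, 6, missRate = 0.15)
    d <- computeDiffVectors(tg)
    cc <- !(is.na(tg@M) | is.na(tg@F) | is.na(tg@C))
    expect_identical(d@complete, cc)
    expect_equal(d@X[cc], (2 * tg@C - tg@F - tg@M)[cc])
    expect_equal(d@Y[cc], (tg@M - tg@F)[cc])
    expect_true(all(d@X[!cc] == 0) && all(d@Y[!cc] == 0))
    expect_true(all(abs(d@X[cc]) <= 4) && all(abs(d@Y[cc]) <= 2))
})

test_that("genotype counts outside 0..2 are rejected", {
    expect_error(trioGenotypes(M = matrix(3), F = matrix(0), C = matrix(1)),
                 "0, 1, 2")
})

test_that("Mendelian screen flags impossible triples and only those", {
    tg <- trioGenotypes(M = rbind(c(0, 2, 1, 1)),
                        F = rbind(c(0, 2, 0, 1)),
                        C = rbind(c(1, 2, 2, 0)))
    v <- checkMendelian(tg)
    expect_equal(sort(v$locus), c(1, 3))  # C>0 with no parental A; father cannot transmit A

    # exhaustive: every (M, F, C) triple vs direct enumeration of
    # transmissible allele pairs
    grid <- expand.grid(M = 0:2, F = 0:2, C = 0:2)
    tg <- trioGenotypes(M = t(grid$M), F = t(grid$F), C = t(grid$C))
    flagged <- seq_len(nrow(grid)) %in% checkMendelian(tg)$locus
    possible <- mapply(function(m, f, c) {
        tm <- unique(c((m == 2) + 0, (m >= 1) + 0))
        tf <- unique(c((f == 2) + 0, (f >= 1) + 0))
        c %in% outer(tm, tf, "+")
    }, grid$M, grid$F, grid$C)
    expect_identical(flagged, !possible)
})

test_that("masking hits the requested rate and shrinks the complete mask", {
    set.seed(11)
    tg <- randomTrios(300, 20)
    expect_identical(maskGenotypes(tg, 0), tg)
    mk <- maskGenotypes(tg, 0.1)
    frac <- mean(is.na(cbind(mk@M, mk@F, mk@C)))
    se <- sqrt(0.1 * 0.9 / (3 * 300 * 20))
    expect_lt(abs(frac - 0.1), 3 * se)
    d <- computeDiffVectors(mk)
    expect_lt(sum(d@complete), sum(computeDiffVectors(tg)@complete))
})
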