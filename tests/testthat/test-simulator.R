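test_that("Markov haplotypes recover marker frequencies and adjacent-pair LD", {
    set.seed(100)
    # independence case: D' = 0 everywhere
    m0 <- populationModel(nMarkers = 5, ldRange = c(0, 0))
    h <- sampleMarkerHaplotypes(m0, 50000)
    freq <- colMeans(h)
    se <- sqrt(m0@markerFreqs * (1 - m0@markerFreqs) / 50000)
    expect_true(all(abs(freq - m0@markerFreqs) < 3.5 * se))
    for (l in 1:4) {
        D <- mean(h[, l] * h[, l + 1]) - freq[l] * freq[l + 1]
        expect_lt(abs(D), 3.5 * sqrt(prod(freq[l:(l + 1)] *
                                          (1 - freq[l:(l + 1)])) / 50000) + 1e-3)
    }

    # strong LD at fifty-fifty frequencies: empirical D' near 0.9
    m9 <- populationModel(nMarkers = 4, freqRange = c(0.5, 0.5),
                          ldRange = c(0.9, 0.9))
    h <- sampleMarkerHaplotypes(m9, 50000)
    for (l in 1:3) {
        p <- colMeans(h)
        D <- mean(h[, l] * h[, l + 1]) - p[l] * p[l + 1]
        dmax <- min(p[l] * (1 - p[l + 1]), (1 - p[l]) * p[l + 1])
        expect_lt(abs(D / dmax - 0.9), 0.03)
    }
})

test_that("disease haplotypes start ancestral and decay with time", {
    set.seed(101)
    pm <- populationModel()
    h0 <- evolveDiseaseHaplotypes(
        populationModel(generations = 0), 200)
    expect_equal(nrow(unique(h0)), 1L)

    norec <- populationModel(recombRate = 0)
    expect_equal(nrow(unique(evolveDiseaseHaplotypes(norec, 200))), 1L)

    # retention of the ancestral allele at the nearest marker decays
    # monotonically (in expectation) with generations
    ret <- vapply(c(0, 100, 1000), function(g) {
        m <- pm
        m@generations <- as.integer(g)
        nearest <- which.min(abs(m@positionsKb - m@diseasePosKb))
        h <- evolveDiseaseHaplotypes(m, 3000)
        mean(h[, nearest] == m@ancestralHap[nearest])
    }, numeric(1))
    expect_equal(ret[1], 1)
    expect_true(ret[2] >= ret[3] - 0.02)
})

test_that("simulated trios are Mendelian-consistent and reproducible", {
    set.seed(55)
    tg1 <- sampleAffectedTrios(populationModel(), diseaseScenario(), 60)
    expect_equal(nrow(checkMendelian(tg1)), 0L)
    set.seed(55)
    tg2 <- sampleAffectedTrios(populationModel(), diseaseScenario(), 60)
    expect_identical(tg1, tg2)

    set.seed(56)
    tgA <- sampleAffectedTrios(admixtureModel(),
                               diseaseScenario(effect = "joint"), 40)
    expect_equal(nrow(checkMendelian(tgA)), 0L)
    expect_equal(nTrios(tgA), 40L)
})

test_that("null scenarios transmit without bias and with mating symmetry", {
    set.seed(60)
    pm <- populationModel()
    tg <- sampleAffectedTrios(pm, diseaseScenario(R1 = 1, R2 = 1), 8000)
    d <- computeDiffVectors(tg)
    zx <- colMeans(d@X) / (apply(d@X, 2, sd) / sqrt(8000))
    zy <- colMeans(d@Y) / (apply(d@Y, 2, sd) / sqrt(8000))
    expect_true(all(abs(zx) < 4))
    expect_true(all(abs(zy) < 4))
    # (M, F) exchangeable: mother's and father's allele counts match in
    # distribution
    expect_lt(abs(mean(tg@M) - mean(tg@F)),
              4 * sd(tg@M - tg@F) / sqrt(length(tg@M)))
})

zScores <- function(m) {
    colMeans(m) / (apply(m, 2, sd) / sqrt(nrow(m)))
}

test_that("a maternal-only effect biases Y but not X", {
    set.seed(61)
    pm <- populationModel()
    tg <- sampleAffectedTrios(pm, diseaseScenario(effect = "maternal"), 4000)
    d <- computeDiffVectors(tg)
    expect_gt(max(abs(zScores(d@Y))), 4)   # markers in LD with D displaced
    expect_lt(max(abs(zScores(d@X))), 4.5) # transmission stays unbiased
})

test_that("a child effect biases transmissions (X) but not the parental contrast (Y)", {
    set.seed(62)
    pm <- populationModel()
    tg <- sampleAffectedTrios(pm, diseaseScenario(effect = "child"), 4000)
    d <- computeDiffVectors(tg)
    expect_gt(max(abs(zScores(d@X))), 4)
    expect_lt(max(abs(zScores(d@Y))), 4.5)
})

test_that("scenario construction rejects impossible penetrances", {
    expect_error(diseaseScenario(baseline = 0.4, R1 = 2, R2 = 3),
                 "penetrance")
    expect_error(diseaseScenario(baseline = 0.3, R1 = 2, R2 = 2,
                                 effect = "joint"), "penetrance")
    expect_silent(diseaseScenario(baseline = 0.2, R1 = 2, R2 = 2,
                                  effect = "child"))
})
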