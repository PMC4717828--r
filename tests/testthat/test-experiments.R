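test_that("rejection-rate boundaries: alpha = 1 rejects always, alpha = 0 only at p = 0", {
    cell <- runCell("null", N = 30, nReplicates = 8, nPermutations = 50,
                    seed = 42, nMarkers = 5, poolSize = 1000)
    rr <- rejectionRates(cell, alpha = 1)
    expect_true(all(rr$rate == 1))
    rr0 <- rejectionRates(cell, alpha = 1e-9)
    expect_equal(rr0$rate[rr0$statistic == "maxPC"],
                 mean(cell$pValues[, "maxPC"] == 0))
    expect_true(all(rr$se == sqrt(rr$rate * (1 - rr$rate) / 8)))
})

test_that("study cells are reproducible from the master seed", {
    c1 <- runCell("child", N = 30, nReplicates = 5, nPermutations = 50,
                  seed = 9, nMarkers = 5, poolSize = 1000)
    c2 <- runCell("child", N = 30, nReplicates = 5, nPermutations = 50,
                  seed = 9, nMarkers = 5, poolSize = 1000)
    expect_identical(c1$pValues, c2$pValues)
})

test_that("powerStudy stacks cells into a tidy table and summarizeStudy renders it", {
    res <- powerStudy(effects = "child", models = list(dominant = c(2, 2)),
                      Ns = 30, nReplicates = 4, nPermutations = 50,
                      seed = 2, nMarkers = 5, poolSize = 1000)
    expect_equal(nrow(res), 3)  # one row per statistic at one alpha
    expect_setequal(res$statistic, c("maxPC", "maxZ2assoc", "maxZ2maternal"))
    expect_true(all(res$rate >= 0 & res$rate <= 1))
    wide <- summarizeStudy(res, file = tempfile(fileext = ".tsv"))
    expect_equal(nrow(wide), 1)
    expect_true(all(c("maxPC", "maxZ2assoc") %in% names(wide)))

    empty <- res[0, ]
    expect_output(summarizeStudy(empty), "empty")
})
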