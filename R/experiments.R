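# Replicated simulation studies: type I error and power of max_PC and
# max_Z^2 under configurable disease scenarios, sample sizes and
# population structures. One master seed spawns deterministic
# per-replicate substreams (one for the data, one for the permutation
# flips), so results are reproducible and independent of execution
# order.

.STATS <- c("maxPC", "maxZ2assoc", "maxZ2maternal")

.oneReplicate <- function(effect, R1, R2, N, population, baseline,
                          nPermutations, simSeed, permSeed, ...) {
    set.seed(simSeed)
    scenario <- if (effect == "null")
        diseaseScenario(baseline = baseline, R1 = 1, R2 = 1,
                        effect = "child")
    else
        diseaseScenario(baseline = baseline, R1 = R1, R2 = R2,
                        effect = effect)
    model <- if (population == "admixed") admixtureModel(...)
             else populationModel(...)
    trios <- sampleAffectedTrios(model, scenario, N)
    diffs <- computeDiffVectors(trios)
    plan <- permutationPlan(nPermutations, N, permSeed)
    res <- .permAll(diffs, plan)
    vapply(.STATS, function(s)
        .permPValue(res$observed[[s]]@maxStat, res$nulls[[s]]),
        numeric(1))
}

#' Run one simulation-study cell
#'
#' Simulates `nReplicates` independent datasets of `N` case-parent trios
#' under one scenario cell (effect channel, relative risks, population
#' structure), computes the permutation p-value of max_PC, max_Z^2 on
#' X = 2C - F - M and max_Z^2 on Y = M - F for each dataset (all three
#' share each dataset's flip matrix), and returns the p-values. The
#' region model (marker frequencies, LD, disease position, founder
#' haplotype) is redrawn for every replicate. A replicate that fails is
#' retried on a fresh substream (at most 5 times) with a message.
#'
#' @param effect `"null"` (R1 = R2 = 1), `"child"`, `"maternal"` or
#'   `"joint"`.
#' @param R1,R2 relative risks (ignored under `"null"`); dominant
#'   R1 = R2 = 2, recessive R1 = 1, R2 = 2.
#' @param N trios per replicate.
#' @param population `"homogeneous"` or `"admixed"` (30/70 two-way
#'   admixture, see [admixtureModel()]).
#' @param nReplicates,nPermutations study scale; 1,000 replicates x 500
#'   permutations is the desk-scale profile, 10,000 x 1,000 the
#'   full-scale one.
#' @param seed master seed for the cell.
#' @param baseline baseline risk for the homogeneous population (the
#'   admixed one uses its per-subpopulation baselines).
#' @param verbose message progress every 100 replicates.
#' @param ... further arguments to [populationModel()] (e.g. `nMarkers`,
#'   `poolSize`, `recombRate`).
#' @return A list with `pValues` (matrix nReplicates x 3, columns
#'   `maxPC`, `maxZ2assoc`, `maxZ2maternal`) and `config` (the cell
#'   parameters), of class `"triadPCCell"`.
#' @seealso [rejectionRates()], [powerStudy()]
#' @export
runCell <- function(effect = c("null", "child", "maternal", "joint"),
                    R1 = 2, R2 = 2, N = 100,
                    population = c("homogeneous", "admixed"),
                    nReplicates = 1000, nPermutations = 500, seed = 1,
                    baseline = 0.01, verbose = FALSE, ...) {
    effect <- match.arg(effect)
    population <- match.arg(population)
    stopifnot(nReplicates >= 1, nPermutations >= 1)
    set.seed(seed)
    simSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
    permSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
    p <- matrix(NA_real_, nReplicates, 3L,
                dimnames = list(NULL, .STATS))
    for (i in seq_len(nReplicates)) {
        for (try in 0:4) {
            res <- tryCatch(
                .oneReplicate(effect, R1, R2, N, population, baseline,
                              nPermutations,
                              simSeed = (simSeeds[i] + try * 1000003L) %%
                                  .Machine$integer.max,
                              permSeed = permSeeds[i], ...),
                error = function(e) e)
            if (!inherits(res, "error")) break
            message("replicate ", i, " failed (", conditionMessage(res),
                    "); retrying on a fresh substream")
        }
        if (inherits(res, "error")) stop(res)
        p[i, ] <- res
        if (verbose && i %% 100 == 0)
            message("  replicate ", i, "/", nReplicates)
    }
    structure(list(pValues = p,
                   config = list(effect = effect, R1 = R1, R2 = R2, N = N,
                                 population = population,
                                 nReplicates = nReplicates,
                                 nPermutations = nPermutations,
                                 seed = seed, baseline = baseline)),
              class = "triadPCCell")
}

#' Rejection rates of a study cell
#'
#' The estimated power (or type I error, under the null cell) at each
#' significance level: the proportion of replicates with permutation
#' p-value <= alpha, with its binomial Monte-Carlo standard error.
#'
#' @param cell a `"triadPCCell"` from [runCell()].
#' @param alpha significance levels (default 0.05, 0.01, 0.001).
#' @return A data.frame with columns `statistic`, `alpha`, `rate`, `se`,
#'   `nReplicates`.
#' @export
rejectionRates <- function(cell, alpha = c(0.05, 0.01, 0.001)) {
    stopifnot(inherits(cell, "triadPCCell"), all(alpha > 0 & alpha <= 1))
    R <- nrow(cell$pValues)
    out <- expand.grid(statistic = colnames(cell$pValues), alpha = alpha,
                       stringsAsFactors = FALSE)
    out$rate <- mapply(function(s, a) mean(cell$pValues[, s] <= a),
                       out$statistic, out$alpha)
    out$se <- sqrt(out$rate * (1 - out$rate) / R)
    out$nReplicates <- R
    out
}

#' Run a grid of simulation-study cells
#'
#' Crosses the requested effect channels, relative-risk models, sample
#' sizes and population structures, runs [runCell()] on each and stacks
#' the rejection rates into one tidy table.
#'
#' @param effects,populations character vectors of cells to run.
#' @param models named list of `c(R1, R2)` pairs (default dominant and
#'   recessive).
#' @param Ns trio counts.
#' @param alpha significance levels.
#' @inheritParams runCell
#' @return A data.frame with one row per (cell, statistic, alpha):
#'   columns `effect`, `model`, `R1`, `R2`, `N`, `population`,
#'   `statistic`, `alpha`, `rate`, `se`, `nReplicates`.
#' @export
powerStudy <- function(effects = c("child", "maternal", "joint"),
                       models = list(dominant = c(2, 2),
                                     recessive = c(1, 2)),
                       Ns = 100,
                       populations = "homogeneous",
                       nReplicates = 1000, nPermutations = 500,
                       alpha = 0.05, seed = 1, verbose = FALSE, ...) {
    grid <- expand.grid(effect = effects, model = names(models), N = Ns,
                        population = populations,
                        stringsAsFactors = FALSE)
    out <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
        rr <- models[[grid$model[g]]]
        if (verbose)
            message("cell ", g, "/", nrow(grid), ": ", grid$effect[g],
                    " ", grid$model[g], " N=", grid$N[g], " ",
                    grid$population[g])
        cell <- runCell(effect = grid$effect[g], R1 = rr[1L], R2 = rr[2L],
                        N = grid$N[g], population = grid$population[g],
                        nReplicates = nReplicates,
                        nPermutations = nPermutations,
                        seed = seed + g, verbose = verbose, ...)
        rates <- rejectionRates(cell, alpha)
        out[[g]] <- cbind(grid[rep(g, nrow(rates)), , drop = FALSE],
                          R1 = rr[1L], R2 = rr[2L], rates,
                          row.names = NULL)
    }
    do.call(rbind, out)
}

#' Format a study table
#'
#' Renders the tidy table from [powerStudy()] (or a stack of
#' [rejectionRates()] outputs) as a fixed-layout text table - one row
#' per cell, one column per statistic - and optionally writes the tidy
#' version to a TSV file.
#'
#' @param results data.frame from [powerStudy()].
#' @param file optional path for a TSV copy of `results`.
#' @return The wide data.frame, invisibly; prints the formatted table.
#' @export
summarizeStudy <- function(results, file = NULL) {
    if (!is.null(file))
        write.table(results, file, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!nrow(results)) {
        cat("(empty study)\n")
        return(invisible(results))
    }
    key <- c("effect", "model", "N", "population", "alpha")
    key <- key[key %in% names(results)]
    wide <- stats::reshape(
        results[c(key, "statistic", "rate")],
        idvar = key, timevar = "statistic", direction = "wide")
    names(wide) <- sub("^rate\\.", "", names(wide))
    rownames(wide) <- NULL
    print(wide, digits = 3)
    invisible(wide)
}
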