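#' Draw a trio-level sign-flip permutation plan
#'
#' For each permutation and each trio, the case/complement labels are
#' swapped with probability 1/2 (negating that trio's X = 2C - F - M at
#' every locus, since the complement carries F + M - C copies) and,
#' independently, the mother/father labels are swapped with probability
#' 1/2 (negating Y = M - F). Both swaps together enforce the joint null
#' of no association and no maternally mediated genetic effect. Flips are
#' shared across loci within a trio, preserving the between-locus
#' correlation the max statistic must be calibrated against.
#'
#' @param nPermutations number of permutations (simulation studies here
#'   use 1,000 by default; 10,000 is typical for a single data analysis).
#' @param nTrios number of trios.
#' @param seed integer seed for the flip draws.
#' @return A [PermutationPlan-class] object.
#' @export
permutationPlan <- function(nPermutations, nTrios, seed) {
    stopifnot(nPermutations >= 1, nTrios >= 1)
    seed <- as.integer(seed)
    B <- as.integer(nPermutations)
    n <- as.integer(nTrios)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    fx <- matrix(1 - 2 * rbinom(B * n, 1L, 0.5), B, n)
    fy <- matrix(1 - 2 * rbinom(B * n, 1L, 0.5), B, n)
    new("PermutationPlan", nPermutations = B, nTrios = n, seed = seed,
        flipX = fx, flipY = fy)
}

#' @export
setMethod("show", "PermutationPlan", function(object) {
    cat("PermutationPlan:", object@nPermutations, "permutations x",
        object@nTrios, "trios (seed", object@seed, ")\n")
})

#' Permutation p-value for a max statistic
#'
#' Computes the observed statistic, recomputes it on every sign-flipped
#' dataset of the plan with identical conventions (same eigenvector
#' canonicalization, same per-locus complete-case masks, same usable
#' locus set), and returns the estimated p-value: the proportion of
#' permutation statistics strictly larger than the observed one. With
#' `addOneCorrection = TRUE` the small-sample estimate
#' (1 + #larger) / (B + 1) is used instead, which cannot be exactly zero.
#'
#' @param diffs a [DiffVectors-class] object.
#' @param statistic which max statistic to calibrate.
#' @param plan a [PermutationPlan-class] object with `nTrios` matching
#'   `diffs`.
#' @param addOneCorrection logical; default `FALSE` (strict proportion).
#' @param signConvention eigenvector sign convention, applied identically
#'   to observed and permuted data; the p-value is invariant to it.
#' @param verbose log progress every 100 permutations (the whole stack is
#'   evaluated vectorized, so this reports only the batch).
#' @return A [MaxStatResult-class] object with `pValue`, `nullStats`,
#'   `nPermutations` and `seed` filled in.
#' @export
permuteStat <- function(diffs,
                        statistic = c("maxPC", "maxZ2assoc", "maxZ2maternal"),
                        plan, addOneCorrection = FALSE,
                        signConvention = c("positive", "negative"),
                        verbose = FALSE) {
    stopifnot(is(diffs, "DiffVectors"), is(plan, "PermutationPlan"))
    statistic <- match.arg(statistic)
    signConvention <- match.arg(signConvention)
    if (plan@nTrios != nrow(diffs@X))
        stop("plan was drawn for ", plan@nTrios, " trios but data have ",
             nrow(diffs@X))
    res <- .permAll(diffs, plan, signConvention = signConvention,
                    verbose = verbose)
    obs <- res$observed[[statistic]]
    nulls <- res$nulls[[statistic]]
    p <- .permPValue(obs@maxStat, nulls, addOneCorrection)
    initialize(obs, pValue = p, nullStats = nulls,
               nPermutations = plan@nPermutations, seed = plan@seed)
}

.permPValue <- function(observed, nulls, addOneCorrection = FALSE) {
    larger <- sum(nulls > observed)
    if (addOneCorrection) (1 + larger) / (length(nulls) + 1)
    else larger / length(nulls)
}

# All three max statistics, observed and under every flip of the plan,
# sharing one vectorized pass. Returns list(observed = list of
# MaxStatResult, nulls = list of numeric(B)).
.permAll <- function(diffs, plan, signConvention = "positive",
                     verbose = FALSE) {
    n <- nrow(diffs@X)
    obs <- .flipStats(diffs, .identityFlips(n), .identityFlips(n),
                      signConvention = signConvention)
    if (!any(obs$usablePC))
        stop("no usable locus: every locus has fewer than 2 complete trios or no variation")
    if (verbose)
        message("evaluating ", plan@nPermutations,
                " permutations (vectorized, batches of 100)")
    perm <- .flipStats(diffs, plan@flipX, plan@flipY,
                       signConvention = signConvention)
    list(observed = list(
             maxPC = .newMaxStat("maxPC", drop(obs$pc), obs$n, obs$usablePC),
             maxZ2assoc = .newMaxStat("maxZ2assoc", drop(obs$z2x), obs$n,
                                      obs$usableZ),
             maxZ2maternal = .newMaxStat("maxZ2maternal", drop(obs$z2y),
                                         obs$n, obs$usableZ)),
         nulls = list(
             maxPC = .rowMax(perm$pc[, obs$usablePC, drop = FALSE]),
             maxZ2assoc = .rowMax(perm$z2x[, obs$usableZ, drop = FALSE]),
             maxZ2maternal = .rowMax(perm$z2y[, obs$usableZ, drop = FALSE])))
}
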