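# Forward trio simulator: first-order Markov marker haplotypes with
# adjacent-pair LD, a latent disease allele D introduced on a single
# founder haplotype and eroded by recombination, and rejection sampling
# of case-parent trios by affection status. All randomness comes from
# the R global RNG; seed with set.seed() for reproducibility.

#' Draw a realized population model
#'
#' Draws one candidate-region model: `nMarkers` evenly spaced markers
#' with allele frequencies uniform on `freqRange`, adjacent-pair
#' standardized disequilibrium D' uniform on `ldRange`, a disease locus
#' at a uniform position with allele frequency `diseaseFreq`, and a
#' founder ("ancestral") haplotype drawn from the same Markov model that
#' generates background haplotypes. Marker frequencies, LD and the
#' disease position are redrawn on every call, so replicated studies
#' average over region configurations.
#'
#' @param nMarkers number of marker loci (default 20).
#' @param regionKb region length in kb (default 100); markers sit at the
#'   centers of `nMarkers` equal bins.
#' @param freqRange range of the uniform marker-allele-frequency draw.
#' @param ldRange range of the uniform adjacent-pair D' draw; D' is
#'   converted to raw D through the Lewontin bound for each frequency
#'   pair, so any draw is feasible.
#' @param diseaseFreq population frequency of disease allele D.
#' @param generations generations since D arose on the founder haplotype.
#' @param recombRate recombination rate, Morgans per kb (default 1e-5,
#'   i.e. 1 cM/Mb, giving a 0.001 per-meiosis crossover probability
#'   across a 100 kb region; at most one crossover per meiosis).
#' @param poolSize present-day haplotype pool size (default 10,000).
#' @return A [PopulationModel-class] object.
#' @export
populationModel <- function(nMarkers = 20, regionKb = 100,
                            freqRange = c(0.1, 0.9),
                            ldRange = c(-0.9, 0.9),
                            diseaseFreq = 0.1, generations = 1000,
                            recombRate = 1e-5, poolSize = 10000) {
    q <- as.integer(nMarkers)
    freqs <- runif(q, freqRange[1L], freqRange[2L])
    dprime <- if (q > 1L) runif(q - 1L, ldRange[1L], ldRange[2L]) else numeric()
    pos <- (seq_len(q) - 0.5) * regionKb / q
    m <- new("PopulationModel", nMarkers = q, regionKb = regionKb,
             positionsKb = pos, markerFreqs = freqs, adjLd = dprime,
             diseasePosKb = runif(1L, 0, regionKb),
             diseaseFreq = diseaseFreq,
             ancestralHap = integer(q),
             generations = as.integer(generations),
             recombRate = recombRate, poolSize = as.integer(poolSize))
    m@ancestralHap <- as.integer(drop(.markovHaplotypes(m, 1L)))
    m
}

#' @export
setMethod("show", "PopulationModel", function(object) {
    cat("PopulationModel:", object@nMarkers, "markers over",
        object@regionKb, "kb\n")
    cat(sprintf("  disease allele D: freq %.2f at %.1f kb, introduced %d generations ago\n",
                object@diseaseFreq, object@diseasePosKb,
                object@generations))
})

#' Disease penetrance scenario
#'
#' @param baseline penetrance of the no-copy genotype dd (default 0.01).
#' @param R1,R2 relative risks for one and two copies of D (default
#'   dominant, R1 = R2 = 2; a recessive model is R1 = 1, R2 = 2; the
#'   null is R1 = R2 = 1).
#' @param effect channel of the genotype effect: the child's genotype
#'   (`"child"`, association), the mother's (`"maternal"`), or the
#'   product of both relative risks (`"joint"`).
#' @return A [DiseaseScenario-class] object; construction fails if any
#'   penetrance would exceed 1.
#' @export
diseaseScenario <- function(baseline = 0.01, R1 = 2, R2 = 2,
                            effect = c("child", "maternal", "joint")) {
    effect <- match.arg(effect)
    new("DiseaseScenario", baseline = baseline, R1 = R1, R2 = R2,
        effect = effect)
}

#' @export
setMethod("show", "DiseaseScenario", function(object) {
    cat(sprintf("DiseaseScenario: %s effect, baseline %.3g, R1 = %g, R2 = %g\n",
                object@effect, object@baseline, object@R1, object@R2))
})

#' Two-subpopulation admixture model
#'
#' Defaults follow the stratification setting used in the simulation
#' study: disease-allele frequencies 0.1 and 0.2, D introduced 1,000 and
#' 500 generations ago on different founder haplotypes, baseline risks
#' 0.01 and 0.05, and 30/70 mixing applied at the last generation (each
#' trio's parents both come from one subpopulation).
#'
#' @param pop1,pop2 [PopulationModel-class] objects (fresh draws by
#'   default).
#' @param mixing mixing proportions (default `c(0.3, 0.7)`).
#' @param baselines per-subpopulation baseline risks (default
#'   `c(0.01, 0.05)`), overriding the scenario baseline.
#' @param ... passed to [populationModel()] for the default draws.
#' @return An [AdmixtureModel-class] object.
#' @export
admixtureModel <- function(pop1 = populationModel(diseaseFreq = 0.1,
                                                  generations = 1000, ...),
                           pop2 = populationModel(diseaseFreq = 0.2,
                                                  generations = 500, ...),
                           mixing = c(0.3, 0.7),
                           baselines = c(0.01, 0.05), ...) {
    new("AdmixtureModel", pop1 = pop1, pop2 = pop2, mixing = mixing,
        baselines = baselines)
}

#' @export
setMethod("show", "AdmixtureModel", function(object) {
    cat(sprintf("AdmixtureModel: mixing %.0f%%/%.0f%%, baselines %.3g/%.3g\n",
                100 * object@mixing[1L], 100 * object@mixing[2L],
                object@baselines[1L], object@baselines[2L]))
})

# Lewontin conversion: standardized D' -> raw D for adjacent pair
# frequencies p (left) and r (right).
.dprimeToD <- function(dprime, p, r) {
    dmax <- ifelse(dprime >= 0,
                   pmin(p * (1 - r), (1 - p) * r),
                   pmin(p * r, (1 - p) * (1 - r)))
    dprime * dmax
}

# n background haplotypes from the first-order Markov chain over markers.
.markovHaplotypes <- function(model, n) {
    q <- model@nMarkers
    p <- model@markerFreqs
    hap <- matrix(0L, n, q)
    hap[, 1L] <- rbinom(n, 1L, p[1L])
    for (l in seq_len(q - 1L)) {
        D <- .dprimeToD(model@adjLd[l], p[l], p[l + 1L])
        pa <- min(max(p[l + 1L] + D / p[l], 0), 1)          # P(A | A)
        pb <- min(max(p[l + 1L] - D / (1 - p[l]), 0), 1)    # P(A | a)
        prev <- hap[, l]
        hap[, l + 1L] <- rbinom(n, 1L, ifelse(prev == 1L, pa, pb))
    }
    hap
}

#' Sample background marker haplotypes
#'
#' Haplotypes are generated left to right by a first-order Markov chain:
#' the first marker is Bernoulli with its allele frequency, and each
#' subsequent marker is drawn from the conditional distribution implied
#' by its frequency and the raw adjacent-pair disequilibrium D
#' (P(A_next | A) = p_next + D/p, P(A_next | a) = p_next - D/(1 - p)),
#' with D obtained from the model's standardized D' via the Lewontin
#' bound.
#'
#' @param model a [PopulationModel-class] object.
#' @param n number of haplotypes.
#' @return An `n x nMarkers` 0/1 matrix (1 = allele "A").
#' @export
sampleMarkerHaplotypes <- function(model, n) {
    stopifnot(is(model, "PopulationModel"), n >= 1)
    .markovHaplotypes(model, as.integer(n))
}

#' Sample present-day disease-bearing haplotypes
#'
#' Each D-bearing haplotype descends from the founder haplotype through
#' `generations` meioses; in each meiosis a single crossover occurs with
#' probability `recombRate * regionKb` at a uniform position, replacing
#' the markers on the side away from the disease locus with a fresh
#' background haplotype. With `generations = 0` (or a zero recombination
#' rate) every haplotype equals the founder.
#'
#' @param model a [PopulationModel-class] object.
#' @param n number of haplotypes.
#' @return An `n x nMarkers` 0/1 matrix.
#' @export
evolveDiseaseHaplotypes <- function(model, n) {
    stopifnot(is(model, "PopulationModel"), n >= 1)
    n <- as.integer(n)
    q <- model@nMarkers
    pos <- model@positionsKb
    hap <- matrix(rep(model@ancestralHap, each = n), n, q)
    rMeiosis <- model@recombRate * model@regionKb
    K <- rbinom(n, model@generations, rMeiosis)
    j <- 1L
    while (any(K >= j)) {
        act <- which(K >= j)
        m <- length(act)
        bp <- runif(m, 0, model@regionKb)
        bg <- .markovHaplotypes(model, m)
        P <- matrix(pos, m, q, byrow = TRUE)
        # keep the side carrying the disease locus from the D lineage
        repl <- ifelse(model@diseasePosKb >= bp, P < bp, P >= bp)
        sub <- hap[act, , drop = FALSE]
        sub[repl] <- bg[repl]
        hap[act, ] <- sub
        j <- j + 1L
    }
    hap
}

# Present-day haplotype pool: markers plus the latent D allele.
.buildPool <- function(model) {
    nD <- max(1L, as.integer(round(model@poolSize * model@diseaseFreq)))
    nB <- model@poolSize - nD
    list(mark = rbind(evolveDiseaseHaplotypes(model, nD),
                      .markovHaplotypes(model, nB)),
         d = c(rep(1L, nD), rep(0L, nB)))
}

# Transmit one haplotype from parents with haplotype-pair indices
# (i1, i2) into pool rows; single crossover with the per-meiosis
# probability. Returns the transmitted marker haplotypes and D alleles.
.transmit <- function(pool, i1, i2, model) {
    B <- length(i1)
    pick <- runif(B) < 0.5
    src <- ifelse(pick, i1, i2)
    oth <- ifelse(pick, i2, i1)
    hap <- pool$mark[src, , drop = FALSE]
    d <- pool$d[src]
    rec <- which(runif(B) < model@recombRate * model@regionKb)
    if (length(rec)) {
        q <- model@nMarkers
        bp <- runif(length(rec), 0, model@regionKb)
        P <- matrix(model@positionsKb, length(rec), q, byrow = TRUE)
        right <- P >= bp                    # markers right of the crossover
        sub <- hap[rec, , drop = FALSE]
        othHap <- pool$mark[oth[rec], , drop = FALSE]
        sub[right] <- othHap[right]
        hap[rec, ] <- sub
        d[rec] <- ifelse(model@diseasePosKb >= bp, pool$d[oth[rec]], d[rec])
    }
    list(mark = hap, d = d)
}

# One batch of candidate trios from one pool; returns genotype matrices
# and the latent D-genotypes used by the penetrance model.
.candidateTrios <- function(pool, model, B) {
    N <- nrow(pool$mark)
    i <- matrix(sample.int(N, 4L * B, replace = TRUE), B, 4L)
    tm <- .transmit(pool, i[, 1L], i[, 2L], model)
    tf <- .transmit(pool, i[, 3L], i[, 4L], model)
    list(M = pool$mark[i[, 1L], , drop = FALSE] + pool$mark[i[, 2L], , drop = FALSE],
         F = pool$mark[i[, 3L], , drop = FALSE] + pool$mark[i[, 4L], , drop = FALSE],
         C = tm$mark + tf$mark,
         Md = pool$d[i[, 1L]] + pool$d[i[, 2L]],
         Cd = tm$d + tf$d)
}

.affectionProb <- function(cand, scenario, baseline) {
    rr <- c(1, scenario@R1, scenario@R2)
    switch(scenario@effect,
           child = baseline * rr[cand$Cd + 1L],
           maternal = baseline * rr[cand$Md + 1L],
           joint = baseline * rr[cand$Cd + 1L] * rr[cand$Md + 1L])
}

#' Sample case-parent trios ascertained through an affected child
#'
#' @description
#' Repeatedly draws parental haplotype pairs from the present-day pool,
#' forms the child by transmitting one (possibly recombined) haplotype
#' from each parent, assigns affection status from the penetrance model
#' (child's, mother's, or both latent D genotypes), and retains trios
#' with an affected child until `nTrios` are collected. The disease
#' locus itself is latent: only the marker genotypes are reported, as
#' counts of allele "A".
#'
#' Under an [AdmixtureModel-class], each trio's parents are drawn from
#' one subpopulation chosen with the mixing proportions, and that
#' subpopulation's baseline risk replaces the scenario baseline.
#'
#' @param model a [PopulationModel-class] or [AdmixtureModel-class]
#'   object.
#' @param scenario a [DiseaseScenario-class] object.
#' @param nTrios number of trios to collect.
#' @return A [TrioGenotypes-class] object with `nTrios` rows.
#' @examples
#' set.seed(7)
#' pm <- populationModel()
#' tg <- sampleAffectedTrios(pm, diseaseScenario(effect = "child"), 50)
#' tg
#' @export
setGeneric("sampleAffectedTrios",
           function(model, scenario, nTrios) standardGeneric("sampleAffectedTrios"))

.collectTrios <- function(draw, nTrios) {
    M <- NULL; F <- NULL; C <- NULL
    got <- 0L
    while (got < nTrios) {
        cand <- draw()
        keep <- which(cand$affected)
        if (length(keep)) {
            M <- rbind(M, cand$M[keep, , drop = FALSE])
            F <- rbind(F, cand$F[keep, , drop = FALSE])
            C <- rbind(C, cand$C[keep, , drop = FALSE])
            got <- nrow(M)
        }
    }
    idx <- seq_len(nTrios)
    trioGenotypes(M[idx, , drop = FALSE], F[idx, , drop = FALSE],
                  C[idx, , drop = FALSE])
}

#' @rdname sampleAffectedTrios
#' @export
setMethod("sampleAffectedTrios", signature(model = "PopulationModel"),
    function(model, scenario, nTrios) {
        stopifnot(is(scenario, "DiseaseScenario"), nTrios >= 1)
        pool <- .buildPool(model)
        batch <- min(50000L, as.integer(ceiling(1.3 * nTrios / scenario@baseline)))
        .collectTrios(function() {
            cand <- .candidateTrios(pool, model, batch)
            cand$affected <- runif(batch) <
                .affectionProb(cand, scenario, scenario@baseline)
            cand
        }, nTrios)
    })

#' @rdname sampleAffectedTrios
#' @export
setMethod("sampleAffectedTrios", signature(model = "AdmixtureModel"),
    function(model, scenario, nTrios) {
        stopifnot(is(scenario, "DiseaseScenario"), nTrios >= 1)
        pool1 <- .buildPool(model@pop1)
        pool2 <- .buildPool(model@pop2)
        baseMean <- sum(model@mixing * model@baselines)
        batch <- min(50000L, as.integer(ceiling(1.3 * nTrios / baseMean)))
        .collectTrios(function() {
            k2 <- runif(batch) < model@mixing[2L]
            n2 <- sum(k2)
            n1 <- batch - n2
            parts <- list()
            if (n1) {
                cand <- .candidateTrios(pool1, model@pop1, n1)
                cand$affected <- runif(n1) <
                    .affectionProb(cand, scenario, model@baselines[1L])
                parts <- c(parts, list(cand))
            }
            if (n2) {
                cand <- .candidateTrios(pool2, model@pop2, n2)
                cand$affected <- runif(n2) <
                    .affectionProb(cand, scenario, model@baselines[2L])
                parts <- c(parts, list(cand))
            }
            list(M = do.call(rbind, lapply(parts, `[[`, "M")),
                 F = do.call(rbind, lapply(parts, `[[`, "F")),
                 C = do.call(rbind, lapply(parts, `[[`, "C")),
                 affected = unlist(lapply(parts, `[[`, "affected")))
        }, nTrios)
    })
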