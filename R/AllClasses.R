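#' @import methods
#' @importFrom stats runif rbinom cov pchisq var setNames
#' @importFrom utils read.table write.table
NULL

.MISSING_OK <- function(m) all(is.na(m) | (m %in% 0:2))

#' Case-parent trio genotypes at multiple biallelic SNPs
#'
#' Container for minor-allele counts carried by the mother, father and
#' affected child of each case-parent trio, at each of a set of biallelic
#' marker loci. Counts are 0, 1 or 2 copies of the counted allele; `NA`
#' marks a missing genotype call. A (trio, locus) cell is *complete* when
#' all three members are non-missing there; all downstream statistics are
#' per-locus complete-case.
#'
#' @slot M,F,C integer matrices (trios x loci) of allele counts for the
#'   mother, father and affected child.
#' @slot snpId character vector of locus identifiers (length = number of
#'   loci).
#'
#' @seealso [trioGenotypes()] for construction, [computeDiffVectors()],
#'   [checkMendelian()], [sampleAffectedTrios()].
#' @export
setClass("TrioGenotypes",
    representation(M = "matrix", F = "matrix", C = "matrix",
                   snpId = "character"),
    validity = function(object) {
        msg <- character()
        d <- dim(object@M)
        if (!identical(d, dim(object@F)) || !identical(d, dim(object@C)))
            msg <- c(msg, "M, F and C must have identical dimensions")
        if (length(object@snpId) != ncol(object@M))
            msg <- c(msg, "snpId length must equal the number of loci")
        if (!.MISSING_OK(object@M) || !.MISSING_OK(object@F) ||
            !.MISSING_OK(object@C))
            msg <- c(msg, "genotype counts must be in {0, 1, 2} or NA")
        if (length(msg)) msg else TRUE
    })

#' Per-trio genotype difference vectors
#'
#' Holds, for every trio and locus, the association difference
#' X = 2C - F - M (affected child versus the untransmitted "complement")
#' and the maternal difference Y = M - F (mother versus father, her
#' matched control under mating symmetry). The pair Z = (X, Y)' is the
#' bivariate observation the PC statistic operates on. `complete` marks
#' the cells where all three genotypes were observed; X and Y are 0 and
#' ignored elsewhere.
#'
#' @slot X,Y numeric matrices (trios x loci); X in [-4, 4], Y in [-2, 2]
#'   on complete cells, 0 elsewhere.
#' @slot complete logical matrix (trios x loci).
#' @slot snpId character vector of locus identifiers.
#'
#' @seealso [computeDiffVectors()], [maxPC()], [maxZ2()], [permuteStat()]
#' @export
setClass("DiffVectors",
    representation(X = "matrix", Y = "matrix", complete = "matrix",
                   snpId = "character"),
    validity = function(object) {
        msg <- character()
        d <- dim(object@X)
        if (!identical(d, dim(object@Y)) || !identical(d, dim(object@complete)))
            msg <- c(msg, "X, Y and complete must have identical dimensions")
        if (length(object@snpId) != ncol(object@X))
            msg <- c(msg, "snpId length must equal the number of loci")
        cc <- object@complete
        if (any(abs(object@X[cc]) > 4) || any(abs(object@Y[cc]) > 2))
            msg <- c(msg, "X must lie in [-4, 4] and Y in [-2, 2]")
        if (length(msg)) msg else TRUE
    })

#' Single-locus principal-component statistic
#'
#' Result of the PC computation at one locus: the sample covariance
#' matrix S of Z = (X, Y)', its eigenpairs (lambda1 >= lambda2 >= 0,
#' unit eigenvectors canonicalized so the first nonzero component is
#' positive), the sample principal-component means zetaBar_k = e_k' Zbar,
#' and the statistic PC = n (zetaBar_1 + zetaBar_2)^2 / (lambda1 + lambda2),
#' asymptotically chi-square with 1 df under the joint null of no
#' association and no maternal effect.
#'
#' @slot nComplete integer, trios with complete data at this locus.
#' @slot S 2x2 sample covariance matrix of (X, Y).
#' @slot lambda numeric(2), eigenvalues in decreasing order.
#' @slot vectors 2x2 matrix whose columns are the canonical unit
#'   eigenvectors e1, e2.
#' @slot zetaBar numeric(2), means of the two sample principal components.
#' @slot pc the PC statistic (0 for a degenerate locus).
#' @slot degenerate logical, TRUE when lambda1 + lambda2 = 0 (the locus
#'   carries no variation hence no evidence).
#'
#' @seealso [locusPC()]
#' @export
setClass("LocusPC",
    representation(nComplete = "integer", S = "matrix", lambda = "numeric",
                   vectors = "matrix", zetaBar = "numeric", pc = "numeric",
                   degenerate = "logical"))

#' Maximum-over-loci test result
#'
#' Per-locus statistic values (PC or Z^2), their maximum across usable
#' loci, the index of the maximizing locus, and - once a permutation run
#' has been attached - the permutation p-value and null statistics.
#'
#' @slot statistic one of "maxPC", "maxZ2assoc", "maxZ2maternal".
#' @slot perLocus numeric vector of per-locus values; NA for unusable
#'   loci (too few complete trios, or degenerate for the PC max).
#' @slot nComplete integer vector of per-locus complete-trio counts.
#' @slot maxStat the maximum over usable loci.
#' @slot argmax integer index of the maximizing locus (lowest index on
#'   ties).
#' @slot pValue permutation p-value, NA until permutation is run.
#' @slot nullStats numeric vector of permutation statistics (may be
#'   empty).
#' @slot nPermutations,seed provenance of the permutation run.
#'
#' @seealso [maxPC()], [maxZ2()], [permuteStat()]
#' @export
setClass("MaxStatResult",
    representation(statistic = "character", perLocus = "numeric",
                   nComplete = "integer", maxStat = "numeric",
                   argmax = "integer", pValue = "numeric",
                   nullStats = "numeric", nPermutations = "integer",
                   seed = "integer"))

#' Trio-level sign-flip permutation plan
#'
#' Pre-drawn label swaps for a permutation run. Each permutation flips,
#' per trio, the case/complement labels (negating X, since the
#' complement's count is F + M - C) and, independently, the
#' mother/father labels (negating Y), each with probability 1/2. Flips
#' are trio-level - shared across all loci of the trio - so the
#' between-locus correlation that the max statistic exploits is
#' preserved in the permutation null.
#'
#' @slot nPermutations,nTrios,seed integers.
#' @slot flipX,flipY numeric matrices (permutations x trios) with
#'   entries +1/-1.
#'
#' @seealso [permutationPlan()], [permuteStat()]
#' @export
setClass("PermutationPlan",
    representation(nPermutations = "integer", nTrios = "integer",
                   seed = "integer", flipX = "matrix", flipY = "matrix"),
    validity = function(object) {
        msg <- character()
        d <- c(object@nPermutations, object@nTrios)
        if (!identical(dim(object@flipX), as.integer(d)) ||
            !identical(dim(object@flipY), as.integer(d)))
            msg <- c(msg, "flip matrices must be nPermutations x nTrios")
        if (!all(object@flipX %in% c(-1, 1)) ||
            !all(object@flipY %in% c(-1, 1)))
            msg <- c(msg, "flips must be +1 or -1")
        if (length(msg)) msg else TRUE
    })

#' Realized population model for the trio simulator
#'
#' One draw of the candidate-region population model: q markers evenly
#' spaced across a region, per-marker allele frequencies, standardized
#' disequilibrium coefficients D' between adjacent markers (converted to
#' raw D through the Lewontin bound when haplotypes are generated), a
#' latent biallelic disease locus at a uniform position, and a single
#' founder ("ancestral") haplotype on which the disease allele D arose a
#' given number of generations ago.
#'
#' @slot nMarkers number of marker loci emitted (disease locus excluded).
#' @slot regionKb region length in kb; markers at the centers of equal
#'   bins.
#' @slot positionsKb marker positions (kb).
#' @slot markerFreqs per-marker frequency of the counted allele "A".
#' @slot adjLd standardized disequilibrium D' for each adjacent marker
#'   pair (length nMarkers - 1).
#' @slot diseasePosKb position of the latent disease locus.
#' @slot diseaseFreq population frequency of disease allele D.
#' @slot ancestralHap 0/1 marker alleles of the founder D haplotype.
#' @slot generations generations since D arose (haplotype decay time).
#' @slot recombRate recombination rate in Morgans per kb (default 1
#'   cM/Mb = 1e-5 M/kb; at most one crossover per meiosis across the
#'   region).
#' @slot poolSize present-day haplotype pool size used for trio sampling.
#'
#' @seealso [populationModel()], [sampleMarkerHaplotypes()],
#'   [evolveDiseaseHaplotypes()], [sampleAffectedTrios()]
#' @export
setClass("PopulationModel",
    representation(nMarkers = "integer", regionKb = "numeric",
                   positionsKb = "numeric", markerFreqs = "numeric",
                   adjLd = "numeric", diseasePosKb = "numeric",
                   diseaseFreq = "numeric", ancestralHap = "integer",
                   generations = "integer", recombRate = "numeric",
                   poolSize = "integer"),
    validity = function(object) {
        msg <- character()
        q <- object@nMarkers
        if (length(object@markerFreqs) != q ||
            length(object@positionsKb) != q ||
            length(object@ancestralHap) != q)
            msg <- c(msg, "markerFreqs, positionsKb, ancestralHap must have length nMarkers")
        if (length(object@adjLd) != q - 1L)
            msg <- c(msg, "adjLd must have length nMarkers - 1")
        if (any(object@markerFreqs <= 0) || any(object@markerFreqs >= 1))
            msg <- c(msg, "marker frequencies must lie in (0, 1)")
        if (any(abs(object@adjLd) > 1))
            msg <- c(msg, "|adjLd| must be <= 1")
        if (object@diseaseFreq <= 0 || object@diseaseFreq >= 1)
            msg <- c(msg, "diseaseFreq must lie in (0, 1)")
        if (object@generations < 0L)
            msg <- c(msg, "generations must be >= 0")
        if (length(msg)) msg else TRUE
    })

#' Penetrance model for the simulated disease
#'
#' Penetrance of the genotype with no copies of the disease allele D
#' (`baseline`), relative risks R1 and R2 for one and two copies, and
#' the channel through which genotype acts on the child's affection
#' status: the child's own D genotype (`"child"`), the mother's
#' (`"maternal"`), or their product (`"joint"`, multiplicative).
#'
#' @slot baseline penetrance of genotype dd, in (0, 1).
#' @slot R1,R2 relative risks for 1 and 2 copies of D (dominant model
#'   R1 = R2; recessive model R1 = 1).
#' @slot effect "child", "maternal" or "joint".
#'
#' @seealso [diseaseScenario()], [sampleAffectedTrios()]
#' @export
setClass("DiseaseScenario",
    representation(baseline = "numeric", R1 = "numeric", R2 = "numeric",
                   effect = "character"),
    validity = function(object) {
        msg <- character()
        if (object@baseline <= 0 || object@baseline >= 1)
            msg <- c(msg, "baseline must lie in (0, 1)")
        if (object@R1 < 0 || object@R2 < 0)
            msg <- c(msg, "relative risks must be >= 0")
        if (!object@effect %in% c("child", "maternal", "joint"))
            msg <- c(msg, "effect must be 'child', 'maternal' or 'joint'")
        rmax <- max(1, object@R1, object@R2)
        pen <- object@baseline * if (object@effect == "joint") rmax^2 else rmax
        if (pen > 1)
            msg <- c(msg, "maximum penetrance exceeds 1")
        if (length(msg)) msg else TRUE
    })

#' Two-subpopulation admixture model
#'
#' Two independently parameterized subpopulations (their own marker
#' frequencies, LD draws, disease-allele frequencies, founder haplotypes
#' and decay times, and baseline risks) admixed at the last generation:
#' each trio's parents are drawn from one subpopulation, chosen with the
#' mixing proportions (mating within subpopulation, the classic
#' stratification setting family-based tests must tolerate).
#'
#' @slot pop1,pop2 [PopulationModel-class] objects.
#' @slot mixing numeric(2) mixing proportions, summing to 1.
#' @slot baselines numeric(2) per-subpopulation baseline risks
#'   (overriding the scenario baseline).
#'
#' @seealso [admixtureModel()], [sampleAffectedTrios()]
#' @export
setClass("AdmixtureModel",
    representation(pop1 = "PopulationModel", pop2 = "PopulationModel",
                   mixing = "numeric", baselines = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@mixing) != 2L ||
            abs(sum(object@mixing) - 1) > 1e-12 || any(object@mixing < 0))
            msg <- c(msg, "mixing must be two nonnegative proportions summing to 1")
        if (length(object@baselines) != 2L ||
            any(object@baselines <= 0) || any(object@baselines >= 1))
            msg <- c(msg, "baselines must be two risks in (0, 1)")
        if (length(msg)) msg else TRUE
    })
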