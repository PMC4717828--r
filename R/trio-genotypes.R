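#' Construct a TrioGenotypes object
#'
#' @param M,F,C matrices (trios x loci) of counted-allele copy numbers
#'   (0/1/2) for mother, father and affected child; `NA` = missing call.
#' @param snpId optional locus identifiers; defaults to the column names
#'   of `C` or `snp1 ... snpq`.
#' @return A [TrioGenotypes-class] object.
#' @examples
#' tg <- trioGenotypes(M = matrix(2), F = matrix(0), C = matrix(1))
#' motherGenotypes(tg)
#' @export
trioGenotypes <- function(M, F, C, snpId = NULL) {
    M <- as.matrix(M); F <- as.matrix(F); C <- as.matrix(C)
    if (is.null(snpId))
        snpId <- colnames(C)
    if (is.null(snpId))
        snpId <- paste0("snp", seq_len(ncol(C)))
    storage.mode(M) <- "integer"
    storage.mode(F) <- "integer"
    storage.mode(C) <- "integer"
    dimnames(M) <- dimnames(F) <- dimnames(C) <- NULL
    .newTrioGenotypes(M, F, C, as.character(snpId))
}

# new() cannot take a slot literally named "C" (it partially matches its
# Class argument), so build by slot assignment.
.newTrioGenotypes <- function(M, F, C, snpId) {
    obj <- new("TrioGenotypes")
    obj@M <- M
    obj@F <- F
    obj@C <- C
    obj@snpId <- snpId
    validObject(obj)
    obj
}

#' @describeIn trioGenotypes Number of trios.
#' @param x a `TrioGenotypes` object.
#' @export
nTrios <- function(x) nrow(x@M)

#' @describeIn trioGenotypes Number of marker loci.
#' @export
nLoci <- function(x) ncol(x@M)

#' @describeIn trioGenotypes Locus identifiers.
#' @export
snpIds <- function(x) x@snpId

#' @describeIn trioGenotypes Mother's allele-count matrix.
#' @export
motherGenotypes <- function(x) x@M

#' @describeIn trioGenotypes Father's allele-count matrix.
#' @export
fatherGenotypes <- function(x) x@F

#' @describeIn trioGenotypes Affected child's allele-count matrix.
#' @export
childGenotypes <- function(x) x@C

#' @export
setMethod("show", "TrioGenotypes", function(object) {
    miss <- mean(is.na(object@M) | is.na(object@F) | is.na(object@C))
    cat("TrioGenotypes:", nTrios(object), "case-parent trios x",
        nLoci(object), "loci\n")
    cat(sprintf("  incomplete (trio, locus) cells: %.1f%%\n", 100 * miss))
})

#' Difference vectors X = 2C - F - M and Y = M - F
#'
#' Computes, for every trio and locus with a complete genotype triple,
#' the association difference X (affected child versus the untransmitted
#' complement, whose count is F + M - C) and the maternal difference Y
#' (mother versus father). Cells with any missing member are marked
#' incomplete and excluded from all downstream statistics.
#'
#' @param trios a [TrioGenotypes-class] object.
#' @return A [DiffVectors-class] object.
#' @examples
#' tg <- trioGenotypes(M = matrix(2), F = matrix(0), C = matrix(1))
#' diffs <- computeDiffVectors(tg)
#' diffs@X  # 0
#' diffs@Y  # 2
#' @export
computeDiffVectors <- function(trios) {
    stopifnot(is(trios, "TrioGenotypes"))
    complete <- !(is.na(trios@M) | is.na(trios@F) | is.na(trios@C))
    X <- 2 * trios@C - trios@F - trios@M
    Y <- trios@M - trios@F
    X[!complete] <- 0L
    Y[!complete] <- 0L
    storage.mode(X) <- "double"
    storage.mode(Y) <- "double"
    new("DiffVectors", X = X, Y = Y, complete = complete,
        snpId = trios@snpId)
}

#' @export
setMethod("show", "DiffVectors", function(object) {
    cat("DiffVectors:", nrow(object@X), "trios x", ncol(object@X),
        "loci;", sum(object@complete), "complete cells\n")
})

#' Flag Mendelian-inconsistent genotype triples
#'
#' A complete (trio, locus) cell is consistent when the child's count can
#' be written as one allele inherited from each parent: a parent with
#' count 0 must transmit 0, with 2 must transmit 1, with 1 may transmit
#' either. Returns every complete cell violating this, so the caller can
#' drop cells, drop trios, or raise an error.
#'
#' @param trios a [TrioGenotypes-class] object.
#' @return A data.frame with columns `trio`, `locus`, `snpId`, `M`, `F`,
#'   `C` (zero rows if no violations).
#' @examples
#' tg <- trioGenotypes(M = matrix(0), F = matrix(0), C = matrix(1))
#' checkMendelian(tg)  # flagged: child allele absent from both parents
#' @export
checkMendelian <- function(trios) {
    stopifnot(is(trios, "TrioGenotypes"))
    M <- trios@M; F <- trios@F; C <- trios@C
    # transmissible allele counts: parent 0 -> {0}, 1 -> {0,1}, 2 -> {1}
    loM <- (M == 2L) + 0L; hiM <- (M >= 1L) + 0L
    loF <- (F == 2L) + 0L; hiF <- (F >= 1L) + 0L
    bad <- (C < loM + loF) | (C > hiM + hiF)
    bad[is.na(bad)] <- FALSE
    idx <- which(bad, arr.ind = TRUE)
    data.frame(trio = idx[, 1L], locus = idx[, 2L],
               snpId = trios@snpId[idx[, 2L]],
               M = M[idx], F = F[idx], C = C[idx])
}

#' Randomly mask genotype calls
#'
#' Sets each individual genotype call (independently for mother, father
#' and child, per locus) to missing with probability `rate`, emulating
#' incomplete SNP data. The trio statistics handle the result by
#' per-locus complete-case analysis.
#'
#' @param trios a [TrioGenotypes-class] object.
#' @param rate missingness probability in `[0, 1)`.
#' @return A [TrioGenotypes-class] object with `NA`s inserted.
#' @export
maskGenotypes <- function(trios, rate) {
    stopifnot(is(trios, "TrioGenotypes"), rate >= 0, rate < 1)
    if (rate == 0) return(trios)
    d <- dim(trios@M)
    mk <- function(g) {
        g[runif(length(g)) < rate] <- NA_integer_
        g
    }
    .newTrioGenotypes(mk(trios@M), mk(trios@F), mk(trios@C), trios@snpId)
}
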