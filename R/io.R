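# Linkage-format (PED/MAP) input, trio assembly, and the end-to-end
# test pipeline with report writing.

.readMap <- function(map) {
    m <- read.table(map, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(m) < 4L)
        stop("MAP file must have 4 columns: chromosome, snp id, genetic distance, position")
    data.frame(chrom = m[[1L]], snpId = as.character(m[[2L]]),
               cm = m[[3L]], pos = m[[4L]])
}

#' Read case-parent trios from linkage PED/MAP files
#'
#' @description
#' Parses a whitespace-delimited PED file (family id, individual id,
#' father id, mother id, sex, phenotype, then two allele columns per
#' SNP; allele "0" = missing call) and its MAP file, collapses each
#' allele pair to a count of a per-SNP counted allele, and assembles
#' case-parent trios: every individual with phenotype 2 whose father and
#' mother are both present in the same family becomes one trio.
#' Individuals not part of a complete trio are dropped with a warning;
#' families contributing several affected siblings contribute one trio
#' per sibling (the trios are then not independent, which is noted in a
#' message).
#'
#' By default the counted allele of each SNP is the minor allele in the
#' parental pool (ties broken lexicographically). The choice is
#' inconsequential for inference: recoding a SNP replaces counts c by
#' 2 - c for all three members, which negates X and Y at that locus and
#' leaves PC, Z^2 and permutation p-values unchanged.
#'
#' @param ped,map paths to the PED and MAP files.
#' @param refAlleles optional character vector (one per SNP) naming the
#'   allele to count, overriding the minor-allele rule.
#' @param mendelian what to do with Mendelian-inconsistent cells:
#'   `"drop-cell"` (default) sets the three genotypes of the offending
#'   (trio, locus) cell to missing, `"drop-trio"` removes the trio,
#'   `"error"` aborts.
#' @return A [TrioGenotypes-class] object; the realized counted alleles
#'   are in `attr(, "refAlleles")`.
#' @export
readPed <- function(ped, map, refAlleles = NULL,
                    mendelian = c("drop-cell", "drop-trio", "error")) {
    mendelian <- match.arg(mendelian)
    mp <- .readMap(map)
    q <- nrow(mp)
    lines <- readLines(ped)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    nc <- lengths(toks)
    bad <- which(nc != 6L + 2L * q)
    if (length(bad))
        stop("PED line ", bad[1L], " has ", nc[bad[1L]],
             " fields; expected ", 6L + 2L * q, " for ", q, " SNPs")
    tab <- do.call(rbind, toks)
    fam <- tab[, 1L]; iid <- tab[, 2L]; pat <- tab[, 3L]; mat <- tab[, 4L]
    pheno <- tab[, 6L]
    al1 <- tab[, 6L + 2L * seq_len(q) - 1L, drop = FALSE]
    al2 <- tab[, 6L + 2L * seq_len(q), drop = FALSE]

    key <- paste(fam, iid)
    isChild <- pheno == "2" & pat != "0" & mat != "0" &
        paste(fam, pat) %in% key & paste(fam, mat) %in% key
    if (!any(isChild))
        stop("no affected child with both parents present in its family")
    kidRows <- which(isChild)
    faRows <- match(paste(fam[kidRows], pat[kidRows]), key)
    moRows <- match(paste(fam[kidRows], mat[kidRows]), key)
    used <- unique(c(kidRows, faRows, moRows))
    if (length(used) < nrow(tab))
        warning(nrow(tab) - length(used),
                " individual(s) not part of a complete case-parent trio; dropped")
    if (anyDuplicated(fam[kidRows]))
        message("some families contribute several affected siblings; their trios are not independent")

    counted <- character(q)
    parents <- c(faRows, moRows)
    M <- matrix(NA_integer_, length(kidRows), q)
    F <- M; C <- M
    for (l in seq_len(q)) {
        obs <- c(al1[parents, l], al2[parents, l])
        obs <- obs[obs != "0"]
        counted[l] <- if (!is.null(refAlleles)) refAlleles[l]
        else if (!length(obs)) "0"
        else {
            tb <- table(obs)
            names(tb)[order(tb, names(tb))][1L]
        }
        cnt <- function(rows) {
            a <- al1[rows, l]; b <- al2[rows, l]
            ifelse(a == "0" | b == "0", NA_integer_,
                   (a == counted[l]) + (b == counted[l]))
        }
        M[, l] <- cnt(moRows)
        F[, l] <- cnt(faRows)
        C[, l] <- cnt(kidRows)
    }
    tg <- trioGenotypes(M, F, C, snpId = mp$snpId)
    viol <- checkMendelian(tg)
    if (nrow(viol)) {
        if (mendelian == "error")
            stop(nrow(viol), " Mendelian-inconsistent (trio, locus) cell(s)")
        if (mendelian == "drop-trio") {
            keep <- setdiff(seq_len(nTrios(tg)), unique(viol$trio))
            if (!length(keep)) stop("every trio has a Mendelian inconsistency")
            tg <- trioGenotypes(M[keep, , drop = FALSE],
                                F[keep, , drop = FALSE],
                                C[keep, , drop = FALSE], snpId = mp$snpId)
            message("dropped ", length(unique(viol$trio)),
                    " trio(s) with Mendelian inconsistencies")
        } else {
            idx <- cbind(viol$trio, viol$locus)
            M[idx] <- NA_integer_; F[idx] <- NA_integer_; C[idx] <- NA_integer_
            tg <- trioGenotypes(M, F, C, snpId = mp$snpId)
            message("masked ", nrow(viol),
                    " Mendelian-inconsistent cell(s)")
        }
    }
    attr(tg, "refAlleles") <- counted
    tg
}

#' Write trios to linkage PED/MAP files
#'
#' Emits three PED rows per trio (father, mother, affected child) with
#' the counted allele written as `alleles[1]` and the other as
#' `alleles[2]`; missing genotypes become "0 0". The MAP file places the
#' SNPs at `positionsKb` (or 1 kb apart) on chromosome 1.
#'
#' @param trios a [TrioGenotypes-class] object.
#' @param ped,map output paths (`map = NULL` skips the MAP file).
#' @param alleles two allele symbols; the first is the counted allele.
#' @param positionsKb optional SNP positions in kb.
#' @return The counted-allele vector (per SNP), invisibly, for use as
#'   `refAlleles` when reading back.
#' @export
writePed <- function(trios, ped, map = NULL, alleles = c("A", "B"),
                     positionsKb = NULL) {
    stopifnot(is(trios, "TrioGenotypes"), length(alleles) == 2L)
    n <- nTrios(trios); q <- nLoci(trios)
    pair <- function(g) {
        out <- matrix("0", length(g), 2L)
        out[!is.na(g) & g == 2L, ] <- alleles[1L]
        out[!is.na(g) & g == 1L, ] <- rep(alleles, each = sum(!is.na(g) & g == 1L))
        out[!is.na(g) & g == 0L, ] <- alleles[2L]
        out
    }
    rows <- vector("list", 3L * n)
    for (i in seq_len(n)) {
        famId <- paste0("fam", i)
        gf <- pair(trios@F[i, ]); gm <- pair(trios@M[i, ]); gc <- pair(trios@C[i, ])
        rows[[3L * i - 2L]] <- c(famId, "f", "0", "0", "1", "1",
                                 as.vector(t(gf)))
        rows[[3L * i - 1L]] <- c(famId, "m", "0", "0", "2", "1",
                                 as.vector(t(gm)))
        rows[[3L * i]] <- c(famId, "c", "f", "m", "0", "2",
                            as.vector(t(gc)))
    }
    writeLines(vapply(rows, paste, "", collapse = " "), ped)
    if (!is.null(map)) {
        if (is.null(positionsKb)) positionsKb <- seq_len(q)
        write.table(data.frame(1L, snpIds(trios), 0,
                               as.integer(round(positionsKb * 1000))),
                    map, sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    invisible(rep(alleles[1L], q))
}

#' Run the full trio test pipeline
#'
#' Computes the difference vectors, the per-locus PC and Z^2 statistics,
#' the requested max statistics and their permutation p-values, and
#' (optionally) writes a per-locus TSV table plus a JSON summary.
#'
#' @param trios a [TrioGenotypes-class] object.
#' @param statistic `"all"` (default) or one of `"maxPC"`,
#'   `"maxZ2assoc"`, `"maxZ2maternal"`.
#' @param nPermutations,seed permutation run parameters.
#' @param addOneCorrection use the (1 + #larger)/(B + 1) p-value
#'   estimate.
#' @param perLocusP also report a per-locus permutation p-value for each
#'   SNP (each locus statistic against its own permutation
#'   distribution), for screening risk-haplotype-tagging alleles.
#' @param outDir optional directory: writes `per_locus.tsv` and
#'   `summary.json` there.
#' @return A list with `perLocus` (data.frame: snpId, nComplete, pc,
#'   z2Assoc, z2Maternal, and per-locus p columns when requested) and
#'   `summary` (one row per requested statistic: maxStat, argmax SNP,
#'   pValue, nPermutations, seed).
#' @export
runTrioTest <- function(trios, statistic = c("all", "maxPC", "maxZ2assoc",
                                             "maxZ2maternal"),
                        nPermutations = 1000, seed = 1,
                        addOneCorrection = FALSE, perLocusP = FALSE,
                        outDir = NULL) {
    stopifnot(is(trios, "TrioGenotypes"))
    statistic <- match.arg(statistic)
    wanted <- if (statistic == "all") .STATS else statistic
    diffs <- computeDiffVectors(trios)
    plan <- permutationPlan(nPermutations, nTrios(trios), seed)
    res <- .permAll(diffs, plan)

    obsPC <- res$observed$maxPC
    perLocus <- data.frame(
        snpId = snpIds(trios),
        nComplete = obsPC@nComplete,
        pc = obsPC@perLocus,
        z2Assoc = res$observed$maxZ2assoc@perLocus,
        z2Maternal = res$observed$maxZ2maternal@perLocus)
    if (perLocusP) {
        perm <- .flipStats(diffs, plan@flipX, plan@flipY)
        obs <- .flipStats(diffs, .identityFlips(nTrios(trios)),
                          .identityFlips(nTrios(trios)))
        lp <- function(mat, o) colMeans(sweep(mat, 2L, drop(o), ">"))
        perLocus$pPc <- lp(perm$pc, obs$pc)
        perLocus$pZ2Assoc <- lp(perm$z2x, obs$z2x)
        perLocus$pZ2Maternal <- lp(perm$z2y, obs$z2y)
    }
    summary <- do.call(rbind, lapply(wanted, function(s) {
        o <- res$observed[[s]]
        data.frame(statistic = s, maxStat = o@maxStat,
                   argmaxSnp = snpIds(trios)[o@argmax],
                   pValue = .permPValue(o@maxStat, res$nulls[[s]],
                                        addOneCorrection),
                   nPermutations = plan@nPermutations, seed = plan@seed)
    }))
    out <- list(perLocus = perLocus, summary = summary)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        write.table(perLocus, file.path(outDir, "per_locus.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(summary = summary,
                 config = list(statistic = statistic,
                               nPermutations = nPermutations, seed = seed,
                               addOneCorrection = addOneCorrection,
                               nTrios = nTrios(trios),
                               nLoci = nLoci(trios))),
            file.path(outDir, "summary.json"),
            auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    out
}
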