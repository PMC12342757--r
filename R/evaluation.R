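#' Reference alignment with core annotation
#'
#' Benchmark reference alignments mark trusted ("core") positions in
#' uppercase and unreliable ones in lowercase; lowercase positions are
#' excluded from Q/TC scoring. This class stores the uppercased alignment
#' together with the per-position core flags recovered from the letter
#' case of the source file.
#'
#' @slot aln the uppercased [GappedAlignment-class].
#' @slot core logical matrix, same shape as the alignment: `TRUE` where
#'   the reference residue was uppercase (gaps are `TRUE`, irrelevant to
#'   scoring).
#' @exportClass ReferenceAlignment
setClass("ReferenceAlignment",
         representation(aln = "GappedAlignment", core = "matrix"))

setValidity("ReferenceAlignment", function(object) {
    m <- as.matrix(object@aln)
    if (!identical(dim(object@core), dim(m)))
        return("core flag matrix shape does not match the alignment")
    TRUE
})

#' @export
setMethod("show", "ReferenceAlignment", function(object) {
    cat(sprintf("ReferenceAlignment: %d sequence(s) x %d column(s), %d core position(s)\n",
                alnNrow(object@aln), alnWidth(object@aln),
                sum(object@core & as.matrix(object@aln) != "-")))
})

#' @describeIn ReferenceAlignment-class the underlying alignment.
#' @param x a `ReferenceAlignment`.
#' @export
refAlignment <- function(x) x@aln

#' Read a reference alignment, preserving case annotation
#'
#' Like [readAlignedFasta()] but records which positions were lowercase
#' in the file before uppercasing.
#'
#' @param path path to a FASTA reference alignment.
#' @return A [ReferenceAlignment-class].
#' @export
readReferenceAlignment <- function(path) {
    raw <- .readFastaRaw(path)
    rawNorm <- chartr(".", "-", raw)
    aln <- GappedAlignment(names(raw), unname(rawNorm))
    caseM <- matrix(TRUE, nrow = alnNrow(aln), ncol = alnWidth(aln))
    if (alnWidth(aln) > 0L) {
        chars <- matrix(unlist(strsplit(unname(rawNorm), "", fixed = TRUE),
                               use.names = FALSE),
                        nrow = alnNrow(aln), byrow = TRUE)
        caseM <- !(chars %in% letters)
        dim(caseM) <- dim(chars)
    }
    new("ReferenceAlignment", aln = aln, core = caseM)
}

#' Treat an alignment as an all-core reference
#'
#' @param aln a [GappedAlignment-class].
#' @return A [ReferenceAlignment-class] with every position marked core.
#' @export
asReference <- function(aln) {
    new("ReferenceAlignment", aln = aln,
        core = matrix(TRUE, nrow = alnNrow(aln), ncol = alnWidth(aln)))
}

# Common checks + reorder for Q/TC; returns list(test, ref, coreResidue)
.evalPrep <- function(test, ref) {
    if (!is(ref, "ReferenceAlignment"))
        stop("ref must be a ReferenceAlignment (see readReferenceAlignment/asReference)")
    refAln <- ref@aln
    missA <- setdiff(refAln@ids, test@ids)
    missB <- setdiff(test@ids, refAln@ids)
    if (length(missA) || length(missB))
        stop("test and reference ids differ; missing: ",
             paste(c(missA, missB), collapse = ", "))
    test <- reorderToMatch(test, refAln)
    gt <- removeGaps(test); gr <- removeGaps(refAln)
    if (!identical(unname(toupper(gt)), unname(toupper(gr))))
        stop("test and reference disagree on ungapped sequence content")
    list(test = test, ref = refAln, core = ref@core)
}

#' Q score: fraction of reference residue pairs reproduced
#'
#' A residue pair is two residues of distinct sequences sharing a column.
#' Q = (pairs aligned in the reference that are also aligned in the test
#' alignment) / (pairs aligned in the reference). Pairs involving a
#' lowercase (non-core) reference residue are excluded from both counts.
#' A reference with zero scorable pairs yields 0 with a warning.
#'
#' @param test a [GappedAlignment-class].
#' @param ref a [ReferenceAlignment-class] over the same sequences.
#' @return A fraction in `[0, 1]`.
#' @export
qScore <- function(test, ref) {
    pp <- .evalPrep(test, ref)
    pT <- mapPositions(pp$test)
    pR <- mapPositions(pp$ref)
    core <- pp$core
    n <- nrow(pR)
    refPairs <- 0L; hit <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            okR <- pR[i, ] > 0L & pR[j, ] > 0L & core[i, ] & core[j, ]
            if (!any(okR)) next
            keyR <- pR[i, okR] * (max(pR[j, ]) + 1L) + pR[j, okR]
            okT <- pT[i, ] > 0L & pT[j, ] > 0L
            keyT <- pT[i, okT] * (max(pR[j, ]) + 1L) + pT[j, okT]
            refPairs <- refPairs + length(keyR)
            hit <- hit + sum(keyR %in% keyT)
        }
    }
    if (refPairs == 0L) {
        warning("reference contains no scorable residue pairs; Q defined as 0")
        return(0)
    }
    hit / refPairs
}

#' TC score: fraction of reference columns reproduced intact
#'
#' A reference column (restricted to columns containing at least one
#' uppercase residue) is reproduced when all its uppercase residues
#' appear together in a single column of the test alignment. TC is the
#' fraction of such reference columns reproduced. A reference with no
#' scorable column yields 0 with a warning.
#'
#' @inheritParams qScore
#' @return A fraction in `[0, 1]`.
#' @export
tcScore <- function(test, ref) {
    pp <- .evalPrep(test, ref)
    pT <- mapPositions(pp$test)
    pR <- mapPositions(pp$ref)
    core <- pp$core
    scorable <- 0L; hit <- 0L
    for (cc in seq_len(ncol(pR))) {
        rows <- which(pR[, cc] > 0L & core[, cc])
        if (length(rows) == 0L) next
        scorable <- scorable + 1L
        pos <- pR[rows, cc]
        # the residue of the first row pins down the unique candidate column
        cand <- which(pT[rows[[1L]], ] == pos[[1L]])
        if (length(cand) == 1L && all(pT[rows, cand] == pos))
            hit <- hit + 1L
    }
    if (scorable == 0L) {
        warning("reference contains no scorable columns; TC defined as 0")
        return(0)
    }
    hit / scorable
}
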