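# Run code under a fixed RNG seed without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' Simulate a synthetic protein family with known true alignment
#'
#' Samples an ancestor uniformly over the 20 standard residues and
#' evolves each descendant independently: every site outside the
#' conserved core mutates with probability `substitutionRate` (the
#' replacement drawn uniformly from the 19 other residues) and suffers an
#' indel event with probability `indelRate` (insertion or deletion with
#' equal chance, geometric length with mean `indelLenMean`). The middle
#' 40-60% of ancestor positions form an indel-free conserved core, so the
#' true alignment always has a gap-free central block — the premise of
#' the head/target/tail segmentation. Insertions are private to their
#' sequence and occupy their own gap columns (no homology is claimed
#' between independent insertions). The true alignment induced by the
#' shared ancestry is returned along with the ungapped sequences;
#' deterministic given `seed`.
#'
#' @param nSeqs number of descendant sequences (>= 2).
#' @param ancestorLen ancestor length in residues (>= 1).
#' @param substitutionRate per-site substitution probability per lineage.
#' @param indelRate per-site indel event probability per lineage.
#' @param indelLenMean mean of the geometric indel length (>= 1).
#' @param seed integer RNG seed.
#' @return A list: `reference` (the true alignment as an all-core
#'   [ReferenceAlignment-class]), `sequences` (named character vector,
#'   equal to the gap-stripped truth), `ancestor` (character string).
#' @export
generateFamily <- function(nSeqs = 8L, ancestorLen = 200L,
                           substitutionRate = 0.10, indelRate = 0.03,
                           indelLenMean = 1.5, seed = 1L) {
    stopifnot(nSeqs >= 2L, ancestorLen >= 1L,
              substitutionRate >= 0, substitutionRate <= 1,
              indelRate >= 0, indelRate <= 1, indelLenMean >= 1)
    .withSeed(seed, {
        L <- as.integer(ancestorLen)
        anc <- sample(.RESIDUES20, L, replace = TRUE)
        coreStart <- max(1L, as.integer(ceiling(0.4 * L)))
        coreEnd <- min(L, max(coreStart, as.integer(floor(0.6 * L))))
        inCore <- seq_len(L) >= coreStart & seq_len(L) <= coreEnd
        geomLen <- function() 1L + stats::rgeom(1L, prob = 1 / indelLenMean)
        ids <- sprintf("seq%02d", seq_len(nSeqs))
        kept <- matrix(TRUE, nSeqs, L)       # ancestor site retained?
        resid <- matrix("", nSeqs, L)        # residue at retained sites
        inserts <- matrix("", nSeqs, L)      # insertion string after site s
        for (i in seq_len(nSeqs)) {
            r <- anc
            mut <- stats::runif(L) < substitutionRate & !inCore
            for (s in which(mut))
                r[s] <- sample(setdiff(.RESIDUES20, r[s]), 1L)
            ev <- which(stats::runif(L) < indelRate & !inCore)
            for (s in ev) {
                if (!kept[i, s]) next  # already inside an earlier deletion
                g <- geomLen()
                if (stats::runif(1L) < 0.5) {
                    # deletion of sites s .. s+g-1, truncated at the core
                    span <- s:min(L, s + g - 1L)
                    span <- span[!cumsum(inCore[span]) > 0L]
                    kept[i, span] <- FALSE
                } else {
                    inserts[i, s] <- paste(
                        sample(.RESIDUES20, g, replace = TRUE),
                        collapse = "")
                }
            }
            resid[i, ] <- r
        }
        # true alignment: one column per ancestor site, plus per-row
        # private blocks for insertions after that site
        cols <- list()
        for (s in seq_len(L)) {
            col <- ifelse(kept[, s], resid[, s], "-")
            cols[[length(cols) + 1L]] <- matrix(col, ncol = 1L)
            for (i in which(nzchar(inserts[, s]))) {
                ins <- strsplit(inserts[i, s], "")[[1L]]
                block <- matrix("-", nSeqs, length(ins))
                block[i, ] <- ins
                cols[[length(cols) + 1L]] <- block
            }
        }
        m <- do.call(cbind, cols)
        rownames(m) <- ids
        truth <- .alnFromMatrix(m)
        list(reference = asReference(truth),
             sequences = removeGaps(truth),
             ancestor = paste(anc, collapse = ""))
    })
}

#' Degrade an alignment by random local gap shifts
#'
#' Produces an imperfect "initial alignment" from a good one: `nShifts`
#' times, a random gap is swapped with an adjacent residue within its
#' row. Columns at the first and last gap-free column of the input are
#' never touched, so the head/tail segmentation of the original is
#' preserved. Ungapped content is conserved; deterministic given `seed`.
#'
#' @param aln a [GappedAlignment-class].
#' @param nShifts number of gap moves to apply.
#' @param seed integer RNG seed.
#' @return A degraded [GappedAlignment-class].
#' @export
degradeAlignment <- function(aln, nShifts, seed = 1L) {
    if (nShifts == 0L) return(aln)
    m <- as.matrix(aln)
    w <- ncol(m)
    if (w < 2L) return(aln)
    cp <- findCutPoints(columnConservationMask(aln))
    allowed <- rep(TRUE, w)
    if (!is.null(cp)) allowed[c(cp[[1L]], cp[[2L]])] <- FALSE
    .withSeed(seed, {
        done <- 0L; attempts <- 0L
        maxAttempts <- 50L * nShifts
        while (done < nShifts && attempts < maxAttempts) {
            attempts <- attempts + 1L
            i <- sample.int(nrow(m), 1L)
            g <- sample.int(w, 1L)
            if (!allowed[g] || m[i, g] != "-") next
            dirs <- sample(c(-1L, 1L))
            moved <- FALSE
            for (d in dirs) {
                t <- g + d
                if (t >= 1L && t <= w && allowed[t] && m[i, t] != "-") {
                    m[i, c(g, t)] <- m[i, c(t, g)]
                    moved <- TRUE
                    break
                }
            }
            if (moved) done <- done + 1L
        }
        .alnFromMatrix(m)
    })
}
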