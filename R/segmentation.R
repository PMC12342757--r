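#' Gap-free column mask
#'
#' Marks each column of the alignment: `TRUE` if no row has a gap there
#' (a fully conserved, residue-only column), `FALSE` otherwise.
#'
#' @param aln a [GappedAlignment-class].
#' @return Logical vector of length `alnWidth(aln)`.
#' @export
columnConservationMask <- function(aln) {
    m <- as.matrix(aln)
    if (ncol(m) == 0L) return(logical(0))
    colSums(m == "-") == 0L
}

#' Cut points delimiting the realignment target
#'
#' The first and last gap-free columns delimit the central region the
#' refinement works on; the flanks outside them are left untouched.
#'
#' @param mask logical vector from [columnConservationMask()].
#' @return `c(first, last)` (1-based column indices), or `NULL` when no
#'   column is gap-free.
#' @export
findCutPoints <- function(mask) {
    w <- which(mask)
    if (length(w) == 0L) return(NULL)
    c(first = w[[1L]], last = w[[length(w)]])
}

#' Split an alignment into head, target and tail
#'
#' Columns before the first gap-free column form the head, columns after
#' the last gap-free column form the tail, and everything in between
#' (inclusive of both cut columns) is the target region submitted to
#' vertical iterative realignment. When no gap-free column exists the
#' whole alignment becomes the target and head/tail are empty.
#'
#' @param aln a [GappedAlignment-class].
#' @return A list with elements `head`, `target`, `tail` (each a
#'   `GappedAlignment`), and `cutPoints` (`c(first, last)` or `NULL`).
#' @export
splitAlignment <- function(aln) {
    w <- alnWidth(aln)
    cp <- findCutPoints(columnConservationMask(aln))
    if (is.null(cp)) {
        list(head = alnColumns(aln, 1L, 0L),
             target = aln,
             tail = alnColumns(aln, 1L, 0L),
             cutPoints = NULL)
    } else {
        list(head = alnColumns(aln, 1L, cp[[1L]] - 1L),
             target = alnColumns(aln, cp[[1L]], cp[[2L]]),
             tail = if (cp[[2L]] < w) alnColumns(aln, cp[[2L]] + 1L, w)
                    else alnColumns(aln, 1L, 0L),
             cutPoints = cp)
    }
}
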