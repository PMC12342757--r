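#' Match identical columns between two alignments of the same sequences
#'
#' Compares the positional matrices of the original and realigned
#' alignments column-wise and reports every pair of columns whose full
#' label vectors are identical and contain at least one residue.
#' All-gap (all-zero) columns never match. Because any shared residue
#' label fixes the relative order, matches are strictly increasing in
#' both coordinates.
#'
#' @param pInit,pReal integer matrices from [mapPositions()], both derived
#'   from alignments over the same sequences in the same row order.
#' @return A data.frame with integer columns `init` and `real` (1-based
#'   column indices), ordered by `init`.
#' @export
matchIdenticalColumns <- function(pInit, pReal) {
    if (nrow(pInit) != nrow(pReal))
        stop("not the same sequences: row counts differ")
    maxI <- apply(pInit, 1L, function(r) if (length(r)) max(r) else 0L)
    maxR <- apply(pReal, 1L, function(r) if (length(r)) max(r) else 0L)
    if (!identical(unname(maxI), unname(maxR)))
        stop("not the same sequences: per-row residue counts differ")
    keyOf <- function(P) {
        if (ncol(P) == 0L) return(character(0))
        apply(P, 2L, paste, collapse = ",")
    }
    ki <- keyOf(pInit); kr <- keyOf(pReal)
    nzI <- colSums(pInit != 0L) > 0L
    nzR <- colSums(pReal != 0L) > 0L
    idx <- match(ki, kr)
    keep <- nzI & !is.na(idx) & nzR[ifelse(is.na(idx), 1L, idx)]
    out <- data.frame(init = which(keep), real = idx[keep])
    out[order(out$init), , drop = FALSE]
}

#' Chain column matches into unchanged anchor intervals
#'
#' Groups the matches into maximal runs where both coordinates increase
#' by exactly 1 from one match to the next, and keeps runs of at least
#' `minLen` columns as unchanged anchors.
#'
#' @param matches data.frame from [matchIdenticalColumns()].
#' @param minLen minimum anchor length (default 2).
#' @return A data.frame with columns `init_start`, `init_end`,
#'   `real_start`, `real_end` (1-based, closed spans).
#' @export
chainUnchangedIntervals <- function(matches, minLen = 2L) {
    empty <- data.frame(init_start = integer(0), init_end = integer(0),
                        real_start = integer(0), real_end = integer(0))
    if (nrow(matches) == 0L) return(empty)
    brk <- c(TRUE, !(diff(matches$init) == 1L & diff(matches$real) == 1L))
    grp <- cumsum(brk)
    out <- do.call(rbind, lapply(split(seq_len(nrow(matches)), grp), function(i) {
        if (length(i) < minLen) return(NULL)
        data.frame(init_start = matches$init[i[1L]],
                   init_end = matches$init[i[length(i)]],
                   real_start = matches$real[i[1L]],
                   real_end = matches$real[i[length(i)]])
    }))
    if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

# Per-row cumulative residue counts; column c+1 holds the number of
# residues of each row in alignment columns 1..c (column 1 is all zero).
.cumResid <- function(aln) {
    m <- as.matrix(aln) != "-"
    out <- matrix(0L, nrow(m), ncol(m) + 1L)
    for (i in seq_len(nrow(m)))
        out[i, -1L] <- cumsum(m[i, ])
    out
}

# An anchor is a sound partition boundary only if, for every row, the two
# alignments have consumed the same number of residues before it. Rows
# with a residue in the anchor column guarantee this through their label;
# rows that are gapped there do not (label 0 carries no position), so the
# cumulative counts must be checked explicitly. Anchors failing the check
# would put different residues into the flanking changed pairs.
.consistentAnchors <- function(anchors, aInit, aReal) {
    if (nrow(anchors) == 0L) return(anchors)
    ui <- .cumResid(aInit); ur <- .cumResid(aReal)
    ok <- vapply(seq_len(nrow(anchors)), function(k)
        all(ui[, anchors$init_start[k]] == ur[, anchors$real_start[k]]),
        logical(1))
    anchors[ok, , drop = FALSE]
}

# Anchors whose columns share no sequence row carry no mutual order
# constraint, so two runs can cross (increasing in the original alignment,
# decreasing in the realigned one). A partition needs a jointly increasing
# subset; keep the one anchoring the most columns (weighted longest
# increasing subsequence, O(k^2) over k anchors, ties to earlier anchors).
.monotoneAnchors <- function(anchors) {
    n <- nrow(anchors)
    if (n <= 1L) return(anchors)
    anchors <- anchors[order(anchors$init_start), , drop = FALSE]
    wts <- anchors$init_end - anchors$init_start + 1L
    best <- numeric(n); prev <- integer(n)
    for (i in seq_len(n)) {
        best[i] <- wts[i]
        for (j in seq_len(i - 1L)) {
            if (anchors$init_end[j] < anchors$init_start[i] &&
                anchors$real_end[j] < anchors$real_start[i] &&
                best[j] + wts[i] > best[i]) {
                best[i] <- best[j] + wts[i]
                prev[i] <- j
            }
        }
    }
    k <- which.max(best)
    sel <- integer(0)
    while (k > 0L) { sel <- c(k, sel); k <- prev[k] }
    out <- anchors[sel, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Partition two alignments into anchors and changed region pairs
#'
#' Given the anchors, the column spans between (and flanking) them become
#' changed region pairs: the same residues, gapped differently in the two
#' alignments. Either side of a changed pair may be empty (width 0), but
#' not both. With no anchors the whole of both alignments forms a single
#' changed pair.
#'
#' Candidate anchors that would break the partition are screened out and
#' fall into changed regions instead: boundaries where the two alignments
#' disagree on how many residues of some (gapped) row precede them, and
#' anchor runs that cross each other in the two coordinate systems (a
#' jointly increasing subset maximizing anchored columns is kept).
#'
#' @param aInit,aReal [GappedAlignment-class] objects over the same
#'   sequences in the same row order (`aReal` already reordered).
#' @param anchors data.frame from [chainUnchangedIntervals()].
#' @return A data.frame with columns `type` (`"anchor"`/`"changed"`),
#'   `init_start`, `init_end`, `real_start`, `real_end`; 1-based closed
#'   spans, a span with `end = start - 1` being empty. Spans cover both
#'   alignments completely, in order.
#' @export
partitionRegions <- function(aInit, aReal, anchors) {
    wi <- alnWidth(aInit); wr <- alnWidth(aReal)
    anchors <- .monotoneAnchors(.consistentAnchors(anchors, aInit, aReal))
    segs <- list()
    curI <- 1L; curR <- 1L
    addChanged <- function(ie, re) {
        if (curI <= ie || curR <= re)
            segs[[length(segs) + 1L]] <<- data.frame(
                type = "changed", init_start = curI, init_end = ie,
                real_start = curR, real_end = re)
    }
    if (nrow(anchors) > 0L) {
        for (k in seq_len(nrow(anchors))) {
            a <- anchors[k, ]
            addChanged(a$init_start - 1L, a$real_start - 1L)
            segs[[length(segs) + 1L]] <- data.frame(
                type = "anchor", init_start = a$init_start,
                init_end = a$init_end, real_start = a$real_start,
                real_end = a$real_end)
            curI <- a$init_end + 1L
            curR <- a$real_end + 1L
        }
    }
    addChanged(wi, wr)
    if (length(segs) == 0L)
        return(data.frame(type = character(0), init_start = integer(0),
                          init_end = integer(0), real_start = integer(0),
                          real_end = integer(0)))
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out
}
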