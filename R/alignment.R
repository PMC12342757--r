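#' @import methods
NULL

# Alphabet: 20 standard residues, ambiguity letters, stop, gap.
.RESIDUES20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AMBIG <- c("B", "Z", "X", "U", "O", "J", "*")
.GAP <- "-"
.ALN_ALPHABET <- c(.RESIDUES20, .AMBIG, .GAP)

#' Gapped protein multiple sequence alignment
#'
#' An ordered set of (identifier, gapped sequence) records of equal length.
#' Sequences use the 20 standard amino-acid letters plus the ambiguity
#' letters B, Z, X, U, O, J and `*`, with `-` as the gap symbol; residues
#' are stored uppercase. Identifiers are unique.
#'
#' @slot ids character vector of unique record identifiers.
#' @slot seqs character vector of gapped sequences, parallel to `ids`.
#'
#' @seealso [readAlignedFasta()], [alnIds()], [alnWidth()]
#' @exportClass GappedAlignment
setClass("GappedAlignment",
         representation(ids = "character", seqs = "character"))

setValidity("GappedAlignment", function(object) {
    if (length(object@ids) != length(object@seqs))
        return("ids and seqs must have equal length")
    if (anyDuplicated(object@ids))
        return(paste0("duplicate identifiers: ",
                      paste(unique(object@ids[duplicated(object@ids)]),
                            collapse = ", ")))
    w <- unique(nchar(object@seqs))
    if (length(w) > 1)
        return("sequences have unequal lengths: not an alignment")
    bad <- grepl(paste0("[^", paste(c(.RESIDUES20, "BZXUOJ"), collapse = ""),
                        "*\\-]"), object@seqs)
    if (any(bad))
        return(paste0("invalid characters in record(s): ",
                      paste(object@ids[bad], collapse = ", ")))
    TRUE
})

#' Construct a GappedAlignment
#'
#' @param ids character vector of record identifiers.
#' @param seqs character vector of gapped sequences (same length as `ids`).
#'   Lowercase letters are uppercased; `.` gaps are normalized to `-`.
#' @return A [GappedAlignment-class] object.
#' @examples
#' GappedAlignment(c("s1", "s2"), c("AR-N", "A-RN"))
#' @export
GappedAlignment <- function(ids = character(), seqs = character()) {
    seqs <- chartr(".", "-", toupper(as.character(seqs)))
    new("GappedAlignment", ids = as.character(ids), seqs = seqs)
}

#' @describeIn GappedAlignment-class record identifiers.
#' @param x,object a `GappedAlignment`.
#' @export
alnIds <- function(x) x@ids

#' @describeIn GappedAlignment-class gapped sequences, named by id.
#' @export
alnSeqs <- function(x) stats::setNames(x@seqs, x@ids)

#' @describeIn GappedAlignment-class alignment width (number of columns).
#' @export
alnWidth <- function(x) if (length(x@seqs) == 0L) 0L else nchar(x@seqs[[1L]])

#' @describeIn GappedAlignment-class number of records.
#' @export
alnNrow <- function(x) length(x@ids)

#' @export
setMethod("show", "GappedAlignment", function(object) {
    cat(sprintf("GappedAlignment: %d sequence(s) x %d column(s)\n",
                alnNrow(object), alnWidth(object)))
    n <- min(6L, alnNrow(object))
    for (i in seq_len(n)) {
        s <- object@seqs[[i]]
        if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
        cat(sprintf("  %-12s %s\n", object@ids[[i]], s))
    }
    if (alnNrow(object) > n) cat(sprintf("  ... %d more\n", alnNrow(object) - n))
})

#' @export
setMethod("as.matrix", "GappedAlignment", function(x, ...) {
    if (alnWidth(x) == 0L || alnNrow(x) == 0L) {
        m <- matrix(character(0), nrow = alnNrow(x), ncol = alnWidth(x))
    } else {
        m <- matrix(unlist(strsplit(x@seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = alnNrow(x), byrow = TRUE)
    }
    rownames(m) <- x@ids
    m
})

.alnFromMatrix <- function(m) {
    seqs <- if (ncol(m) == 0L) rep("", nrow(m)) else
        apply(m, 1L, paste, collapse = "")
    new("GappedAlignment", ids = rownames(m), seqs = unname(seqs))
}

#' Extract a contiguous block of columns
#'
#' Spans are 1-based and closed; `end = start - 1` gives a width-0 block.
#'
#' @param x a [GappedAlignment-class].
#' @param start,end first and last column of the block.
#' @return A `GappedAlignment` over the same records.
#' @export
alnColumns <- function(x, start, end) {
    if (end < start)
        return(new("GappedAlignment", ids = x@ids,
                   seqs = rep("", length(x@ids))))
    stopifnot(start >= 1L, end <= alnWidth(x))
    new("GappedAlignment", ids = x@ids, seqs = substr(x@seqs, start, end))
}

#' Read an aligned FASTA file
#'
#' Reads a protein alignment in FASTA format. Sequences are uppercased, `.`
#' gaps are normalized to `-`, and record order is preserved. Unequal
#' sequence lengths, duplicate identifiers, empty files and characters
#' outside the amino-acid-plus-gap alphabet are errors.
#'
#' @param path path to a FASTA file.
#' @return A [GappedAlignment-class].
#' @export
readAlignedFasta <- function(path) {
    raw <- .readFastaRaw(path)
    seqs <- chartr(".", "-", toupper(raw))
    .checkAlphabet(seqs, names(raw))
    w <- nchar(seqs)
    if (length(unique(w)) > 1) {
        off <- names(raw)[w != w[[1L]]][[1L]]
        stop("not an alignment: record '", off,
             "' has a different length than the first record")
    }
    GappedAlignment(names(raw), unname(seqs))
}

# Shared low-level FASTA reader (keeps original case for the reference loader)
.readFastaRaw <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e)
                        stop("could not parse FASTA file '", path, "': ",
                             conditionMessage(e)))
    if (length(set) == 0L) stop("empty FASTA file: ", path)
    stats::setNames(as.character(set), names(set))
}

.checkAlphabet <- function(seqs, ids) {
    bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYBZXUOJ*\\-]", seqs)
    if (any(bad > 0)) {
        i <- which(bad > 0)[[1L]]
        stop("invalid character '", substr(seqs[[i]], bad[[i]], bad[[i]]),
             "' at position ", bad[[i]], " of record '", ids[[i]], "'")
    }
    invisible(TRUE)
}

#' Write an alignment to FASTA
#'
#' Emits `-` for gaps and wraps sequence lines at 60 columns. Reading the
#' file back yields an identical alignment.
#'
#' @param aln a [GappedAlignment-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeAlignedFasta <- function(aln, path) {
    set <- Biostrings::BStringSet(stats::setNames(aln@seqs, aln@ids))
    Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                                width = 60L)
    invisible(path)
}

#' Strip all gaps from an alignment
#'
#' @param aln a [GappedAlignment-class].
#' @return Named character vector of ungapped sequences (possibly empty
#'   strings), ids and order preserved.
#' @export
removeGaps <- function(aln) {
    stats::setNames(gsub("-", "", aln@seqs, fixed = TRUE), aln@ids)
}

#' Positional mapping of an alignment
#'
#' Labels every cell of the alignment: gaps get 0, residues are numbered
#' 1, 2, 3, ... left to right within each row (their position in the
#' ungapped sequence). Two columns of two alignments over the same
#' sequences are identical exactly when their label vectors are equal.
#'
#' @param aln a [GappedAlignment-class].
#' @return Integer matrix, one row per record (rownames = ids), one column
#'   per alignment column.
#' @export
mapPositions <- function(aln) {
    m <- as.matrix(aln)
    res <- m != "-"
    if (ncol(m) == 0L) {
        out <- matrix(integer(0), nrow = nrow(m), ncol = 0L)
    } else if (nrow(m) == 1L) {
        out <- matrix(cumsum(res[1L, ]) * as.integer(res[1L, ]), nrow = 1L)
    } else {
        cs <- apply(res, 1L, cumsum)  # returns a vector when ncol == 1
        if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
        out <- t(cs) * res
    }
    storage.mode(out) <- "integer"
    rownames(out) <- aln@ids
    out
}

#' Reorder an alignment's rows to match a template
#'
#' Inner aligners may permute sequence order; this restores the order of
#' the original alignment so the two can be compared column-wise.
#'
#' @param realigned a [GappedAlignment-class] to reorder.
#' @param template a `GappedAlignment` holding the desired id order.
#' @return `realigned` with records permuted into `template`'s id order.
#' @export
reorderToMatch <- function(realigned, template) {
    missA <- setdiff(template@ids, realigned@ids)
    missB <- setdiff(realigned@ids, template@ids)
    if (length(missA) || length(missB))
        stop("alignments do not contain the same ids; missing: ",
             paste(c(missA, missB), collapse = ", "))
    idx <- match(template@ids, realigned@ids)
    new("GappedAlignment", ids = realigned@ids[idx],
        seqs = realigned@seqs[idx])
}

#' Concatenate alignments column-wise
#'
#' All parts must hold the same ids in the same order; width-0 parts are
#' permitted. Row i of the output is the concatenation of row i across
#' parts.
#'
#' @param parts list of [GappedAlignment-class] objects.
#' @return A single `GappedAlignment`.
#' @export
concatColumns <- function(parts) {
    stopifnot(length(parts) >= 1L)
    ids <- parts[[1L]]@ids
    for (p in parts)
        if (!identical(p@ids, ids))
            stop("cannot concatenate: parts have different id order")
    seqs <- do.call(paste0, lapply(parts, function(p) p@seqs))
    if (length(ids) == 0L) seqs <- character(0)
    new("GappedAlignment", ids = ids, seqs = seqs)
}
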