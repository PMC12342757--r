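#' Sum-of-pairs objective configuration
#'
#' Bundles the amino-acid substitution matrix with the two flat gap
#' penalties used by the objective: `aaGap` for a residue paired with a
#' gap and `gapGap` for two gaps in the same column. Defaults are
#' BLOSUM62, aaGap = -6, gapGap = 0.
#'
#' @slot matrixName name of the substitution matrix.
#' @slot matrix numeric substitution matrix (symmetric, residue letters as
#'   dimnames).
#' @slot aaGap residue-vs-gap score (typically negative).
#' @slot gapGap gap-vs-gap score.
#' @slot lookup internal score lookup over the full alignment alphabet
#'   including the gap symbol.
#' @exportClass ScoringParams
setClass("ScoringParams",
         representation(matrixName = "character", matrix = "matrix",
                        aaGap = "numeric", gapGap = "numeric",
                        lookup = "matrix"))

setValidity("ScoringParams", function(object) {
    m <- object@matrix
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        return("substitution matrix must have identical row/column names")
    if (!isTRUE(all.equal(m, t(m))))
        return("substitution matrix must be symmetric")
    TRUE
})

#' @export
setMethod("show", "ScoringParams", function(object) {
    cat(sprintf("ScoringParams: matrix=%s, aaGap=%g, gapGap=%g\n",
                object@matrixName, object@aaGap, object@gapGap))
})

#' Load a bundled substitution matrix
#'
#' @param name `"BLOSUM62"` or `"PAM250"` (the published matrices as
#'   shipped by Biostrings).
#' @return Numeric matrix with residue letters as dimnames.
#' @export
scoringMatrix <- function(name = c("BLOSUM62", "PAM250")) {
    name <- match.arg(toupper(name), c("BLOSUM62", "PAM250"))
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    get(name, envir = env)
}

#' Parse an NCBI-format substitution matrix file
#'
#' Whitespace-separated square matrix with one header row of letters,
#' one letter labelling each row, and `#` comment lines.
#'
#' @param path path to the matrix file.
#' @return Numeric matrix with letters as dimnames.
#' @export
readScoringMatrix <- function(path) {
    if (!file.exists(path)) stop("matrix file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) < 2L) stop("malformed matrix file: ", path)
    header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
    n <- length(header)
    rows <- lapply(lines[-1L], function(ln) strsplit(trimws(ln), "\\s+")[[1L]])
    labs <- vapply(rows, `[[`, character(1), 1L)
    vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])))
    if (any(vapply(vals, length, 1L) != n) || anyNA(unlist(vals)))
        stop("malformed matrix file: ", path)
    m <- do.call(rbind, vals)
    dimnames(m) <- list(toupper(labs), toupper(header))
    m <- m[, rownames(m), drop = FALSE]  # align column order to row order
    if (!isTRUE(all.equal(m, t(m))))
        stop("matrix in ", path, " is not symmetric")
    m
}

# Full lookup table over the alignment alphabet (residues + gap). Letters
# missing from the matrix fall back to its wildcard 'X' row; pairs with no
# resolution at all become NA and error out when actually scored.
.buildLookup <- function(m, aaGap, gapGap) {
    ab <- .ALN_ALPHABET
    res <- setdiff(ab, .GAP)
    fallback <- function(l) {
        if (l %in% rownames(m)) l
        else if ("X" %in% rownames(m)) "X"
        else NA_character_
    }
    mapped <- vapply(res, fallback, character(1))
    L <- matrix(NA_real_, length(ab), length(ab), dimnames = list(ab, ab))
    ok <- !is.na(mapped)
    L[res[ok], res[ok]] <- m[mapped[ok], mapped[ok]]
    L[res, .GAP] <- aaGap
    L[.GAP, res] <- aaGap
    L[.GAP, .GAP] <- gapGap
    L
}

#' Construct the objective configuration
#'
#' @param matrix matrix name (`"BLOSUM62"`/`"PAM250"`), a numeric matrix,
#'   or a path to an NCBI-format matrix file.
#' @param aaGap residue-vs-gap score; default -6.
#' @param gapGap gap-vs-gap score; default 0.
#' @return A [ScoringParams-class] object.
#' @examples
#' p <- scoringParams()           # BLOSUM62, -6, 0
#' pairScore("A", "A", p)         # 4
#' @export
scoringParams <- function(matrix = "BLOSUM62", aaGap = -6, gapGap = 0) {
    if (is.character(matrix) && length(matrix) == 1L) {
        if (toupper(matrix) %in% c("BLOSUM62", "PAM250")) {
            name <- toupper(matrix)
            m <- scoringMatrix(name)
        } else {
            name <- basename(matrix)
            m <- readScoringMatrix(matrix)
        }
    } else if (is.matrix(matrix)) {
        name <- "custom"
        m <- matrix
    } else stop("matrix must be a name, a file path, or a numeric matrix")
    new("ScoringParams", matrixName = name, matrix = m,
        aaGap = aaGap, gapGap = gapGap,
        lookup = .buildLookup(m, aaGap, gapGap))
}

#' Score one character pair
#'
#' Residue/residue pairs use the substitution matrix, residue/gap pairs
#' score `aaGap`, gap/gap pairs score `gapGap`. Vectorized over `a`, `b`.
#'
#' @param a,b alignment characters (residue letters or `"-"`).
#' @param p a [ScoringParams-class].
#' @return Numeric score(s).
#' @export
pairScore <- function(a, b, p) {
    ia <- match(a, .ALN_ALPHABET)
    ib <- match(b, .ALN_ALPHABET)
    if (anyNA(ia) || anyNA(ib))
        stop("character outside the alignment alphabet: ",
             paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
    s <- p@lookup[cbind(ia, ib)]
    if (anyNA(s))
        stop("letter(s) not covered by matrix '", p@matrixName,
             "' and no wildcard row present")
    s
}

#' Column score of the sum-of-pairs objective
#'
#' Sums `pairScore` over all ordered pairs of distinct rows of one
#' alignment column, i.e. each unordered pair is counted twice.
#'
#' @param col character vector: one alignment column, one entry per row.
#' @param p a [ScoringParams-class].
#' @return Numeric score.
#' @export
columnScore <- function(col, p) {
    idx <- match(col, .ALN_ALPHABET)
    if (anyNA(idx))
        stop("character outside the alignment alphabet: ",
             paste(unique(col[is.na(idx)]), collapse = ", "))
    s <- p@lookup[idx, idx, drop = FALSE]
    if (anyNA(s))
        stop("letter(s) not covered by matrix '", p@matrixName, "'")
    sum(s) - sum(diag(s))
}

#' Sum-of-pairs score of an alignment fragment
#'
#' The objective used to arbitrate competing sub-alignments: the column
#' score summed over all columns. A width-0 fragment scores 0, as does a
#' single-row fragment (no pairs).
#'
#' @param frag a [GappedAlignment-class] (or character matrix of alignment
#'   characters, rows = sequences).
#' @param p a [ScoringParams-class].
#' @return Numeric score.
#' @export
spScore <- function(frag, p) {
    m <- if (is.matrix(frag)) frag else as.matrix(frag)
    if (ncol(m) == 0L || nrow(m) < 2L) return(0)
    ab <- .ALN_ALPHABET
    idx <- match(m, ab)
    if (anyNA(idx))
        stop("character outside the alignment alphabet in fragment")
    # per-column letter counts -> quadratic form against the lookup table
    C <- matrix(0, nrow = length(ab), ncol = ncol(m))
    dim(idx) <- dim(m)
    for (j in seq_len(ncol(m))) {
        t <- tabulate(idx[, j], nbins = length(ab))
        C[, j] <- t
    }
    L <- p@lookup
    used <- rowSums(C) > 0
    if (anyNA(L[used, used]))
        stop("letter(s) not covered by matrix '", p@matrixName, "'")
    L0 <- L
    L0[is.na(L0)] <- 0
    total <- sum((L0 %*% C) * C) - sum(diag(L0) * rowSums(C))
    total
}
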