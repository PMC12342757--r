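#' Inner aligner backend specification
#'
#' The vertical iterative realignment strips a region to its gap-free
#' sequences and hands them to an inner multiple-alignment engine. Three
#' kinds are supported: `"external"` (a child process run from a command
#' template with `{in}`/`{out}` placeholders, e.g. MUSCLE5 or MAFFT
#' FFT-NS-I), `"builtin"` (a deterministic center-star progressive
#' aligner, so the package works with no external binary), and
#' `"function"` (an in-process R function, mainly for testing).
#'
#' @slot name backend name (`"muscle5"`, `"fftnsi"`, `"builtin"`, or
#'   custom).
#' @slot kind one of `"external"`, `"builtin"`, `"function"`.
#' @slot command command template with `{in}` and `{out}` placeholders
#'   (external only).
#' @slot fun function taking a named character vector of ungapped
#'   sequences and returning a [GappedAlignment-class] (function kind
#'   only).
#' @slot timeout per-call timeout in seconds for external processes.
#' @exportClass BackendSpec
setClass("BackendSpec",
         representation(name = "character", kind = "character",
                        command = "character", fun = "ANY",
                        timeout = "numeric"))

setValidity("BackendSpec", function(object) {
    if (!object@kind %in% c("external", "builtin", "function"))
        return("kind must be external, builtin or function")
    if (object@kind == "external" && !nzchar(object@command))
        return("external backend requires a command template")
    if (object@kind == "function" && !is.function(object@fun))
        return("function backend requires a function")
    TRUE
})

#' @export
setMethod("show", "BackendSpec", function(object) {
    cat(sprintf("BackendSpec '%s' (%s)\n", object@name, object@kind))
    if (object@kind == "external")
        cat("  command:", object@command, "\n")
})

.DEFAULT_COMMANDS <- c(
    muscle5 = "muscle -align {in} -output {out}",
    fftnsi = "mafft --retree 2 --maxiterate 2 --inputorder {in} > {out}")

#' Construct a backend specification
#'
#' @param name backend name. `"muscle5"` and `"fftnsi"` come with
#'   conventional command templates; `"builtin"` selects the internal
#'   center-star aligner; any other name requires `command` or `fun`.
#' @param command command template with `{in}`/`{out}` placeholders;
#'   overrides the default template.
#' @param fun an R function `(seqs) -> GappedAlignment`; makes this a
#'   function backend.
#' @param timeout per-call timeout in seconds (default 600).
#' @return A [BackendSpec-class].
#' @examples
#' backendSpec("builtin")
#' backendSpec("muscle5")
#' @export
backendSpec <- function(name = "muscle5", command = NULL, fun = NULL,
                        timeout = 600) {
    if (!is.null(fun)) {
        new("BackendSpec", name = name, kind = "function", command = "",
            fun = fun, timeout = timeout)
    } else if (identical(name, "builtin")) {
        new("BackendSpec", name = "builtin", kind = "builtin", command = "",
            fun = NULL, timeout = timeout)
    } else {
        cmd <- if (!is.null(command)) command
               else if (name %in% names(.DEFAULT_COMMANDS))
                   .DEFAULT_COMMANDS[[name]]
               else stop("unknown backend '", name,
                         "': supply a command template")
        new("BackendSpec", name = name, kind = "external", command = cmd,
            fun = NULL, timeout = timeout)
    }
}

#' Align a sequence set with a backend
#'
#' Wraps the inner engine with the degenerate-input contract: rows whose
#' sequence is empty are withheld from the engine and re-inserted as
#' all-gap rows; a single non-empty sequence is returned as-is; all-empty
#' input yields a width-0 alignment. The output holds exactly the input
#' ids (in input order) and stripping its gaps recovers the input
#' sequences (validated; a violation is reported as a backend error).
#'
#' @param backend a [BackendSpec-class].
#' @param seqs named character vector of ungapped sequences (ids as
#'   names).
#' @param params a [ScoringParams-class]; used by the builtin backend's
#'   pairwise steps.
#' @return A [GappedAlignment-class].
#' @export
alignBackend <- function(backend, seqs, params = scoringParams()) {
    stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
    if (any(grepl("-", seqs, fixed = TRUE)))
        stop("backend input must be ungapped")
    nonempty <- nchar(seqs) > 0L
    ids <- names(seqs)
    if (sum(nonempty) == 0L)
        return(GappedAlignment(ids, rep("", length(ids))))
    if (sum(nonempty) == 1L) {
        w <- nchar(seqs[nonempty])
        out <- ifelse(nonempty, seqs, strrep("-", w))
        return(GappedAlignment(ids, unname(out)))
    }
    sub <- seqs[nonempty]
    aln <- switch(backend@kind,
        builtin = builtinAlign(sub, params),
        "function" = backend@fun(sub),
        external = .externalAlign(backend, sub))
    if (!setequal(alnIds(aln), names(sub)))
        stop("backend '", backend@name, "' returned wrong ids; missing: ",
             paste(setdiff(names(sub), alnIds(aln)), collapse = ", "))
    got <- removeGaps(aln)
    if (!identical(unname(got[names(sub)]), unname(sub)))
        stop("backend '", backend@name,
             "' did not conserve residues of the input sequences")
    w <- alnWidth(aln)
    gapRow <- strrep("-", w)
    full <- stats::setNames(rep(gapRow, length(ids)), ids)
    full[names(sub)] <- alnSeqs(aln)[names(sub)]
    GappedAlignment(ids, unname(full))
}

.externalAlign <- function(backend, seqs) {
    tmpIn <- tempfile(fileext = ".fasta")
    tmpOut <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(tmpIn, tmpOut)), add = TRUE)
    writeAlignedFasta(GappedAlignment(names(seqs), unname(seqs)), tmpIn)
    cmd <- gsub("{out}", shQuote(tmpOut),
                gsub("{in}", shQuote(tmpIn), backend@command, fixed = TRUE),
                fixed = TRUE)
    errFile <- tempfile()
    on.exit(unlink(errFile), add = TRUE)
    status <- suppressWarnings(
        system2("/bin/sh", c("-c", shQuote(cmd)), stdout = FALSE,
                stderr = errFile, timeout = backend@timeout))
    if (!identical(status, 0L)) {
        diag <- tryCatch(paste(readLines(errFile, warn = FALSE),
                               collapse = "\n"),
                         error = function(e) "")
        stop("backend '", backend@name, "' failed (exit ", status, "): ",
             diag)
    }
    if (!file.exists(tmpOut) || file.size(tmpOut) == 0L)
        stop("backend '", backend@name, "' produced no output")
    readAlignedFasta(tmpOut)
}

#' Built-in deterministic center-star aligner
#'
#' A simple progressive multiple aligner used when no external engine is
#' available (tests, demos, fully reproducible runs). The center sequence
#' is the one maximizing its summed pairwise global-alignment score
#' against all others (ties go to the lowest input index); every other
#' sequence is aligned to the center by Needleman-Wunsch global alignment
#' under the objective's substitution matrix with a linear per-character
#' gap cost of `|aaGap|`, and the pairwise alignments are merged on the
#' center's coordinates ("once a gap, always a gap"). Deterministic: the
#' same input always yields byte-identical output. Not claimed to match a
#' dedicated MSA tool's quality.
#'
#' @param seqs named character vector of at least two non-empty ungapped
#'   sequences.
#' @param params a [ScoringParams-class]; `aaGap` must be non-positive.
#' @return A [GappedAlignment-class] in the input row order.
#' @export
builtinAlign <- function(seqs, params = scoringParams()) {
    stopifnot(length(seqs) >= 2L, all(nchar(seqs) > 0L))
    if (params@aaGap > 0)
        stop("builtin aligner requires a non-positive aaGap penalty")
    n <- length(seqs)
    subMat <- .pairwiseMatrix(params)
    xs <- Biostrings::AAStringSet(unname(seqs))
    gapPen <- abs(params@aaGap)
    # center = sequence with maximal summed pairwise score
    S <- matrix(0, n, n)
    for (j in 2:n) {
        sc <- Biostrings::pairwiseAlignment(
            xs[seq_len(j - 1L)], xs[[j]], type = "global",
            substitutionMatrix = subMat, gapOpening = 0,
            gapExtension = gapPen, scoreOnly = TRUE)
        S[seq_len(j - 1L), j] <- sc
        S[j, seq_len(j - 1L)] <- sc
    }
    center <- which.max(rowSums(S))
    others <- setdiff(seq_len(n), center)
    # progressive merge on the center's coordinates
    cen <- strsplit(seqs[[center]], "")[[1L]]
    rows <- list()
    rows[[center]] <- cen
    for (j in others) {
        pa <- Biostrings::pairwiseAlignment(
            xs[[center]], xs[[j]], type = "global",
            substitutionMatrix = subMat, gapOpening = 0,
            gapExtension = gapPen)
        cg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
        sg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
        merged <- .mergeOnCenter(cen, rows, cg, sg)
        cen <- merged$cen
        rows <- merged$rows
        rows[[j]] <- merged$newRow
    }
    GappedAlignment(names(seqs),
                    vapply(rows, paste, character(1), collapse = ""))
}

# Merge a new pairwise (center, seq) alignment into the growing MSA.
# cen: current gapped center; rows: list of gapped rows (center included);
# cg/sg: the new pairwise alignment's gapped center and gapped sequence.
# Once a column is a gap it stays a gap: gap columns of either center view
# are preserved, residue columns are matched one-to-one.
.mergeOnCenter <- function(cen, rows, cg, sg) {
    nA <- length(cen); nB <- length(cg)
    takeA <- integer(nA + nB); takeB <- integer(nA + nB)
    i <- 1L; j <- 1L; k <- 0L
    while (i <= nA || j <= nB) {
        k <- k + 1L
        aRes <- i <= nA && cen[i] != "-"
        bRes <- j <= nB && cg[j] != "-"
        if (i <= nA && !aRes) {
            takeA[k] <- i; i <- i + 1L
        } else if (j <= nB && !bRes) {
            takeB[k] <- j; j <- j + 1L
        } else {
            takeA[k] <- i; takeB[k] <- j
            i <- i + 1L; j <- j + 1L
        }
    }
    takeA <- takeA[seq_len(k)]; takeB <- takeB[seq_len(k)]
    newRows <- lapply(rows, function(r) {
        if (is.null(r)) return(NULL)
        out <- rep("-", length(takeA))
        out[takeA > 0L] <- r[takeA[takeA > 0L]]
        out
    })
    newCen <- rep("-", length(takeA))
    newCen[takeA > 0L] <- cen[takeA[takeA > 0L]]
    newCen[takeB > 0L] <- cg[takeB[takeB > 0L]]
    newRow <- rep("-", length(takeB))
    newRow[takeB > 0L] <- sg[takeB[takeB > 0L]]
    list(cen = newCen, rows = newRows, newRow = newRow)
}

# Substitution matrix for pairwise steps: extend the objective's matrix to
# any residue letters it lacks via the wildcard 'X' row.
.pairwiseMatrix <- function(params) {
    m <- params@matrix
    res <- setdiff(.ALN_ALPHABET, .GAP)
    missing <- setdiff(res, rownames(m))
    if (length(missing) && "X" %in% rownames(m)) {
        ext <- matrix(0, length(res), length(res),
                      dimnames = list(res, res))
        map <- ifelse(res %in% rownames(m), res, "X")
        ext[] <- m[map, map]
        ext
    } else m
}
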