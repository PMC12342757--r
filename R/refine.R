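#' Refinement configuration
#'
#' Collects everything the vertical iterative realignment needs: the
#' inner aligner backend, the sum-of-pairs objective parameters, the
#' minimum unchanged-anchor length, a recursion depth backstop, and the
#' policy applied when the input has no gap-free column at all.
#'
#' @slot backend a [BackendSpec-class].
#' @slot params a [ScoringParams-class].
#' @slot minAnchorLen minimum length of an unchanged anchor interval
#'   (default 2).
#' @slot maxDepth maximum recursion depth (default 10).
#' @slot noConservedPolicy `"all"` (treat the whole alignment as the
#'   target region when no gap-free column exists) or `"skip"` (return
#'   the input untouched in that case).
#' @exportClass RefineConfig
setClass("RefineConfig",
         representation(backend = "BackendSpec", params = "ScoringParams",
                        minAnchorLen = "integer", maxDepth = "integer",
                        noConservedPolicy = "character"))

setValidity("RefineConfig", function(object) {
    if (object@maxDepth < 1L) return("maxDepth must be >= 1")
    if (object@minAnchorLen < 1L) return("minAnchorLen must be >= 1")
    if (!object@noConservedPolicy %in% c("all", "skip"))
        return("noConservedPolicy must be 'all' or 'skip'")
    TRUE
})

#' @export
setMethod("show", "RefineConfig", function(object) {
    cat("RefineConfig\n")
    cat(sprintf("  backend: %s (%s)\n", object@backend@name,
                object@backend@kind))
    cat(sprintf("  objective: %s, aaGap=%g, gapGap=%g\n",
                object@params@matrixName, object@params@aaGap,
                object@params@gapGap))
    cat(sprintf("  minAnchorLen=%d, maxDepth=%d, noConservedPolicy=%s\n",
                object@minAnchorLen, object@maxDepth,
                object@noConservedPolicy))
})

#' Construct a refinement configuration
#'
#' Defaults follow the tool's recommended settings: MUSCLE5 as the inner
#' aligner, BLOSUM62 with aaGap = -6 and gapGap = 0 as the objective,
#' anchors of length >= 2.
#'
#' @param backend a [BackendSpec-class] (default `backendSpec("muscle5")`).
#' @param params a [ScoringParams-class] (default `scoringParams()`).
#' @param minAnchorLen minimum anchor length, default 2.
#' @param maxDepth recursion depth backstop, default 10.
#' @param noConservedPolicy `"all"` or `"skip"`, default `"all"`.
#' @return A [RefineConfig-class].
#' @export
refineConfig <- function(backend = backendSpec("muscle5"),
                         params = scoringParams(),
                         minAnchorLen = 2L, maxDepth = 10L,
                         noConservedPolicy = c("all", "skip")) {
    new("RefineConfig", backend = backend, params = params,
        minAnchorLen = as.integer(minAnchorLen),
        maxDepth = as.integer(maxDepth),
        noConservedPolicy = match.arg(noConservedPolicy))
}

.newReportEnv <- function() {
    e <- new.env(parent = emptyenv())
    e$decisions <- list()
    e$anchors <- 0L
    e$notes <- character(0)
    e
}

.reportDecision <- function(env, depth, seg, scoreInit, scoreReal, chosen,
                            fragInit, fragReal) {
    env$decisions[[length(env$decisions) + 1L]] <- data.frame(
        depth = depth, init_start = seg$init_start, init_end = seg$init_end,
        real_start = seg$real_start, real_end = seg$real_end,
        score_initial = scoreInit, score_realigned = scoreReal,
        chosen = chosen,
        init_rows = paste(fragInit@seqs, collapse = ";"),
        real_rows = paste(fragReal@seqs, collapse = ";"))
}

.finishReport <- function(env, extra = list()) {
    dec <- if (length(env$decisions)) do.call(rbind, env$decisions)
           else data.frame(depth = integer(0), init_start = integer(0),
                           init_end = integer(0), real_start = integer(0),
                           real_end = integer(0),
                           score_initial = numeric(0),
                           score_realigned = numeric(0),
                           chosen = character(0),
                           init_rows = character(0),
                           real_rows = character(0))
    c(list(decisions = dec, anchors = env$anchors, notes = env$notes), extra)
}

#' Vertical iterative realignment of an alignment region
#'
#' The recursive core of the refinement. One round: (1) strip all gaps
#' and re-align the gap-free sequences with the inner backend, reordering
#' the result to the input's row order; (2) if the realigned alignment is
#' column-for-column identical to the input, stop; (3) partition the two
#' alignments into unchanged anchors and changed region pairs; (4) keep
#' anchors verbatim from the input; for each changed pair score both
#' sides with the sum-of-pairs objective, keep the higher-scoring side
#' (ties keep the input's version) and recurse on it; (5) concatenate
#' everything back in order.
#'
#' Residue content is conserved exactly: stripping gaps from the result
#' gives the same sequences as stripping gaps from the input. Two guards
#' ensure termination even with a backend that keeps proposing a rejected
#' alternative: a changed pair spanning the whole input whose input side
#' wins is returned without recursion, and recursion never exceeds
#' `maxDepth`.
#'
#' @param aln a [GappedAlignment-class] (the region to refine).
#' @param config a [RefineConfig-class].
#' @return A list: `alignment` (the refined [GappedAlignment-class]) and
#'   `report` (region decisions, anchor count, termination notes).
#' @export
verticalIterativeRealign <- function(aln, config = refineConfig()) {
    env <- .newReportEnv()
    out <- .vir(aln, config, 0L, env)
    list(alignment = out, report = .finishReport(env))
}

.vir <- function(aln, cfg, depth, env) {
    S <- removeGaps(aln)
    if (sum(nchar(S) > 0L) <= 1L) {
        env$notes <- c(env$notes,
                       sprintf("depth %d: <2 non-empty sequences, nothing to align",
                               depth))
        return(aln)
    }
    aReal <- tryCatch(
        alignBackend(cfg@backend, S, cfg@params),
        error = function(e) stop("inner aligner failed on region of width ",
                                 alnWidth(aln), " at depth ", depth, ": ",
                                 conditionMessage(e), call. = FALSE))
    aReal <- reorderToMatch(aReal, aln)
    # Termination: realignment reproduces the input exactly (gapped strings)
    if (identical(aReal@seqs, aln@seqs)) {
        env$notes <- c(env$notes, sprintf("depth %d: converged", depth))
        return(aln)
    }
    part <- partitionRegions(aln, aReal,
                             chainUnchangedIntervals(
                                 matchIdenticalColumns(mapPositions(aln),
                                                       mapPositions(aReal)),
                                 cfg@minAnchorLen))
    wholeInput <- nrow(part) == 1L && part$type[[1L]] == "changed"
    pieces <- vector("list", nrow(part))
    for (k in seq_len(nrow(part))) {
        seg <- part[k, ]
        if (seg$type == "anchor") {
            env$anchors <- env$anchors + 1L
            pieces[[k]] <- alnColumns(aln, seg$init_start, seg$init_end)
            next
        }
        fragInit <- alnColumns(aln, seg$init_start, seg$init_end)
        fragReal <- alnColumns(aReal, seg$real_start, seg$real_end)
        sInit <- spScore(fragInit, cfg@params)
        sReal <- spScore(fragReal, cfg@params)
        keepInit <- sInit >= sReal
        chosen <- if (keepInit) fragInit else fragReal
        .reportDecision(env, depth, seg, sInit, sReal,
                        if (keepInit) "initial" else "realigned",
                        fragInit, fragReal)
        if (wholeInput && keepInit) {
            # recursing would repeat the identical call forever
            env$notes <- c(env$notes,
                           sprintf("depth %d: whole-input region kept initial, stopping",
                                   depth))
            pieces[[k]] <- chosen
        } else if (depth + 1L > cfg@maxDepth) {
            env$notes <- c(env$notes,
                           sprintf("depth %d: max depth reached", depth))
            pieces[[k]] <- chosen
        } else if (sum(nchar(removeGaps(chosen)) > 0L) <= 1L) {
            pieces[[k]] <- chosen
        } else {
            pieces[[k]] <- .vir(chosen, cfg, depth + 1L, env)
        }
    }
    concatColumns(pieces)
}

#' Refine a protein multiple sequence alignment
#'
#' The top-level workflow: segment the input at its first and last
#' gap-free columns into head, target and tail; submit the target region
#' to [verticalIterativeRealign()]; concatenate the untouched head, the
#' refined target, and the untouched tail. Head and tail columns appear
#' verbatim at the output's flanks; the output's gap-stripped sequences
#' equal the input's. The output width may differ from the input width
#' (gap columns inside the target may be removed or introduced).
#'
#' @param aln a [GappedAlignment-class] (the initial alignment).
#' @param config a [RefineConfig-class].
#' @return A list: `alignment` (the final [GappedAlignment-class]) and
#'   `report` (decisions plus `cutPoints`, `headWidth`, `tailWidth`).
#' @examples
#' aln <- GappedAlignment(c("s1", "s2", "s3"),
#'                        c("MKV-LT", "MKVALT", "MK-VLT"))
#' cfg <- refineConfig(backend = backendSpec("builtin"))
#' res <- realignMSA(aln, cfg)
#' res$alignment
#' @export
realignMSA <- function(aln, config = refineConfig()) {
    seg <- splitAlignment(aln)
    if (is.null(seg$cutPoints) && config@noConservedPolicy == "skip") {
        env <- .newReportEnv()
        env$notes <- "no gap-free column; skipped per policy"
        return(list(alignment = aln,
                    report = .finishReport(env, list(
                        cutPoints = NULL, headWidth = 0L, tailWidth = 0L))))
    }
    res <- verticalIterativeRealign(seg$target, config)
    out <- concatColumns(list(seg$head, res$alignment, seg$tail))
    report <- res$report
    report$cutPoints <- seg$cutPoints
    report$headWidth <- alnWidth(seg$head)
    report$tailWidth <- alnWidth(seg$tail)
    list(alignment = out, report = report)
}
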