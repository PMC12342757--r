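builtinCfg <- function(...) refineConfig(backend = backendSpec("builtin"), ...)

test_that("a backend reproducing the input terminates the iteration at once", {
    aln <- GappedAlignment(c("s1", "s2"), c("AR-N", "A-RN"))
    cfg <- refineConfig(backend = echoBackendFor(aln))
    res <- verticalIterativeRealign(aln, cfg)
    expect_identical(alnSeqs(res$alignment), alnSeqs(aln))
    expect_identical(nrow(res$report$decisions), 0L)
    expect_match(res$report$notes, "converged", all = FALSE)
})

test_that("all-gap column kept on a tie: traced small example", {
    # builtin realigns "AR-ND"/"AR-ND" to "ARND"/"ARND"; the vacated column
    # scores 0 (gapGap) vs 0 (empty) -> tie keeps the initial version
    aln <- GappedAlignment(c("s1", "s2"), c("AR-ND", "AR-ND"))
    res <- verticalIterativeRealign(aln, builtinCfg())
    expect_identical(unname(alnSeqs(res$alignment)), c("AR-ND", "AR-ND"))
    d <- res$report$decisions
    expect_identical(nrow(d), 1L)
    expect_identical(d$chosen, "initial")
    expect_identical(d$score_initial, 0)
    expect_identical(d$score_realigned, 0)
})

test_that("refinement conserves residues for builtin and mock backends", {
    set.seed(14)
    for (cfg in list(builtinCfg(), refineConfig(backend = diagonalBackend()))) {
        for (k in 1:15) {
            a <- randAln(sample(2:6, 1), sample(2:30, 1),
                         gapProb = runif(1, 0, 0.4))
            res <- realignMSA(a, cfg)
            expect_identical(removeGaps(res$alignment), removeGaps(a))
        }
    }
})

test_that("head and tail flanks are preserved verbatim", {
    aln <- GappedAlignment(c("s1", "s2"), c("-RN-", "-RN-"))
    res <- realignMSA(aln, builtinCfg())
    out <- alnSeqs(res$alignment)
    expect_identical(unname(substr(out, 1, 1)), c("-", "-"))
    w <- alnWidth(res$alignment)
    expect_identical(unname(substr(out, w, w)), c("-", "-"))

    set.seed(15)
    for (k in 1:10) {
        a <- randAln(4, 20, gapProb = 0.3)
        s <- splitAlignment(a)
        res <- realignMSA(a, builtinCfg())
        hw <- alnWidth(s$head); tw <- alnWidth(s$tail)
        out <- res$alignment
        if (hw > 0)
            expect_identical(alnSeqs(alnColumns(out, 1, hw)),
                             alnSeqs(s$head))
        if (tw > 0)
            expect_identical(
                alnSeqs(alnColumns(out, alnWidth(out) - tw + 1,
                                   alnWidth(out))),
                alnSeqs(s$tail))
    }
})

test_that("every region decision picks the SP-maximal side, ties to initial", {
    set.seed(16)
    p <- scoringParams()
    for (k in 1:10) {
        a <- randAln(sample(3:6, 1), sample(6:25, 1), gapProb = 0.3)
        res <- realignMSA(a, builtinCfg())
        d <- res$report$decisions
        for (i in seq_len(nrow(d))) {
            fi <- GappedAlignment(
                sprintf("r%d", seq_along(strsplit(d$init_rows[i], ";")[[1]])),
                strsplit(d$init_rows[i], ";")[[1]])
            fr <- GappedAlignment(
                sprintf("r%d", seq_along(strsplit(d$real_rows[i], ";")[[1]])),
                strsplit(d$real_rows[i], ";")[[1]])
            si <- bruteSpScore(fi, p); sr <- bruteSpScore(fr, p)
            expect_identical(d$score_initial[i], si)
            expect_identical(d$score_realigned[i], sr)
            expect_identical(d$chosen[i],
                             if (si >= sr) "initial" else "realigned")
        }
    }
})

test_that("a pathological backend cannot make the recursion loop", {
    set.seed(17)
    for (k in 1:10) {
        a <- randAln(sample(2:5, 1), sample(3:15, 1), gapProb = 0.3)
        cfg <- refineConfig(backend = diagonalBackend(), maxDepth = 4)
        res <- verticalIterativeRealign(a, cfg)
        expect_identical(removeGaps(res$alignment), removeGaps(a))
        expect_true(all(res$report$decisions$depth <= 4))
    }
    # a backend alternating between two layouts exercises the depth backstop
    flip <- local({
        state <- 0L
        backendSpec("flipflop", fun = function(seqs) {
            state <<- state + 1L
            lens <- nchar(seqs); W <- sum(lens)
            ord <- if (state %% 2L) seq_along(seqs) else rev(seq_along(seqs))
            off <- integer(length(seqs)); pos <- 0L
            for (i in ord) { off[i] <- pos; pos <- pos + lens[i] }
            GappedAlignment(names(seqs), vapply(seq_along(seqs), function(i)
                paste0(strrep("-", off[i]), seqs[i],
                       strrep("-", W - off[i] - lens[i])), ""))
        })
    })
    a <- GappedAlignment(c("s1", "s2", "s3"), c("ARND", "HKLM", "WYVC"))
    res <- verticalIterativeRealign(a, refineConfig(backend = flip,
                                                    maxDepth = 3))
    expect_identical(removeGaps(res$alignment), removeGaps(a))
})

test_that("no-conserved-column policy: skip returns the input, all refines", {
    a <- GappedAlignment(c("s1", "s2"), c("A-", "-A"))
    resSkip <- realignMSA(a, builtinCfg(noConservedPolicy = "skip"))
    expect_identical(alnSeqs(resSkip$alignment), alnSeqs(a))
    resAll <- realignMSA(a, builtinCfg(noConservedPolicy = "all"))
    expect_identical(removeGaps(resAll$alignment), removeGaps(a))
    # the realigned version stacks the two A's, which scores higher than -12
    expect_identical(unname(alnSeqs(resAll$alignment)), c("A", "A"))
})

test_that("refinement is idempotent at its fixed points", {
    set.seed(18)
    for (k in 1:5) {
        a <- randAln(4, 15, gapProb = 0.25)
        r1 <- realignMSA(a, builtinCfg())
        r2 <- realignMSA(r1$alignment, builtinCfg())
        r3 <- realignMSA(r2$alignment, builtinCfg())
        if (identical(alnSeqs(r2$alignment), alnSeqs(r1$alignment)))
            expect_identical(alnSeqs(r3$alignment), alnSeqs(r2$alignment))
    }
})

test_that("output width may shrink when a vacuous column loses its tie-break", {
    # width decreases when the realigned side strictly wins
    aln <- GappedAlignment(c("s1", "s2"), c("ARC--ND", "AR--CND"))
    res <- realignMSA(aln, builtinCfg())
    expect_lt(alnWidth(res$alignment), alnWidth(aln))
    expect_identical(removeGaps(res$alignment), removeGaps(aln))
})
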