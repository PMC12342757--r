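test_that("identical-column matching follows the worked mapping example", {
    aInit <- GappedAlignment(c("s1", "s2"), c("AR-N", "A-RN"))
    aReal <- GappedAlignment(c("s1", "s2"), c("ARN", "ARN"))
    m <- matchIdenticalColumns(mapPositions(aInit), mapPositions(aReal))
    expect_identical(m$init, c(1L, 4L))
    expect_identical(m$real, c(1L, 3L))
})

test_that("identical matrices match column-for-column; all-gap columns never match", {
    a <- GappedAlignment(c("s1", "s2"), c("AR-ND", "AR-ND"))
    P <- mapPositions(a)
    m <- matchIdenticalColumns(P, P)
    # column 3 is all-gap and must be excluded
    expect_identical(m$init, c(1L, 2L, 4L, 5L))
    expect_identical(m$init, m$real)
})

test_that("matching rejects alignments over different sequences", {
    a <- GappedAlignment(c("s1", "s2"), c("ARN", "ARN"))
    b <- GappedAlignment(c("s1", "s2"), c("ARND", "ARND"))
    expect_error(matchIdenticalColumns(mapPositions(a), mapPositions(b)),
                 "not the same sequences")
    c3 <- GappedAlignment(c("s1", "s2", "s3"), c("ARN", "ARN", "ARN"))
    expect_error(matchIdenticalColumns(mapPositions(a), mapPositions(c3)),
                 "not the same sequences")
})

test_that("anchor chaining keeps maximal consecutive runs of length >= minLen", {
    m1 <- data.frame(init = c(1L, 4L), real = c(1L, 3L))
    expect_identical(nrow(chainUnchangedIntervals(m1)), 0L)

    m2 <- data.frame(init = c(1L, 2L, 4L, 5L), real = c(1L, 2L, 3L, 4L))
    a2 <- chainUnchangedIntervals(m2)
    expect_identical(a2$init_start, c(1L, 4L))
    expect_identical(a2$init_end, c(2L, 5L))
    expect_identical(a2$real_start, c(1L, 3L))
    expect_identical(a2$real_end, c(2L, 4L))

    expect_identical(nrow(chainUnchangedIntervals(
        data.frame(init = integer(0), real = integer(0)))), 0L)
    # minLen is honoured
    expect_identical(nrow(chainUnchangedIntervals(m1, minLen = 1)), 2L)
})

test_that("partitioning alternates anchors and changed pairs and covers both alignments", {
    aInit <- GappedAlignment(c("s1", "s2"), c("AR-N", "A-RN"))
    aReal <- GappedAlignment(c("s1", "s2"), c("ARN", "ARN"))
    noAnchors <- chainUnchangedIntervals(
        matchIdenticalColumns(mapPositions(aInit), mapPositions(aReal)))
    p <- partitionRegions(aInit, aReal, noAnchors)
    expect_identical(p$type, "changed")
    expect_identical(c(p$init_start, p$init_end), c(1L, 4L))
    expect_identical(c(p$real_start, p$real_end), c(1L, 3L))

    # identical gap-free alignments: one anchor, no changed pairs
    same <- GappedAlignment(c("s1", "s2"), c("ARNDC", "ARNDC"))
    pSame <- partitionRegions(same, same, chainUnchangedIntervals(
        matchIdenticalColumns(mapPositions(same), mapPositions(same))))
    expect_identical(pSame$type, "anchor")
    expect_identical(c(pSame$init_start, pSame$init_end), c(1L, 5L))

    # all-gap column deleted by realignment: changed pair with empty real side
    aI <- GappedAlignment(c("s1", "s2"), c("AR-ND", "AR-ND"))
    aR <- GappedAlignment(c("s1", "s2"), c("ARND", "ARND"))
    pp <- partitionRegions(aI, aR, chainUnchangedIntervals(
        matchIdenticalColumns(mapPositions(aI), mapPositions(aR))))
    expect_identical(pp$type, c("anchor", "changed", "anchor"))
    chg <- pp[pp$type == "changed", ]
    expect_identical(c(chg$init_start, chg$init_end), c(3L, 3L))
    expect_true(chg$real_end < chg$real_start)  # empty real span
})

test_that("region partition conserves both alignments and changed pairs share residues", {
    set.seed(33)
    for (k in 1:40) {
        pr <- randAlnPair(sample(2:6, 1), sample(2:12, 1))
        anchors <- chainUnchangedIntervals(
            matchIdenticalColumns(mapPositions(pr$a), mapPositions(pr$b)))
        part <- partitionRegions(pr$a, pr$b, anchors)
        iParts <- lapply(seq_len(nrow(part)), function(i)
            alnColumns(pr$a, part$init_start[i], part$init_end[i]))
        rParts <- lapply(seq_len(nrow(part)), function(i)
            alnColumns(pr$b, part$real_start[i], part$real_end[i]))
        expect_identical(alnSeqs(concatColumns(iParts)), alnSeqs(pr$a))
        expect_identical(alnSeqs(concatColumns(rParts)), alnSeqs(pr$b))
        for (i in which(part$type == "changed"))
            expect_identical(removeGaps(iParts[[i]]), removeGaps(rParts[[i]]))
        for (i in which(part$type == "anchor"))
            expect_identical(alnSeqs(iParts[[i]]), alnSeqs(rParts[[i]]))
    }
})

test_that("column matching and chaining agree with the brute-force oracle", {
    set.seed(77)
    for (k in 1:120) {
        pr <- randAlnPair(sample(2:6, 1), sample(1:12, 1),
                          gapProb = runif(1, 0.1, 0.5))
        Pi <- mapPositions(pr$a); Pr <- mapPositions(pr$b)
        got <- matchIdenticalColumns(Pi, Pr)
        want <- bruteMatches(Pi, Pr)
        expect_equal(got$init, want$init)
        expect_equal(got$real, want$real)
        expect_equal(chainUnchangedIntervals(got, 2),
                     bruteRuns(want, 2), ignore_attr = TRUE)
    }
})
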