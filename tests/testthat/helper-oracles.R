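# Shared fixtures and independent brute-force oracles for the test suite.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Random gapped alignment (uses the ambient RNG; callers set the seed).
randAln <- function(nrow = 4, ncol = 10, gapProb = 0.25) {
    m <- matrix(sample(AA20, nrow * ncol, replace = TRUE), nrow = nrow)
    gaps <- matrix(runif(nrow * ncol) < gapProb, nrow = nrow)
    m[gaps] <- "-"
    GappedAlignment(sprintf("s%02d", seq_len(nrow)),
                    apply(m, 1, paste, collapse = ""))
}

# Two random gappings of the same ungapped sequences (for region detection).
randAlnPair <- function(nrow = 4, ncol = 10, gapProb = 0.25) {
    a <- randAln(nrow, ncol, gapProb)
    seqs <- removeGaps(a)
    w <- max(nchar(seqs)) + sample(0:3, 1)
    rows <- vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        out <- rep("-", w)
        if (length(ch) > 0)
            out[sort(sample.int(w, length(ch)))] <- ch
        paste(out, collapse = "")
    }, "")
    list(a = a, b = GappedAlignment(alnIds(a), unname(rows)))
}

# --- sum-of-pairs oracles -------------------------------------------------

# Ordered-pair column score by direct double loop over pairScore.
bruteColumnScore <- function(col, p) {
    s <- 0
    M <- length(col)
    for (i in seq_len(M)) for (j in seq_len(M))
        if (i != j) s <- s + pairScore(col[i], col[j], p)
    s
}

# Unordered pairs x 2 (the equivalent reading of the column formula).
bruteUnorderedColumnScore <- function(col, p) {
    s <- 0
    M <- length(col)
    if (M < 2) return(0)
    for (i in seq_len(M - 1)) for (j in (i + 1):M)
        s <- s + pairScore(col[i], col[j], p)
    2 * s
}

bruteSpScore <- function(frag, p) {
    m <- as.matrix(frag)
    s <- 0
    for (l in seq_len(ncol(m))) s <- s + bruteColumnScore(m[, l], p)
    s
}

# --- region-detection oracles ---------------------------------------------

# All-pairs column-vector comparison, excluding all-zero columns.
bruteMatches <- function(pInit, pReal) {
    out <- NULL
    for (ci in seq_len(ncol(pInit))) {
        if (all(pInit[, ci] == 0)) next
        for (cr in seq_len(ncol(pReal))) {
            if (all(pReal[, cr] == 0)) next
            if (all(pInit[, ci] == pReal[, cr]))
                out <- rbind(out, c(ci, cr))
        }
    }
    if (is.null(out))
        data.frame(init = integer(0), real = integer(0))
    else
        data.frame(init = out[, 1], real = out[, 2])
}

# Run scanning over matches: consecutive +1 steps in both coordinates.
bruteRuns <- function(matches, minLen = 2) {
    n <- nrow(matches)
    runs <- list()
    k <- 1
    while (k <= n) {
        e <- k
        while (e < n && matches$init[e + 1] == matches$init[e] + 1 &&
               matches$real[e + 1] == matches$real[e] + 1)
            e <- e + 1
        if (e - k + 1 >= minLen)
            runs[[length(runs) + 1]] <- data.frame(
                init_start = matches$init[k], init_end = matches$init[e],
                real_start = matches$real[k], real_end = matches$real[e])
        k <- e + 1
    }
    if (length(runs) == 0)
        data.frame(init_start = integer(0), init_end = integer(0),
                   real_start = integer(0), real_end = integer(0))
    else do.call(rbind, runs)
}

# --- evaluation oracles ---------------------------------------------------

# Residue-pair set of an alignment as character keys "i|j|pi|pj", walking
# the character matrix with explicit per-row residue counters.
.pairKeys <- function(m, core = NULL) {
    n <- nrow(m)
    cnt <- rep(0L, n)
    keys <- character(0)
    for (cc in seq_len(ncol(m))) {
        res <- m[, cc] != "-"
        cnt[res] <- cnt[res] + 1L
        rows <- which(res)
        if (!is.null(core)) rows <- rows[core[rows, cc]]
        if (length(rows) >= 2)
            for (a in seq_len(length(rows) - 1))
                for (b in (a + 1):length(rows)) {
                    i <- rows[a]; j <- rows[b]
                    keys <- c(keys, paste(i, j, cnt[i], cnt[j], sep = "|"))
                }
    }
    keys
}

bruteQ <- function(test, ref) {
    test <- reorderToMatch(test, refAlignment(ref))
    refK <- .pairKeys(as.matrix(refAlignment(ref)), ref@core)
    testK <- .pairKeys(as.matrix(test))
    if (length(refK) == 0) return(0)
    sum(refK %in% testK) / length(refK)
}

bruteTC <- function(test, ref) {
    test <- reorderToMatch(test, refAlignment(ref))
    mr <- as.matrix(refAlignment(ref))
    mt <- as.matrix(test)
    cntR <- rep(0L, nrow(mr))
    # per-column "row|pos" sets of the test alignment
    cntT <- rep(0L, nrow(mt))
    testCols <- lapply(seq_len(ncol(mt)), function(cc) {
        res <- which(mt[, cc] != "-")
        cntT[res] <<- cntT[res] + 1L
        paste(res, cntT[res], sep = "|")
    })
    scorable <- 0; hit <- 0
    for (cc in seq_len(ncol(mr))) {
        res <- which(mr[, cc] != "-")
        cntR[res] <- cntR[res] + 1L
        rows <- res[ref@core[res, cc]]
        if (length(rows) == 0) next
        scorable <- scorable + 1
        want <- paste(rows, cntR[rows], sep = "|")
        if (any(vapply(testCols, function(tc) all(want %in% tc), TRUE)))
            hit <- hit + 1
    }
    if (scorable == 0) return(0)
    hit / scorable
}

# --- mock backends --------------------------------------------------------

# Deterministic "staircase" layout: each sequence on its own diagonal.
# A valid but deliberately poor alignment, fixed for a given input.
diagonalBackend <- function() {
    backendSpec("diagonal", fun = function(seqs) {
        lens <- nchar(seqs)
        W <- sum(lens)
        off <- cumsum(c(0, lens[-length(lens)]))
        rows <- vapply(seq_along(seqs), function(i)
            paste0(strrep("-", off[i]), seqs[i],
                   strrep("-", W - off[i] - lens[i])), "")
        GappedAlignment(names(seqs), rows)
    })
}

# Backend that reproduces a fixed alignment (for fixed-point checks).
echoBackendFor <- function(aln) {
    backendSpec("echo", fun = function(seqs) aln)
}
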