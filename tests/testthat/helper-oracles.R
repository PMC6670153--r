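# Independent brute-force oracles. Each deliberately takes the dumbest
# correct route (per-base marking, explicit per-window products, exhaustive
# path enumeration) so that agreement with the package's vectorized /
# DP implementations is informative.

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# per-base prevalence oracle: mark every covered base per cell type, then
# ask per module whether any base in the module is covered.
oraclePrevalence <- function(bins0, hotspots0) {
    # bins0: data.frame start,end (0-based half-open); hotspots0: data.frame
    # start,end,cell_type. Returns integer per bin.
    counts <- integer(nrow(bins0))
    cts <- unique(hotspots0$cell_type)
    L <- max(c(bins0$end, hotspots0$end, 0L))
    for (ct in cts) {
        cov <- rep(FALSE, L)
        hs <- hotspots0[hotspots0$cell_type == ct, , drop = FALSE]
        for (k in seq_len(nrow(hs))) {
            lo <- max(hs$start[k] + 1L, 1L)
            hi <- min(hs$end[k], L)
            if (lo <= hi) cov[lo:hi] <- TRUE
        }
        for (b in seq_len(nrow(bins0))) {
            if (any(cov[(bins0$start[b] + 1L):bins0$end[b]]))
                counts[b] <- counts[b] + 1L
        }
    }
    counts
}

# explicit per-window PWM score oracle (probability products, no
# vectorization), both-strand scan at a cutoff
oracleScoreWindow <- function(pwm, window) {
    p <- pwmProbs(pwm)
    lk <- cbind(p, N = apply(p, 1, min))
    ch <- strsplit(window, "")[[1]]
    num <- 1
    den <- 1
    for (i in seq_len(nrow(p))) {
        num <- num * lk[i, ch[i]]
        den <- den * max(p[i, ])
    }
    unname(num / den)
}

oracleScan <- function(sequence, pwm, cutoff, strands = c("+", "-")) {
    w <- pwmWidth(pwm)
    L <- nchar(sequence)
    out <- list()
    tol <- 1e-9
    scanOne <- function(s, strandLab) {
        hits <- list()
        if (nchar(s) >= w) {
            for (i in 1:(nchar(s) - w + 1)) {
                sc <- oracleScoreWindow(pwm, substr(s, i, i + w - 1))
                if (sc >= cutoff - tol) {
                    ctr <- (i - 1) + pwmCenter(pwm)
                    center <- if (strandLab == "+") ctr else L - 1 - ctr
                    hits[[length(hits) + 1]] <-
                        data.frame(center = center, strand = strandLab,
                                   score = sc)
                }
            }
        }
        hits
    }
    if ("+" %in% strands) out <- c(out, scanOne(sequence, "+"))
    if ("-" %in% strands) out <- c(out, scanOne(revComp(sequence), "-"))
    if (!length(out))
        return(data.frame(center = integer(), strand = character(),
                          score = numeric()))
    res <- do.call(rbind, out)
    res <- res[order(res$center, res$strand), , drop = FALSE]
    rownames(res) <- NULL
    res
}

# sliding-window primer-site oracle with the 3'-terminal-match rule;
# N in the template never matches
oracleSites <- function(template, primer, maxMismatch) {
    tch <- strsplit(template, "")[[1]]
    hitsFor <- function(pat, strandLab, threePrimeAt) {
        pch <- strsplit(pat, "")[[1]]
        m <- length(pch)
        out <- integer(0)
        if (m <= length(tch)) {
            for (p in 0:(length(tch) - m)) {
                win <- tch[(p + 1):(p + m)]
                mm <- sum(win != pch | win == "N")
                tpOk <- if (threePrimeAt == "right")
                    win[m] == pch[m] && win[m] != "N"
                else win[1] == pch[1] && win[1] != "N"
                if (mm <= maxMismatch && tpOk) out <- c(out, p)
            }
        }
        if (length(out)) data.frame(position = out, strand = strandLab)
        else data.frame(position = integer(), strand = character())
    }
    out <- rbind(hitsFor(primer, "+", "right"),
                 hitsFor(revComp(primer), "-", "left"))
    out <- out[order(out$position, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# exhaustive alignment-path enumeration. Gap columns while the other
# sequence has not started (index still 1) or is exhausted are end gaps;
# with freeEnds they cost 0. Returns the maximum score over all paths.
oracleAlignScore <- function(a, b, match = 1, mismatch = -1, gap = -2,
                             freeEnds = TRUE) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    m <- length(A)
    n <- length(B)
    best <- -Inf
    rec <- function(i, j, score) {
        if (i > m && j > n) {
            if (score > best) best <<- score
            return(invisible())
        }
        if (i <= m && j <= n)
            rec(i + 1, j + 1,
                score + if (A[i] == B[j]) match else mismatch)
        if (i <= m) {   # A[i] against a gap in b's row
            cost <- if (freeEnds && (j == 1 || j > n)) 0 else gap
            rec(i + 1, j, score + cost)
        }
        if (j <= n) {   # gap in a's row
            cost <- if (freeEnds && (i == 1 || i > m)) 0 else gap
            rec(i, j + 1, score + cost)
        }
    }
    rec(1L, 1L, 0)
    best
}

# local-alignment oracle: best strict global score over all substring pairs
oracleLocalScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    m <- nchar(a)
    n <- nchar(b)
    best <- 0
    for (i in 1:m) for (j in i:m) for (k in 1:n) for (l in k:n) {
        sc <- oracleAlignScore(substr(a, i, j), substr(b, k, l),
                               match, mismatch, gap, freeEnds = FALSE)
        if (sc > best) best <- sc
    }
    best
}

# direct per-position membership count for TSS / hit assignment
oracleMembership <- function(positions, bins0) {
    vapply(seq_len(nrow(bins0)), function(i)
        sum(positions >= bins0$start[i] & positions < bins0$end[i]), 1L)
}

grRegion <- function(chrom, start0, end0, name = "r") {
    r <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
    names(r) <- name
    r
}

hotspotGRanges <- function(df, chrom = "chrT", assay = "DNASE") {
    if (!nrow(df)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            cell_type = character(), assay = character())
        return(gr)
    }
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(df$start + 1L, df$end),
        cell_type = df$cell_type, assay = assay)
}
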