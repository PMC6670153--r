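#' Construct an initiator-element PWM
#'
#' @param mat numeric matrix of per-position base frequencies, columns
#'   `A,C,G,T` (rows summing to 1), one row per motif position.
#' @param pseudocount smoothing constant (default 0.01).
#' @param center 0-based offset of the +1 base within the motif.
#' @param source provenance string.
#' @return an [InrPWM-class].
#' @export
inrPWM <- function(mat, pseudocount = 0.01, center = 2L,
                   source = "user-supplied") {
    mat <- as.matrix(mat)
    if (is.null(colnames(mat))) colnames(mat) <- c("A", "C", "G", "T")
    methods::new("InrPWM", mat = mat, pseudocount = pseudocount,
                 center = as.integer(center), source = source)
}

#' The default initiator (INR) matrix
#'
#' Loads the hand-curated 7-position frequency matrix shipped with the
#' package (`inst/extdata/inr_pwm.tsv`), consistent with the canonical
#' initiator consensus YYANWYY — a pyrimidine-rich element with the +1
#' (transcription start) adenine at motif offset 2. Promoter-prediction
#' tools keep their own internal matrices; scan results therefore depend on
#' the matrix used, which is why it is a configurable input here.
#'
#' @param pseudocount smoothing constant (default 0.01).
#' @return an [InrPWM-class].
#' @export
inrDefaultPWM <- function(pseudocount = 0.01) {
    readPWM(system.file("extdata", "inr_pwm.tsv", package = "IntraProm"),
            pseudocount = pseudocount)
}

#' Read a PWM from a tab-delimited file
#'
#' Format: optional `#`-prefixed provenance header lines (a line of the form
#' `# center=<i>` sets the 0-based +1 offset), a header row `A C G T`, then
#' one row of frequencies (or counts; rows are normalized) per position.
#'
#' @param file path.
#' @param pseudocount smoothing constant.
#' @return an [InrPWM-class].
#' @export
readPWM <- function(file, pseudocount = 0.01) {
    lines <- readLines(file)
    hdr <- lines[grepl("^#", lines)]
    center <- 2L
    m <- regmatches(hdr, regexpr("center=\\d+", hdr))
    if (length(m))
        center <- as.integer(sub("center=", "", m[[1L]]))
    df <- read.delim(textConnection(lines[!grepl("^#", lines)]))
    mat <- as.matrix(df[, c("A", "C", "G", "T")])
    mat <- mat / rowSums(mat)
    inrPWM(mat, pseudocount = pseudocount, center = center,
           source = paste0("file: ", basename(file),
                           if (length(hdr)) paste0(" (", sub("^#\\s*", "",
                               hdr[1L]), ")") else ""))
}

#' Consensus (per-position argmax) string of a PWM
#'
#' @param pwm an [InrPWM-class].
#' @return character, the maximum-scoring window (first base on ties).
#' @export
pwmConsensus <- function(pwm) {
    p <- pwmProbs(pwm)
    paste(colnames(p)[apply(p, 1L, which.max)], collapse = "")
}

# probability lookup including the N column (minimum of the row)
pwmLookup <- function(pwm) {
    p <- pwmProbs(pwm)
    cbind(p, N = apply(p, 1L, min))
}

#' Score one window against an INR matrix
#'
#' Max-ratio normalization: `score = prod(p_i(w_i)) / prod(max_b p_i(b))`,
#' so the consensus-maximal window scores exactly 1 and a cutoff such as
#' 0.99 admits only near-consensus windows. `N` scores as the minimum
#' probability of its column (conservative handling of ambiguity).
#'
#' @param pwm an [InrPWM-class].
#' @param window character of length `pwmWidth(pwm)` over `A,C,G,T,N`.
#' @return numeric score in `[0, 1]`.
#' @export
scoreWindow <- function(pwm, window) {
    window <- checkSeq(window)
    w <- pwmWidth(pwm)
    if (nchar(window) != w)
        stop("window length ", nchar(window), " != motif width ", w)
    lk <- pwmLookup(pwm)
    idx <- match(strsplit(window, "")[[1L]], colnames(lk))
    prod(lk[cbind(seq_len(w), idx)]) / prod(apply(lk[, 1:4], 1L, max))
}

# vectorized per-window scores on one strand; returns numeric of
# length nchar(seq) - w + 1 (empty when shorter than the motif)
scanScores <- function(seqchars, lk, maxlog) {
    n <- length(seqchars)
    w <- nrow(lk)
    if (n < w) return(numeric())
    idx <- match(seqchars, colnames(lk))
    loglk <- log(lk)
    nwin <- n - w + 1L
    acc <- numeric(nwin)
    for (i in seq_len(w))
        acc <- acc + loglk[cbind(i, idx[i:(i + nwin - 1L)])]
    exp(acc - maxlog)
}

#' Scan a sequence for initiator elements
#'
#' Slides the motif over every window of the sequence (both strands by
#' default; minus-strand windows are scored on the reverse complement and
#' their centers mapped back to forward coordinates) and reports every
#' window whose normalized score reaches the cutoff. Overlapping hits are
#' all retained. The reported `center` is the 0-based forward-strand offset
#' of the motif's +1 base.
#'
#' @param sequence character, the sequence to scan (`A,C,G,T,N`).
#' @param pwm an [InrPWM-class].
#' @param cutoff score threshold in `(0, 1]` (default 0.99).
#' @param strands subset of `c("+", "-")`.
#' @return data.frame with columns `center` (0-based), `strand`, `score`,
#'   sorted by center.
#' @export
scanInr <- function(sequence, pwm, cutoff = 0.99, strands = c("+", "-")) {
    if (cutoff <= 0 || cutoff > 1)
        stop("cutoff must lie in (0, 1]")
    if (!length(strands) || !all(strands %in% c("+", "-")))
        stop("strands must be a non-empty subset of c('+', '-')")
    sequence <- checkSeq(sequence)
    empty <- data.frame(center = integer(), strand = character(),
                        score = numeric())
    if (!nzchar(sequence)) return(empty)
    lk <- pwmLookup(pwm)
    maxlog <- sum(log(apply(lk[, 1:4], 1L, max)))
    w <- pwmWidth(pwm)
    cOff <- pwmCenter(pwm)
    L <- nchar(sequence)
    tol <- 1e-9  # absorb float round-off at score == 1
    out <- list()
    if ("+" %in% strands) {
        sc <- scanScores(strsplit(sequence, "")[[1L]], lk, maxlog)
        keep <- which(sc >= cutoff - tol)
        if (length(keep))
            out$plus <- data.frame(center = keep - 1L + cOff,
                                   strand = "+", score = sc[keep])
    }
    if ("-" %in% strands) {
        rc <- revComp(sequence)
        sc <- scanScores(strsplit(rc, "")[[1L]], lk, maxlog)
        keep <- which(sc >= cutoff - tol)
        if (length(keep))
            out$minus <- data.frame(center = L - 1L - (keep - 1L + cOff),
                                    strand = "-", score = sc[keep])
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    res <- res[order(res$center, res$strand), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Assign hits to subregions by center membership
#'
#' A hit belongs to every subregion whose half-open interval contains its
#' center (subregions may overlap); hits in no subregion are tallied under
#' `"outside"`. This is the colocalization rule used to say a motif "falls
#' within" a breakpoint cluster region.
#'
#' @param hits data.frame from [scanInr()] (needs a `center` column), in the
#'   same coordinate frame as `subregions`.
#' @param subregions data.frame with columns `name`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame with columns `name`, `count`; the last row is
#'   `"outside"`.
#' @export
hitsInRegions <- function(hits, subregions) {
    centers <- hits$center
    if (is.null(subregions) || nrow(as.data.frame(subregions)) == 0L) {
        return(data.frame(name = "outside", count = length(centers)))
    }
    subregions <- as.data.frame(subregions)
    inAny <- rep(FALSE, length(centers))
    counts <- integer(nrow(subregions))
    for (i in seq_len(nrow(subregions))) {
        inside <- centers >= subregions$start[i] & centers < subregions$end[i]
        counts[i] <- sum(inside)
        inAny <- inAny | inside
    }
    rbind(data.frame(name = subregions$name, count = counts),
          data.frame(name = "outside", count = sum(!inAny)))
}

#' Write INR hits as BED6
#'
#' One 1-bp feature per hit center, score scaled by 1000 and truncated to
#' integer, name `INR`.
#'
#' @param hits data.frame from [scanInr()].
#' @param chrom chromosome name for the output.
#' @param offset 0-based genomic position of sequence offset 0.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeInrBed <- function(hits, chrom, offset, file) {
    df <- data.frame(chrom = chrom,
                     start = hits$center + offset,
                     end = hits$center + offset + 1L,
                     name = "INR",
                     score = as.integer(hits$score * 1000),
                     strand = hits$strand)
    write.table(df, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(file)
}
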