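#' Read an EST table
#'
#' Tab-delimited with header columns `accession`, `chrom`, `start`, `end`
#' (0-based half-open genomic span), `strand`, and optionally `sequence`.
#'
#' @param file path.
#' @return data.frame in file order.
#' @export
readEstTable <- function(file) {
    df <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("accession", "chrom", "start", "end", "strand")
    if (!all(need %in% names(df)))
        stop("EST table must have columns: ", paste(need, collapse = ", "))
    if (!all(df$strand %in% c("+", "-")))
        stop("EST strand must be '+' or '-'")
    df
}

#' Select ESTs by region/strand or by explicit accession list
#'
#' Without `accessions`: keeps ESTs overlapping the region by >= 1 bp whose
#' genomic strand matches `strand` (either filter may be omitted). With
#' `accessions`: returns exactly those records, in table order, erroring on
#' missing ids — the mode used when a hand-picked antisense set is named.
#'
#' @param ests data.frame as from [readEstTable()].
#' @param region `GRanges` of length 1, or `NULL`.
#' @param strand `"+"`, `"-"`, or `NULL` for both.
#' @param accessions character vector of accession ids, or `NULL`.
#' @return subset data.frame.
#' @export
selectEsts <- function(ests, region = NULL, strand = NULL,
                       accessions = NULL) {
    if (!is.null(accessions)) {
        miss <- setdiff(accessions, ests$accession)
        if (length(miss))
            stop("accession(s) not in table: ", paste(miss, collapse = ", "))
        return(ests[ests$accession %in% accessions, , drop = FALSE])
    }
    keep <- rep(TRUE, nrow(ests))
    if (!is.null(region)) {
        stopifnot(length(region) == 1L)
        keep <- keep & ests$chrom == as.character(seqnames(region)) &
            ests$start < end(region) & ests$end > (start(region) - 1L)
    }
    if (!is.null(strand))
        keep <- keep & ests$strand == strand
    ests[keep, , drop = FALSE]
}

#' Pairwise alignment with free end gaps
#'
#' Optimal global alignment under a linear scoring scheme in which leading
#' and trailing gaps in either sequence are free — the natural model for two
#' fragments of one transcript that overlap only partially. Traceback
#' tie-break is diagonal > up > left, so output is deterministic.
#'
#' @param a,b character sequences (non-empty).
#' @param match,mismatch,gap scoring scheme (defaults +1 / -1 / -2).
#' @return list with `score`, `a`, `b` (gapped strings of equal length).
#' @export
pairwiseAlign <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    if (!nzchar(a) || !nzchar(b))
        stop("sequences must be non-empty")
    .alignOverlapC(toupper(a), toupper(b), match, mismatch, gap)
}

#' Best local alignment of a query against one subject
#'
#' Smith-Waterman under the same scoring scheme; ties in cell choice resolve
#' to the first-filled cell, ties in traceback to diagonal > up > left.
#'
#' @inheritParams pairwiseAlign
#' @return list with `score`, gapped `a`/`b`, 0-based half-open aligned
#'   spans `a_start`/`a_end`/`b_start`/`b_end`, and `identity` over aligned
#'   columns.
#' @export
localAlign <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    if (!nzchar(a) || !nzchar(b))
        stop("sequences must be non-empty")
    r <- .alignLocalC(toupper(a), toupper(b), match, mismatch, gap)
    r$identity <- if (r$n_cols > 0) r$n_match / r$n_cols else 0
    r
}

# gap profile of the center row of one pairwise alignment: for a center of
# n residues, insEvents[k+1] (k = 0..n) counts gap columns between center
# residue k and k+1 (k = 0: before the first residue), and chars holds the
# partner characters at those columns plus the partner character aligned to
# each center residue.
centerGapProfile <- function(gc, gs) {
    cc <- strsplit(gc, "")[[1L]]
    sc <- strsplit(gs, "")[[1L]]
    n <- sum(cc != "-")
    ins <- integer(n + 1L)
    insChars <- vector("list", n + 1L)
    resChars <- character(n)
    k <- 0L
    for (i in seq_along(cc)) {
        if (cc[i] == "-") {
            ins[k + 1L] <- ins[k + 1L] + 1L
            insChars[[k + 1L]] <- c(insChars[[k + 1L]], sc[i])
        } else {
            k <- k + 1L
            resChars[k] <- sc[i]
        }
    }
    list(ins = ins, insChars = insChars, resChars = resChars)
}

#' Center-star multiple alignment
#'
#' Classic center-star construction: the center is the sequence maximizing
#' its summed pairwise alignment score against all others; every other
#' sequence is aligned to the center with [pairwiseAlign()] and the pairwise
#' alignments are merged under "once a gap, always a gap" (between two
#' center residues, every row reserves as many columns as the widest
#' insertion any row makes there; shorter insertions are right-padded with
#' gaps). Row order equals input order, and removing gaps from any row
#' reproduces its input sequence exactly. The center's pairwise score
#' against each row is preserved by the merge.
#'
#' @param sequences character vector (>= 2 sequences) or named vector; names
#'   become row ids.
#' @param match,mismatch,gap scoring scheme passed to the pairwise aligner.
#' @return a [Biostrings::DNAMultipleAlignment] whose rows degap to the
#'   inputs; attribute `center` holds the index of the center sequence.
#' @export
buildMsa <- function(sequences, match = 1, mismatch = -1, gap = -2) {
    if (length(sequences) < 2L)
        stop("need at least 2 sequences")
    sequences <- toupper(sequences)
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
    m <- length(sequences)
    # summed pairwise score per candidate center
    scores <- matrix(0, m, m)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
        sc <- pairwiseAlign(sequences[i], sequences[j],
                            match, mismatch, gap)$score
        scores[i, j] <- sc
        scores[j, i] <- sc
    }
    center <- which.max(rowSums(scores))
    others <- setdiff(seq_len(m), center)
    profs <- lapply(others, function(i) {
        al <- pairwiseAlign(sequences[center], sequences[i],
                            match, mismatch, gap)
        centerGapProfile(al$a, al$b)
    })
    n <- nchar(sequences[center])
    masterIns <- integer(n + 1L)
    for (p in profs) masterIns <- pmax(masterIns, p$ins)
    cres <- strsplit(sequences[center], "")[[1L]]
    buildRow <- function(prof) {
        out <- character(0)
        for (k in 0:n) {
            blk <- c(prof$insChars[[k + 1L]],
                     rep("-", masterIns[k + 1L] - prof$ins[k + 1L]))
            out <- c(out, blk)
            if (k < n) out <- c(out, prof$resChars[k + 1L])
        }
        paste(out, collapse = "")
    }
    centerRow <- {
        out <- character(0)
        for (k in 0:n) {
            out <- c(out, rep("-", masterIns[k + 1L]))
            if (k < n) out <- c(out, cres[k + 1L])
        }
        paste(out, collapse = "")
    }
    rows <- character(m)
    rows[center] <- centerRow
    rows[others] <- vapply(profs, buildRow, character(1))
    msa <- DNAMultipleAlignment(DNAStringSet(setNames(rows, ids)))
    attr(msa, "center") <- unname(center)
    msa
}

# rows of an MSA as a plain character vector
msaRows <- function(msa) {
    if (methods::is(msa, "DNAMultipleAlignment"))
        as.character(methods::as(msa, "DNAStringSet"))
    else as.character(msa)
}

#' Call a consensus sequence from a multiple alignment
#'
#' Per column, over non-gap residues: columns with depth below `minDepth`
#' (or all gaps) are dropped; otherwise the majority residue is called when
#' its support (fraction of non-gap residues agreeing) reaches `minSupport`,
#' and `N` when it does not or when the top count is tied. Defaults
#' (`minDepth = 2`, `minSupport = 0.5` with ties to `N`) are conservative
#' for noisy single-pass ESTs.
#'
#' @param msa a `DNAMultipleAlignment` from [buildMsa()] or a character
#'   vector of equal-length gapped rows.
#' @param minDepth minimum non-gap residues for a column to be called.
#' @param minSupport minimum agreeing fraction for a residue call.
#' @return a [ConsensusResult-class].
#' @export
callConsensus <- function(msa, minDepth = 2L, minSupport = 0.5) {
    rows <- msaRows(msa)
    if (!length(rows))
        stop("empty alignment")
    if (length(unique(nchar(rows))) != 1L)
        stop("alignment rows must have equal length")
    chars <- do.call(rbind, strsplit(rows, ""))
    L <- ncol(chars)
    seqOut <- character(0)
    support <- numeric(0)
    depth <- integer(0)
    columns <- integer(0)
    for (j in seq_len(L)) {
        col <- chars[, j]
        res <- col[col != "-"]
        d <- length(res)
        if (d == 0L || d < minDepth) next
        tabd <- table(res)
        top <- max(tabd)
        winners <- names(tabd)[tabd == top]
        supp <- top / d
        call <- if (length(winners) > 1L || supp < minSupport) "N"
                else winners[1L]
        seqOut <- c(seqOut, call)
        support <- c(support, supp)
        depth <- c(depth, d)
        columns <- c(columns, j)
    }
    methods::new("ConsensusResult", sequence = paste(seqOut, collapse = ""),
                 support = support, depth = as.integer(depth),
                 columns = as.integer(columns))
}

#' Match a consensus against a transcript set
#'
#' Highest-scoring local alignment of the consensus against each transcript
#' (same scoring scheme as the pairwise aligner); the single best transcript
#' is reported, ties broken by input order. Identity is computed over
#' aligned columns. A `below_threshold` flag marks matches whose identity
#' falls below `minIdentity`.
#'
#' @param consensus a [ConsensusResult-class] or character sequence.
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   transcript sequences.
#' @param match,mismatch,gap scoring scheme.
#' @param minIdentity identity threshold for the flag (default 0.5).
#' @return data.frame with one row: `transcript`, `score`, `identity`,
#'   `t_start`, `t_end` (0-based half-open on the transcript),
#'   `below_threshold`.
#' @export
matchConsensus <- function(consensus, transcripts, match = 1, mismatch = -1,
                           gap = -2, minIdentity = 0.5) {
    if (methods::is(consensus, "ConsensusResult"))
        consensus <- consensusSequence(consensus)
    if (methods::is(transcripts, "DNAStringSet"))
        transcripts <- as.character(transcripts)
    if (!length(transcripts))
        stop("transcript set must be non-empty")
    ids <- names(transcripts)
    if (is.null(ids)) ids <- paste0("tx", seq_along(transcripts))
    best <- NULL
    for (i in seq_along(transcripts)) {
        r <- localAlign(consensus, transcripts[[i]], match, mismatch, gap)
        if (is.null(best) || r$score > best$score) {
            best <- r
            best$id <- ids[i]
        }
    }
    data.frame(transcript = best$id, score = best$score,
               identity = best$identity,
               t_start = best$b_start, t_end = best$b_end,
               below_threshold = best$identity < minIdentity)
}

#' Orient ESTs into transcript coordinates
#'
#' ESTs recorded on the genomic minus strand are reverse-complemented so
#' that all sequences read in the orientation of the transcript they
#' evidence; used before building a multiple alignment of a stranded set.
#'
#' @param ests data.frame with `sequence` and `strand` columns.
#' @param transcriptStrand genomic strand of the transcript being
#'   reconstructed.
#' @return named character vector of oriented sequences (names =
#'   accessions).
#' @export
orientEsts <- function(ests, transcriptStrand = "+") {
    if (is.null(ests$sequence) || any(!nzchar(ests$sequence)))
        stop("ESTs must carry sequences")
    seqs <- toupper(ests$sequence)
    flip <- ests$strand != transcriptStrand
    seqs[flip] <- revComp(seqs[flip])
    setNames(seqs, ests$accession)
}
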