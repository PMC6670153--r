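#' Find primer binding sites on a template
#'
#' Reports every position where the primer matches the template forward
#' strand, and every position where its reverse complement matches (a
#' reverse-strand site), with at most `maxMismatch` mismatches and no
#' indels. The primer's 3'-terminal base must match exactly (a polymerase
#' cannot extend a mismatched 3' end), and `N` in the template never
#' matches. A primer longer than the template yields no sites.
#'
#' @param template character template sequence (`A,C,G,T,N`).
#' @param primer character primer, written 5' to 3' (`A,C,G,T`).
#' @param maxMismatch maximum mismatches outside the 3'-terminal base
#'   (default 0).
#' @return data.frame with columns `position` (0-based offset of the
#'   leftmost template base of the site) and `strand` (`"+"` if the primer
#'   itself matches, `"-"` if its reverse complement does).
#' @export
findSites <- function(template, primer, maxMismatch = 0L) {
    if (maxMismatch < 0L) stop("maxMismatch must be >= 0")
    template <- checkSeq(template)
    primer <- checkSeq(primer, allowN = FALSE)
    empty <- data.frame(position = integer(), strand = character())
    if (nchar(primer) > nchar(template)) return(empty)
    subj <- DNAString(template)
    plen <- nchar(primer)
    hitDf <- function(pattern, strand) {
        m <- matchPattern(DNAString(pattern), subj,
                          max.mismatch = maxMismatch, fixed = TRUE)
        pos <- start(m) - 1L
        if (!length(pos)) return(empty)
        # 3'-terminal base of the primer: rightmost template base of a "+"
        # site, leftmost of a "-" site (where the pattern is revcomp(primer))
        tchars <- strsplit(template, "")[[1L]]
        ok <- if (strand == "+")
            tchars[pos + plen] == substr(primer, plen, plen)
        else
            tchars[pos + 1L] == substr(revComp(primer), 1L, 1L)
        pos <- pos[ok]
        if (!length(pos)) return(empty)
        data.frame(position = pos, strand = rep(strand, length(pos)))
    }
    out <- rbind(hitDf(primer, "+"), hitDf(revComp(primer), "-"))
    out <- out[order(out$position, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Predict PCR amplicons from a primer pair
#'
#' Combines every forward-strand site of the forward primer with every
#' reverse-strand site of the reverse primer lying 3' of it; each pairing
#' whose product length is at most `maxLen` yields one amplicon spanning
#' from the forward primer's 5' base to the reverse primer's 5' base
#' (0-based half-open on the template). Thermodynamics is deliberately not
#' modelled; matching is purely sequence-based.
#'
#' @param template character template sequence (or named length-1 vector;
#'   the name becomes the template id).
#' @param pair list or named character vector with elements `name`
#'   (optional), `forward`, `reverse` (both 5' to 3').
#' @param maxLen maximum product length in bp (default 5000, suppressing
#'   spurious distant pairings).
#' @param maxMismatch maximum mismatches per primer outside the 3' base.
#' @param templateId id used in the report.
#' @return data.frame sorted by length with columns `template`, `start`,
#'   `end` (0-based half-open), `length`, `sequence`.
#' @export
predictAmplicons <- function(template, pair, maxLen = 5000L,
                             maxMismatch = 0L, templateId = NULL) {
    if (maxLen <= 0L) stop("maxLen must be > 0")
    if (is.null(templateId))
        templateId <- if (!is.null(names(template))) names(template)[1L]
                      else "template"
    template <- checkSeq(template[[1L]])
    fwd <- toupper(pair[["forward"]])
    rev <- toupper(pair[["reverse"]])
    if (nchar(fwd) < 10L || nchar(rev) < 10L)
        stop("primers must be at least 10 nt")
    fSites <- findSites(template, fwd, maxMismatch)
    rSites <- findSites(template, rev, maxMismatch)
    fPos <- fSites$position[fSites$strand == "+"]
    rPos <- rSites$position[rSites$strand == "-"]
    out <- data.frame(template = character(), start = integer(),
                      end = integer(), length = integer(),
                      sequence = character())
    lenR <- nchar(rev)
    lenF <- nchar(fwd)
    for (p in fPos) for (q in rPos) {
        e <- q + lenR
        if (q >= p + lenF && (e - p) <= maxLen) {
            out <- rbind(out, data.frame(
                template = templateId, start = p, end = e,
                length = e - p,
                sequence = substr(template, p + 1L, e)))
        }
    }
    out <- out[order(out$length, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read primer pairs from a YAML config or FASTA
#'
#' YAML layout: a top-level `primer_pairs` list (or a bare list) of entries
#' with `name`, `forward`, `reverse`. FASTA layout: records named
#' `<pair>_F` / `<pair>_R`. Whitespace inside primer strings is stripped.
#'
#' @param file path ending in `.yaml`/`.yml` or `.fa`/`.fasta`.
#' @return list of pairs, each a list with `name`, `forward`, `reverse`.
#' @export
readPrimerPairs <- function(file) {
    strip <- function(x) gsub("[[:space:]]", "", x)
    if (grepl("\\.ya?ml$", file)) {
        y <- yaml::read_yaml(file)
        if (!is.null(y$primer_pairs)) y <- y$primer_pairs
        return(lapply(y, function(p)
            list(name = p$name, forward = strip(p$forward),
                 reverse = strip(p$reverse))))
    }
    ss <- readDNAStringSet(file)
    nm <- names(ss)
    pairs <- unique(sub("_[FR]$", "", nm))
    lapply(pairs, function(p) {
        list(name = p,
             forward = as.character(ss[[paste0(p, "_F")]]),
             reverse = as.character(ss[[paste0(p, "_R")]]))
    })
}
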