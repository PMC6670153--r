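#' Load stranded TSS predictions from BED6
#'
#' Each record (which may be wider than 1 bp, as HMM-called TSS intervals
#' are) is reduced to a single representative position: its 5' end in
#' transcription sense, i.e. the interval start for `+` records and the last
#' base (`end - 1`, 0-based) for `-` records. Strand is mandatory.
#'
#' @param file path or connection to a BED6 file.
#' @param cell_type identifier attached to every record.
#' @return data.frame with columns `chrom`, `position` (0-based), `strand`,
#'   `cell_type`, in file order.
#' @export
loadTss <- function(file, cell_type = NA_character_) {
    lines <- readLines(file)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        return(data.frame(chrom = character(), position = integer(),
                          strand = character(), cell_type = character()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6L))
        stop("line ", lineno[which(nf < 6L)[1L]],
             ": BED6 required (strand missing)")
    strand <- vapply(fields, `[[`, character(1), 6L)
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad))
        stop("line ", lineno[bad[1L]], ": invalid strand '",
             strand[bad[1L]], "'")
    s <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
    e <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(s) | is.na(e) | s >= e)
    if (length(bad))
        stop("line ", lineno[bad[1L]], ": invalid interval")
    data.frame(chrom = vapply(fields, `[[`, character(1), 1L),
               position = ifelse(strand == "+", s, e - 1L),
               strand = strand,
               cell_type = rep(cell_type, length(s)))
}

#' Count TSS predictions per module, split by genomic strand
#'
#' Every prediction whose position falls inside a module (half-open
#' membership: a prediction at a boundary base belongs to the module that
#' starts there) increments that module's count for its strand. Predictions
#' are *not* deduplicated across cell types by default — the totals are sums
#' over all cell types, as cross-cell-type TSS surveys report them — and
#' predictions outside all modules are tallied separately. A `sense`
#' column translates genomic strand into sense relative to the module set's
#' declared gene strand.
#'
#' @param modules a [ModuleSet-class].
#' @param predictions data.frame from [loadTss()] (columns `chrom`,
#'   `position`, `strand`, optionally `cell_type`).
#' @param dedupe if `TRUE`, identical (position, strand) predictions from
#'   different cell types count once (default `FALSE`).
#' @return data.frame, one row per module in label order, columns
#'   `module_label`, `start`, `end`, `plus_count`, `minus_count`; attribute
#'   `outside` holds the number of predictions in no module (including those
#'   on other chromosomes).
#' @export
countTss <- function(modules, predictions, dedupe = FALSE) {
    stopifnot(methods::is(modules, "ModuleSet"))
    pred <- as.data.frame(predictions)
    if (nrow(pred) && dedupe)
        pred <- unique(pred[, c("chrom", "position", "strand")])
    bins <- modules@bins
    chrom <- as.character(seqnames(modules@region))
    s0 <- start(bins) - 1L
    e0 <- end(bins)
    n <- length(bins)
    plus <- integer(n)
    minus <- integer(n)
    assigned <- rep(FALSE, nrow(pred))
    if (nrow(pred)) {
        onChrom <- pred$chrom == chrom
        binOf <- rep(NA_integer_, nrow(pred))
        for (i in seq_len(n)) {
            inBin <- onChrom & pred$position >= s0[i] & pred$position < e0[i]
            binOf[inBin] <- i
        }
        assigned <- !is.na(binOf)
        if (any(assigned)) {
            plus <- vapply(seq_len(n), function(i)
                sum(binOf == i & pred$strand == "+", na.rm = TRUE), 1L)
            minus <- vapply(seq_len(n), function(i)
                sum(binOf == i & pred$strand == "-", na.rm = TRUE), 1L)
        }
    }
    ord <- order(as.integer(as.roman(mcols(bins)$label)))
    out <- data.frame(module_label = mcols(bins)$label,
                      start = s0, end = e0,
                      plus_count = plus, minus_count = minus)[ord, ,
                                                              drop = FALSE]
    rownames(out) <- NULL
    attr(out, "outside") <- sum(!assigned)
    out
}

#' Write stranded TSS counts as TSV
#'
#' Long format: `module_label, strand, count`; a final pair of rows tallies
#' predictions outside all modules.
#'
#' @param counts result of [countTss()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTssTsv <- function(counts, file) {
    long <- rbind(
        data.frame(module_label = counts$module_label, strand = "+",
                   count = counts$plus_count),
        data.frame(module_label = counts$module_label, strand = "-",
                   count = counts$minus_count),
        data.frame(module_label = "outside", strand = "*",
                   count = attr(counts, "outside")))
    write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
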