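#' Assays recognized by the prevalence machinery
#' @export
ASSAYS <- c("DNASE", "H3K4ME3")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience over the standard complement table; `N` maps
#' to `N`. Involutive: `revComp(revComp(x)) == x`.
#'
#' @param x character vector of sequences over `A,C,G,T,N` (case-insensitive;
#'   output is uppercase).
#' @return character vector of reverse complements.
#' @examples
#' revComp("AAAC")  # "GTTT"
#' @export
revComp <- function(x) {
    x <- toupper(x)
    bad <- grepl("[^ACGTN]", x)
    if (any(bad))
        stop("sequence contains residues outside {A,C,G,T,N}")
    comp <- chartr("ACGTN", "TGCAN", x)
    vapply(strsplit(comp, ""), function(ch)
        paste(rev(ch), collapse = ""), character(1))
}

#' Read a BED3+ file of hotspot intervals
#'
#' Coordinates are taken verbatim as 0-based half-open per the BED standard
#' and stored in a `GRanges` (1-based closed internally; all writers convert
#' back). Track-level metadata (assay, cell type) is supplied by the caller,
#' mirroring the ENCODE convention of one track per cell type and assay.
#' `track`, `browser` and `#` comment lines are skipped.
#'
#' @param file path or connection to a BED3+ file.
#' @param assay one of `ASSAYS` (`"DNASE"`, `"H3K4ME3"`), attached to every
#'   record; `NA` to omit.
#' @param cell_type cell-type identifier attached to every record; `NA` to
#'   omit.
#' @return `GRanges` in file order with metadata columns `cell_type`, `assay`.
#' @export
readBed <- function(file, assay = NA_character_, cell_type = NA_character_) {
    if (!is.na(assay) && !assay %in% ASSAYS)
        stop("unknown assay '", assay, "'; expected one of: ",
             paste(ASSAYS, collapse = ", "))
    lines <- readLines(file)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(cell_type = character(), assay = character())
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("line ", lineno[which(nf < 3L)[1L]], ": fewer than 3 BED fields")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    s <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
    e <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(s) | is.na(e))
    if (length(bad))
        stop("line ", lineno[bad[1L]], ": non-integer coordinates")
    bad <- which(s >= e | s < 0L)
    if (length(bad))
        stop("line ", lineno[bad[1L]], ": invalid interval (start >= end)")
    GRanges(chrom, IRanges(s + 1L, e),
            cell_type = rep(cell_type, length(s)),
            assay = rep(assay, length(s)))
}

#' Write intervals as BED3 (0-based half-open)
#'
#' @param gr a `GRanges`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeBed <- function(gr, file) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    write.table(df, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Read a region coordinate table
#'
#' Tab-delimited with header columns `name`, `chrom`, `start`, `end`,
#' `coordinate_convention` (`0-half-open` or `1-closed`). All rows are
#' normalized to a common internal representation so that the exported
#' 0-based half-open coordinates of a `1-closed` row are `start-1, end`.
#' Accepting both conventions at the boundary avoids guessing which one an
#' external coordinate table (e.g. an ENSEMBL export) used.
#'
#' @param file path to the TSV.
#' @return named `GRanges`, one range per region, in file order.
#' @export
readRegionTable <- function(file) {
    df <- read.delim(file, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("name", "chrom", "start", "end", "coordinate_convention")
    if (!all(need %in% names(df)))
        stop("region table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$name))
        stop("duplicate region name(s): ",
             paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
    conv <- df$coordinate_convention
    bad <- !conv %in% c("0-half-open", "1-closed")
    if (any(bad))
        stop("unknown coordinate_convention '", conv[which(bad)[1L]], "'")
    start1 <- ifelse(conv == "0-half-open", df$start + 1L, df$start)
    gr <- GRanges(df$chrom, IRanges(as.integer(start1), as.integer(df$end)))
    if (any(start(gr) > end(gr)))
        stop("region with start >= end after normalization")
    names(gr) <- df$name
    gr
}

#' Write a region table in 0-based half-open convention
#'
#' @param gr named `GRanges` of regions.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeRegionTable <- function(gr, file) {
    df <- data.frame(name = names(gr),
                     chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     coordinate_convention = "0-half-open")
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

# uppercase + alphabet check for a single sequence
checkSeq <- function(x, allowN = TRUE) {
    x <- toupper(x)
    pat <- if (allowN) "[^ACGTN]" else "[^ACGT]"
    if (grepl(pat, x))
        stop("sequence contains residues outside the allowed alphabet")
    x
}
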