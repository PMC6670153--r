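#' Subdivide a region into fixed-width modules
#'
#' Splits a region into `ceiling(length / moduleWidth)` contiguous bins
#' anchored at the region's lower genomic coordinate; the genomically-last
#' bin is truncated when the length is not a multiple of the width. Bins are
#' labelled with Roman numerals. With `labelOrientation = "gene_sense"`
#' (default) and `geneStrand = "-"`, label I is the genomically-highest bin,
#' so labels read 5' to 3' along the host gene's mRNA — the convention used
#' for minus-strand genes such as RUNX1; with `"genomic"`, label I is the
#' genomically-lowest bin.
#'
#' @param region `GRanges` of length 1 (named) or a named list/row with
#'   `chrom`, `start`, `end` (0-based half-open).
#' @param moduleWidth bin width in bp (default 2500).
#' @param labelOrientation `"gene_sense"` or `"genomic"`.
#' @param geneStrand `"+"` or `"-"`; used only for gene-sense labelling.
#' @return a [ModuleSet-class].
#' @examples
#' r <- GenomicRanges::GRanges("chr21", IRanges::IRanges(1, 24800))
#' names(r) <- "intron5"
#' makeModules(r, 2500, geneStrand = "-")
#' @export
makeModules <- function(region, moduleWidth = 2500L,
                        labelOrientation = c("gene_sense", "genomic"),
                        geneStrand = "+") {
    labelOrientation <- match.arg(labelOrientation)
    if (moduleWidth <= 0L)
        stop("moduleWidth must be > 0")
    moduleWidth <- as.integer(moduleWidth)
    if (!methods::is(region, "GRanges"))
        stop("region must be a GRanges of length 1")
    if (length(region) != 1L)
        stop("region must be a single range")
    if (is.null(names(region))) names(region) <- "region"
    len <- width(region)
    n <- as.integer(ceiling(len / moduleWidth))
    s <- start(region) + (seq_len(n) - 1L) * moduleWidth
    e <- pmin(s + moduleWidth - 1L, end(region))
    bins <- GRanges(seqnames(region), IRanges(s, e))
    idx <- seq_len(n)
    lab <- if (labelOrientation == "gene_sense" && geneStrand == "-")
        as.character(as.roman(n + 1L - idx)) else as.character(as.roman(idx))
    mcols(bins)$index <- idx
    mcols(bins)$label <- lab
    methods::new("ModuleSet", region = granges(region, use.names = TRUE),
                 bins = bins, moduleWidth = moduleWidth,
                 labelOrientation = labelOrientation,
                 geneStrand = geneStrand)
}

#' Count per-module cell-type hotspot prevalence
#'
#' For every module and assay, counts the number of *distinct* cell types
#' with at least one hotspot overlapping the module by >= 1 bp. A hotspot
#' spanning a module boundary contributes to every module it touches;
#' multiple hotspots of one cell type within one module still contribute 1.
#' Hotspots on a different chromosome than the region are ignored (their
#' number is recorded in the result).
#'
#' @param modules a [ModuleSet-class].
#' @param hotspots `GRanges` with metadata columns `cell_type` and `assay`
#'   (as from [readBed()], concatenated over tracks).
#' @param nCellTypes optional named integer giving the total number of cell
#'   types assayed per assay (e.g. `c(DNASE = 124, H3K4ME3 = 51)`); defaults
#'   to the number of distinct cell types observed in `hotspots` per assay.
#'   Supplying it matters when some assayed cell types have no hotspot at
#'   all in the region.
#' @return a [PrevalenceTable-class]; rows ordered by assay then module label.
#' @export
countPrevalence <- function(modules, hotspots, nCellTypes = NULL) {
    stopifnot(methods::is(modules, "ModuleSet"))
    mc <- mcols(hotspots)
    if (length(hotspots) && (is.null(mc$cell_type) || is.null(mc$assay)))
        stop("hotspots need 'cell_type' and 'assay' metadata columns")
    if (length(hotspots) && !all(mc$assay %in% ASSAYS))
        stop("unknown assay value(s): ",
             paste(setdiff(unique(mc$assay), ASSAYS), collapse = ", "))
    chrom <- as.character(seqnames(modules@region))
    onChrom <- as.character(seqnames(hotspots)) == chrom
    nSkipped <- sum(!onChrom)
    if (nSkipped > 0L)
        warning(nSkipped, " hotspot(s) on other chromosomes ignored")
    hs <- hotspots[onChrom]
    assays <- sort(unique(as.character(mcols(hs)$assay)))
    if (is.null(nCellTypes)) {
        nCellTypes <- vapply(assays, function(a)
            length(unique(mcols(hs)$cell_type[mcols(hs)$assay == a])), 1L)
    } else {
        miss <- setdiff(assays, names(nCellTypes))
        if (length(miss))
            stop("nCellTypes missing assay(s): ", paste(miss, collapse = ", "))
        nCellTypes <- vapply(nCellTypes, as.integer, 1L)
        assays <- intersect(names(nCellTypes), union(names(nCellTypes), assays))
    }
    bins <- modules@bins
    ord <- order(as.integer(as.roman(mcols(bins)$label)))
    rows <- lapply(assays, function(a) {
        sub <- hs[mcols(hs)$assay == a]
        ov <- suppressWarnings(findOverlaps(bins, sub, minoverlap = 1L))
        cnt <- vapply(seq_along(bins), function(i) {
            length(unique(mcols(sub)$cell_type[subjectHits(ov)[
                queryHits(ov) == i]]))
        }, 1L)
        data.frame(region = names(modules@region),
                   module_label = mcols(bins)$label,
                   start = start(bins) - 1L, end = end(bins),
                   assay = a, count = cnt,
                   n_cell_types = unname(nCellTypes[a]))[ord, , drop = FALSE]
    })
    if (!length(rows)) {
        tab <- data.frame(region = character(), module_label = character(),
                          start = integer(), end = integer(),
                          assay = character(), count = integer(),
                          n_cell_types = integer())
    } else {
        tab <- do.call(rbind, rows)
        rownames(tab) <- NULL
    }
    methods::new("PrevalenceTable", table = tab,
                 nCellTypes = setNames(as.integer(nCellTypes[assays]), assays),
                 nSkipped = as.integer(nSkipped))
}

#' Whole-region cell-type prevalence
#'
#' Single-bin variant of [countPrevalence()]: the number of distinct cell
#' types with at least one hotspot of the given assay anywhere in the region
#' (used, e.g., for a gene-free control region reported as a single number).
#'
#' @param region `GRanges` of length 1.
#' @param hotspots `GRanges` with `cell_type` (and optionally `assay`)
#'   metadata.
#' @param assay assay to count; records of other assays are ignored. `NA`
#'   counts all records.
#' @return integer count of cell types.
#' @export
regionPrevalence <- function(region, hotspots, assay = NA_character_) {
    stopifnot(length(region) == 1L)
    if (!is.na(assay)) {
        if (!assay %in% ASSAYS)
            stop("unknown assay '", assay, "'")
        hotspots <- hotspots[mcols(hotspots)$assay == assay]
    }
    hs <- hotspots[as.character(seqnames(hotspots)) ==
                   as.character(seqnames(region))]
    ov <- suppressWarnings(findOverlaps(region, hs, minoverlap = 1L))
    length(unique(mcols(hs)$cell_type[subjectHits(ov)]))
}

#' Write a prevalence table as TSV
#'
#' Columns `region, module_label, start, end, assay, count, n_cell_types`
#' with 0-based half-open coordinates.
#'
#' @param x a [PrevalenceTable-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writePrevalenceTsv <- function(x, file) {
    stopifnot(methods::is(x, "PrevalenceTable"))
    write.table(x@table, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Reconstruct hotspot tracks from a presence/absence matrix
#'
#' Given a 0/1 matrix (rows = cell types, columns = named intervals) and the
#' matching named `GRanges`, emits one hotspot per (cell type, interval)
#' marked present, centered in the interval. This turns a summary
#' presence matrix (the form in which cross-cell-type hotspot surveys are
#' often published) back into interval tracks that the overlap machinery can
#' consume.
#'
#' @param presence data.frame or matrix of 0/1 with cell types as rownames
#'   (or a `cell_type` first column) and interval names as columns.
#' @param intervals named `GRanges`, one range per presence column.
#' @param assay assay tag for the emitted records.
#' @param hotspotWidth width of each emitted hotspot (clipped to the
#'   interval).
#' @return `GRanges` with `cell_type` and `assay` metadata.
#' @export
presenceToHotspots <- function(presence, intervals, assay,
                               hotspotWidth = 150L) {
    presence <- as.data.frame(presence)
    if ("cell_type" %in% names(presence)) {
        rownames(presence) <- presence$cell_type
        presence$cell_type <- NULL
    }
    miss <- setdiff(colnames(presence), names(intervals))
    if (length(miss))
        stop("presence columns without matching interval: ",
             paste(miss, collapse = ", "))
    out <- list()
    for (col in colnames(presence)) {
        iv <- intervals[col]
        cts <- rownames(presence)[presence[[col]] != 0]
        if (!length(cts)) next
        mid <- (start(iv) + end(iv)) %/% 2L
        half <- as.integer(hotspotWidth) %/% 2L
        s <- max(start(iv), mid - half)
        e <- min(end(iv), mid + half)
        out[[col]] <- GRanges(seqnames(iv), IRanges(rep(s, length(cts)),
                                                    rep(e, length(cts))),
                              cell_type = cts, assay = assay)
    }
    if (!length(out)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(cell_type = character(), assay = character())
        return(gr)
    }
    unname(do.call(c, unname(out)))
}
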