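#' ModuleSet: fixed-width subdivisions of a genomic region
#'
#' A `ModuleSet` holds a single analyzed region together with its fixed-width
#' modules (bins). Bins are stored in ascending genomic order and are disjoint,
#' contiguous and cover the region exactly; every bin has the configured width
#' except possibly the genomically-last one, which may be truncated. Each bin
#' carries a 1-based genomic `index` and a Roman-numeral `label`. When
#' `labelOrientation` is `"gene_sense"` and the declared gene strand is `"-"`,
#' labels run I, II, ... in *descending* genomic coordinates, i.e. 5' to 3' in
#' the sense of the host gene's mRNA, matching the convention used when a
#' minus-strand gene's intron is described module-by-module.
#'
#' @slot region `GRanges` of length 1, the parent region (its `names()` is the
#'   region label).
#' @slot bins `GRanges` of the modules, ascending genomic order, with metadata
#'   columns `index` (integer) and `label` (Roman numeral character).
#' @slot moduleWidth integer, the configured bin width in bp.
#' @slot labelOrientation `"gene_sense"` or `"genomic"`.
#' @slot geneStrand `"+"` or `"-"`, the strand of the host gene used for
#'   gene-sense labelling.
#'
#' @seealso [makeModules()]
#' @export
setClass("ModuleSet",
    slots = c(
        region = "GRanges",
        bins = "GRanges",
        moduleWidth = "integer",
        labelOrientation = "character",
        geneStrand = "character"
    )
)

setValidity("ModuleSet", function(object) {
    msg <- character()
    if (length(object@region) != 1L)
        msg <- c(msg, "region must be a single range")
    b <- object@bins
    if (length(b) > 0L) {
        s <- GenomicRanges::start(b)
        e <- GenomicRanges::end(b)
        if (is.unsorted(s, strictly = TRUE))
            msg <- c(msg, "bins must be in strictly ascending genomic order")
        if (length(b) > 1L && any(s[-1L] != e[-length(e)] + 1L))
            msg <- c(msg, "bins must be contiguous and disjoint")
        if (sum(GenomicRanges::width(b)) != GenomicRanges::width(object@region))
            msg <- c(msg, "bin widths must sum to the region length")
        w <- GenomicRanges::width(b)
        if (any(w[-length(w)] != object@moduleWidth))
            msg <- c(msg, "all bins but the genomically-last must have moduleWidth")
        if (is.null(mcols(b)$label) || is.null(mcols(b)$index))
            msg <- c(msg, "bins need 'index' and 'label' metadata columns")
    }
    if (!object@labelOrientation %in% c("gene_sense", "genomic"))
        msg <- c(msg, "labelOrientation must be 'gene_sense' or 'genomic'")
    if (!object@geneStrand %in% c("+", "-"))
        msg <- c(msg, "geneStrand must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' PrevalenceTable: per-module cell-type hotspot counts
#'
#' Result container for [countPrevalence()]. One row per (module, assay) with
#' the number of distinct cell types having at least one overlapping hotspot,
#' and the total number of cell types supplied for that assay.
#'
#' @slot table data.frame with columns `region`, `module_label`, `start`,
#'   `end` (0-based half-open), `assay`, `count`, `n_cell_types`.
#' @slot nCellTypes named integer, total cell types per assay.
#' @slot nSkipped integer, hotspot records ignored because their chromosome
#'   did not match the region.
#'
#' @export
setClass("PrevalenceTable",
    slots = c(
        table = "data.frame",
        nCellTypes = "integer",
        nSkipped = "integer"
    )
)

setValidity("PrevalenceTable", function(object) {
    tab <- object@table
    need <- c("region", "module_label", "start", "end", "assay", "count",
              "n_cell_types")
    if (!all(need %in% names(tab)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (nrow(tab) && any(tab$count < 0 | tab$count > tab$n_cell_types))
        return("counts must lie in [0, n_cell_types]")
    TRUE
})

#' InrPWM: initiator-element position weight matrix
#'
#' A per-position base-frequency model of the initiator (INR) core promoter
#' element. Scoring normalizes the window probability by the probability of
#' the per-position-maximal (consensus) window, so the best possible window
#' scores exactly 1 and a printed cutoff such as 0.99 is directly
#' interpretable. The `center` slot records the 0-based offset of the +1
#' (transcription start) base within the motif; reported hit centers point at
#' that base.
#'
#' @slot mat numeric matrix, one row per motif position, columns `A,C,G,T`,
#'   rows summing to 1 (raw frequencies, before pseudocount smoothing).
#' @slot pseudocount numeric smoothing constant added to each frequency before
#'   per-row renormalization.
#' @slot center integer, 0-based offset of the +1 base within the motif.
#' @slot source character, provenance of the matrix.
#'
#' @seealso [inrDefaultPWM()], [readPWM()], [scanInr()]
#' @export
setClass("InrPWM",
    slots = c(
        mat = "matrix",
        pseudocount = "numeric",
        center = "integer",
        source = "character"
    )
)

setValidity("InrPWM", function(object) {
    m <- object@mat
    msg <- character()
    if (!identical(colnames(m), c("A", "C", "G", "T")))
        msg <- c(msg, "matrix columns must be A, C, G, T in order")
    if (nrow(m) < 4L)
        msg <- c(msg, "motif width must be >= 4")
    if (any(m < 0))
        msg <- c(msg, "frequencies must be non-negative")
    if (nrow(m) && any(abs(rowSums(m) - 1) > 1e-6))
        msg <- c(msg, "each position's frequencies must sum to 1")
    if (object@pseudocount < 0)
        msg <- c(msg, "pseudocount must be >= 0")
    if (object@center < 0L || object@center >= nrow(m))
        msg <- c(msg, "center must be a 0-based offset within the motif")
    p <- pwmProbs(object)
    if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-9))
        msg <- c(msg, "smoothed probabilities must sum to 1 per position")
    if (length(msg)) msg else TRUE
})

#' ConsensusResult: consensus call from a multiple alignment
#'
#' Per-column majority consensus of an EST multiple alignment. Columns with
#' fewer than `min_depth` non-gap residues (or all gaps) are dropped;
#' retained columns yield the majority residue when its support reaches the
#' configured threshold and `N` otherwise (ties always give `N`).
#'
#' @slot sequence character, the called consensus (may contain `N`).
#' @slot support numeric, per retained column: fraction of non-gap residues
#'   agreeing with the call (for `N` calls, the top fraction observed).
#' @slot depth integer, per retained column: number of non-gap residues.
#' @slot columns integer, 1-based indices of the retained alignment columns.
#'
#' @seealso [callConsensus()]
#' @export
setClass("ConsensusResult",
    slots = c(
        sequence = "character",
        support = "numeric",
        depth = "integer",
        columns = "integer"
    )
)

setValidity("ConsensusResult", function(object) {
    n <- nchar(object@sequence)
    msg <- character()
    if (length(object@support) != n || length(object@depth) != n ||
        length(object@columns) != n)
        msg <- c(msg, "support, depth and columns must match sequence length")
    if (n && (any(object@support < 0) || any(object@support > 1)))
        msg <- c(msg, "support must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
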