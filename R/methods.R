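#' @rdname ModuleSet-class
#' @export
setMethod("moduleBins", "ModuleSet", function(x) x@bins)

#' @rdname ModuleSet-class
#' @export
setMethod("moduleLabels", "ModuleSet", function(x) {
    lab <- mcols(x@bins)$label
    lab[order(as.integer(as.roman(lab)))]
})

#' @rdname ModuleSet-class
#' @export
setMethod("moduleWidth", "ModuleSet", function(x) x@moduleWidth)

setMethod("show", "ModuleSet", function(object) {
    cat("ModuleSet:", names(object@region), "(",
        as.character(seqnames(object@region)), ")\n")
    cat("  region: [", start(object@region) - 1L, ",", end(object@region),
        ") 0-based half-open,", width(object@region), "bp\n")
    cat("  ", length(object@bins), " modules of width ", object@moduleWidth,
        " (last genomic bin ", width(object@bins)[length(object@bins)],
        " bp), labels ", object@labelOrientation, "\n", sep = "")
})

#' @rdname ModuleSet-class
#' @export
setMethod("length", "ModuleSet", function(x) length(x@bins))

#' @rdname PrevalenceTable-class
#' @export
setMethod("prevalence", "PrevalenceTable", function(x) x@table)

#' @rdname PrevalenceTable-class
#' @export
setMethod("nCellTypes", "PrevalenceTable", function(x) x@nCellTypes)

setMethod("show", "PrevalenceTable", function(object) {
    cat("PrevalenceTable:", nrow(object@table), "rows;",
        "cell types per assay:",
        paste(names(object@nCellTypes), object@nCellTypes,
              sep = "=", collapse = ", "), "\n")
    if (object@nSkipped > 0L)
        cat("  (", object@nSkipped,
            "hotspots on other chromosomes ignored )\n")
    print(utils::head(object@table, 12L))
    if (nrow(object@table) > 12L) cat("  ...\n")
})

#' @rdname InrPWM-class
#' @export
setMethod("pwmMatrix", "InrPWM", function(x) x@mat)

#' Smoothed per-position probabilities
#'
#' Applies the pseudocount and renormalizes each row:
#' `p = (f + pseudocount) / (1 + 4 * pseudocount)`.
#'
#' @rdname InrPWM-class
#' @export
setMethod("pwmProbs", "InrPWM", function(x) {
    (x@mat + x@pseudocount) / (1 + 4 * x@pseudocount)
})

#' @rdname InrPWM-class
#' @export
setMethod("pwmWidth", "InrPWM", function(x) nrow(x@mat))

#' @rdname InrPWM-class
#' @export
setMethod("pwmCenter", "InrPWM", function(x) x@center)

setMethod("show", "InrPWM", function(object) {
    cat("InrPWM: width", nrow(object@mat), "bp, +1 at offset", object@center,
        ", pseudocount", object@pseudocount, "\n")
    cat("  consensus:", pwmConsensus(object), "\n")
    cat("  source:", object@source, "\n")
})

#' @rdname ConsensusResult-class
#' @export
setMethod("consensusSequence", "ConsensusResult", function(x) x@sequence)

#' @rdname ConsensusResult-class
#' @export
setMethod("consensusSupport", "ConsensusResult", function(x) x@support)

#' @rdname ConsensusResult-class
#' @export
setMethod("consensusDepth", "ConsensusResult", function(x) x@depth)

setMethod("show", "ConsensusResult", function(object) {
    n <- nchar(object@sequence)
    cat("ConsensusResult:", n, "bp,",
        sum(strsplit(object@sequence, "")[[1]] == "N"), "ambiguous (N)\n")
    if (n) {
        cat("  mean depth", round(mean(object@depth), 2),
            "; mean support", round(mean(object@support), 3), "\n")
        cat("  ", substr(object@sequence, 1L, min(60L, n)),
            if (n > 60L) "..." else "", "\n", sep = "")
    }
})
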