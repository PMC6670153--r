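#' @rdname ModuleSet-class
#' @param x a `ModuleSet`
#' @export
setGeneric("moduleBins", function(x) standardGeneric("moduleBins"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname ModuleSet-class
#' @export
setGeneric("moduleWidth", function(x) standardGeneric("moduleWidth"))

#' @rdname PrevalenceTable-class
#' @param x a `PrevalenceTable`
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))

#' @rdname PrevalenceTable-class
#' @export
setGeneric("nCellTypes", function(x) standardGeneric("nCellTypes"))

#' @rdname InrPWM-class
#' @param x an `InrPWM`
#' @export
setGeneric("pwmMatrix", function(x) standardGeneric("pwmMatrix"))

#' @rdname InrPWM-class
#' @export
setGeneric("pwmProbs", function(x) standardGeneric("pwmProbs"))

#' @rdname InrPWM-class
#' @export
setGeneric("pwmWidth", function(x) standardGeneric("pwmWidth"))

#' @rdname InrPWM-class
#' @export
setGeneric("pwmCenter", function(x) standardGeneric("pwmCenter"))

#' @rdname ConsensusResult-class
#' @param x a `ConsensusResult`
#' @export
setGeneric("consensusSequence",
    function(x) standardGeneric("consensusSequence"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("consensusSupport", function(x) standardGeneric("consensusSupport"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("consensusDepth", function(x) standardGeneric("consensusDepth"))
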