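# Core accessors users need for the SummarizedExperiment-based containers,
# re-exported so library(hdacscreen) suffices.

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData
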