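#' @rdname partitionCoreSatellite
#' @export
setGeneric("partitionCoreSatellite", function(x, ...)
  standardGeneric("partitionCoreSatellite"))

#' @rdname raupCrick
#' @export
setGeneric("raupCrick", function(x, ...) standardGeneric("raupCrick"))

#' Core taxa of a partition or truth object
#' @param x a `PartitionResult` or `MetacomTruth`
#' @param ... for `MetacomTruth`, `site =` selects the metacommunity
#' @return character vector of taxon identifiers
#' @export
setGeneric("coreTaxa", function(x, ...) standardGeneric("coreTaxa"))

#' Satellite taxa of a partition or truth object
#' @inheritParams coreTaxa
#' @return character vector of taxon identifiers
#' @export
setGeneric("satelliteTaxa", function(x, ...) standardGeneric("satelliteTaxa"))
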