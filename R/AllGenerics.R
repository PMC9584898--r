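#' @rdname PhosphoProteome-class
#' @param x,object A `PhosphoProteome` (or, where documented, another class).
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname PhosphoProteome-class
#' @export
setGeneric("entryData", function(x) standardGeneric("entryData"))

#' @rdname PhosphoProteome-class
#' @export
setGeneric("phosphoSites", function(x) standardGeneric("phosphoSites"))

#' @rdname PhosphoProteome-class
#' @export
setGeneric("subcellularLocations", function(x) standardGeneric("subcellularLocations"))

#' @rdname PhosphoProteome-class
#' @export
setGeneric("parseReport", function(x) standardGeneric("parseReport"))

#' @rdname PeptideWindow-class
#' @param x A `PeptideWindow` or `SeedFragment`.
#' @export
setGeneric("windowResidues", function(x) standardGeneric("windowResidues"))

#' @rdname PeptideWindow-class
#' @export
setGeneric("centerPos", function(x) standardGeneric("centerPos"))

#' @rdname PeptideWindow-class
#' @export
setGeneric("centerResidue", function(x) standardGeneric("centerResidue"))

#' @rdname PeptideWindow-class
#' @export
setGeneric("leftMissing", function(x) standardGeneric("leftMissing"))

#' @rdname PeptideWindow-class
#' @export
setGeneric("rightMissing", function(x) standardGeneric("rightMissing"))

#' @rdname PeptideWindow-class
#' @export
setGeneric("isCTerminal", function(x) standardGeneric("isCTerminal"))

#' @rdname SeedFragment-class
#' @param x A `SeedFragment`.
#' @export
setGeneric("seedId", function(x) standardGeneric("seedId"))

#' @rdname SeedFragment-class
#' @export
setGeneric("seedWindow", function(x) standardGeneric("seedWindow"))
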