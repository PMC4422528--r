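#' @rdname ExonCatalog-class
#' @param x an object.
#' @export
setGeneric("exonIds", function(x) standardGeneric("exonIds"))
#' @rdname ExonCatalog-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname ExonCatalog-class
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname ExonCatalog-class
#' @export
setGeneric("exonSequences", function(x) standardGeneric("exonSequences"))
#' @rdname ExonCatalog-class
#' @export
setGeneric("sourceChromosomes",
           function(x) standardGeneric("sourceChromosomes"))
#' @rdname ExonCatalog-class
#' @export
setGeneric("geneStrands", function(x) standardGeneric("geneStrands"))

#' @rdname VariantSet-class
#' @param x an object.
#' @export
setGeneric("vcfSamples", function(x) standardGeneric("vcfSamples"))
#' @rdname VariantSet-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname VariantSet-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname VariantSet-class
#' @export
setGeneric("variantPositions",
           function(x) standardGeneric("variantPositions"))
#' @rdname VariantSet-class
#' @export
setGeneric("refAlleles", function(x) standardGeneric("refAlleles"))
#' @rdname VariantSet-class
#' @export
setGeneric("altAlleles", function(x) standardGeneric("altAlleles"))

#' @rdname LineSpec-class
#' @param x an object.
#' @export
setGeneric("lineId", function(x) standardGeneric("lineId"))
#' @rdname LineSpec-class
#' @export
setGeneric("lineSamples", function(x) standardGeneric("lineSamples"))
#' @rdname LineSpec-class
#' @export
setGeneric("inheritanceModel",
           function(x) standardGeneric("inheritanceModel"))
#' @rdname LineSpec-class
#' @export
setGeneric("linkageRegions", function(x) standardGeneric("linkageRegions"))
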