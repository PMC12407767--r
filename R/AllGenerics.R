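#' Accessors
#'
#' Accessor generics for the core classes: donor identifiers, variant
#' identifiers and coordinates, the genotype matrix, molecule calls and
#' coverage, and simulation truth.
#'
#' @param x a demuxamb object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("donorNames", function(x) standardGeneric("donorNames"))
#' @rdname accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @rdname accessors
#' @export
setGeneric("gammaMatrix", function(x) standardGeneric("gammaMatrix"))
#' @rdname accessors
#' @export
setGeneric("variantRanges", function(x) standardGeneric("variantRanges"))
#' @rdname accessors
#' @export
setGeneric("nDonors", function(x) standardGeneric("nDonors"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("moleculeCalls", function(x) standardGeneric("moleculeCalls"))
#' @rdname accessors
#' @export
setGeneric("moleculeCoverage", function(x) standardGeneric("moleculeCoverage"))
#' @rdname accessors
#' @export
setGeneric("truthDroplets", function(x) standardGeneric("truthDroplets"))

#' @rdname accessors
#' @export
setMethod("donorNames", "GenotypeMatrix", function(x) colnames(x@gamma))
#' @rdname accessors
#' @export
setMethod("variantIds", "GenotypeMatrix", function(x) rownames(x@gamma))
#' @rdname accessors
#' @export
setMethod("gammaMatrix", "GenotypeMatrix", function(x) x@gamma)
#' @rdname accessors
#' @export
setMethod("variantRanges", "GenotypeMatrix", function(x) x@ranges)
#' @rdname accessors
#' @export
setMethod("nDonors", "GenotypeMatrix", function(x) ncol(x@gamma))
#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) nrow(x@gamma))
#' @rdname accessors
#' @export
setMethod("moleculeCalls", "MoleculeTable", function(x) copy(x@calls))
#' @rdname accessors
#' @export
setMethod("moleculeCoverage", "MoleculeTable", function(x) copy(x@coverage))
#' @rdname accessors
#' @export
setMethod("truthDroplets", "SimTruth", function(x) copy(x@droplets))
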