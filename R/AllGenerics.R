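#' Reverse complement
#'
#' Involution on DNA strings and \linkS4class{DnaSeq} objects. Topology is
#' preserved; features are remapped to the complementary strand.
#'
#' @param x a DNA string or \linkS4class{DnaSeq}
#' @return object of the same class as \code{x}
#' @examples
#' revComp("GAATTC")   # palindrome
#' @export
setGeneric("revComp", function(x) standardGeneric("revComp"))

#' Sequence accessors
#'
#' @param x a \linkS4class{DnaSeq} (or object wrapping one)
#' @return \code{dnaBases}: the uppercase base string; \code{seqTopology}:
#'   \code{"linear"} or \code{"circular"}; \code{seqFeatures}: the feature
#'   data.frame (0-based half-open coordinates)
#' @name dna-accessors
#' @export
setGeneric("dnaBases", function(x) standardGeneric("dnaBases"))

#' @rdname dna-accessors
#' @export
setGeneric("seqTopology", function(x) standardGeneric("seqTopology"))

#' @rdname dna-accessors
#' @export
setGeneric("seqFeatures", function(x) standardGeneric("seqFeatures"))

#' Validate a BglBrick part or candidate insert
#'
#' For a \linkS4class{BglBrickPart}, checks flank structure (prefix: exactly
#' one EcoRI then one BglII; suffix: exactly one BamHI then one XhoI) and that
#' the insert carries none of the four BglBrick recognition sites. For a bare
#' sequence the whole sequence is treated as a candidate insert and every
#' forbidden site is reported.
#'
#' @param x a \linkS4class{BglBrickPart}, \linkS4class{DnaSeq} or DNA string
#' @return a list with elements \code{valid} (logical), \code{hits}
#'   (data.frame of forbidden sites in the insert, as from
#'   \code{\link{findSites}}) and \code{problems} (character vector)
#' @export
setGeneric("validatePart", function(x) standardGeneric("validatePart"))
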