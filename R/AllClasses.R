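#' @import methods
NULL

.valid_topologies <- c("linear", "circular")

.empty_features <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' DnaSequence: linear or circular DNA with feature annotations
#'
#' The substrate of all cloning operations. Bases are canonicalized to
#' uppercase ACGT on construction; IUPAC ambiguity codes are rejected so that
#' restriction-site scanning stays exact. Feature coordinates are 0-based
#' half-open on the top strand; on a circular molecule a feature whose
#' \code{start >= end} wraps the origin.
#'
#' @slot bases single uppercase ACGT string
#' @slot topology \code{"linear"} or \code{"circular"}
#' @slot features data.frame with columns \code{label}, \code{start},
#'   \code{end}, \code{strand}
#' @exportClass DnaSeq
setClass("DnaSeq",
  representation(bases = "character", topology = "character",
                 features = "data.frame"))

setValidity("DnaSeq", function(object) {
  msg <- character()
  if (length(object@bases) != 1L || is.na(object@bases) || !nzchar(object@bases))
    msg <- c(msg, "bases must be a single non-empty string")
  else {
    bad <- regexpr("[^ACGT]", object@bases)
    if (bad > 0L)
      msg <- c(msg, sprintf("non-ACGT character '%s' at position %d (0-based %d)",
                            substr(object@bases, bad, bad), bad, bad - 1L))
  }
  if (length(object@topology) != 1L || !object@topology %in% .valid_topologies)
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  f <- object@features
  need <- c("label", "start", "end", "strand")
  if (!all(need %in% names(f)))
    msg <- c(msg, "features must have columns label, start, end, strand")
  else if (nrow(f) > 0 && length(msg) == 0) {
    len <- nchar(object@bases)
    if (any(f$start < 0L | f$start >= len | f$end < 0L | f$end > len))
      msg <- c(msg, "feature coordinates must lie within [0, length)")
    if (object@topology == "linear" && any(f$end < f$start))
      msg <- c(msg, "features on a linear sequence cannot wrap")
    if (!all(f$strand %in% c("+", "-")))
      msg <- c(msg, "feature strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DnaSeq
#'
#' @param bases DNA string (case-insensitive; canonicalized to uppercase)
#' @param topology \code{"linear"} (default) or \code{"circular"}
#' @param features optional data.frame of annotations (label, start, end,
#'   strand), 0-based half-open coordinates
#' @return a \linkS4class{DnaSeq}
#' @examples
#' s <- DnaSeq("gaattc", topology = "circular")
#' dnaBases(s)
#' @export
DnaSeq <- function(bases, topology = "linear", features = NULL) {
  if (is(bases, "DnaSeq")) return(bases)
  stopifnot(is.character(bases), length(bases) == 1L)
  if (is.null(features)) features <- .empty_features()
  features$label <- as.character(features$label)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (is.null(features$strand)) features$strand <- rep("+", nrow(features))
  features$strand <- as.character(features$strand)
  new("DnaSeq", bases = toupper(bases), topology = topology,
      features = features[, c("label", "start", "end", "strand"), drop = FALSE])
}

#' Restriction fragment with explicit end chemistry
#'
#' \code{bases} holds the top strand from the top-strand cut on the left to
#' the top-strand cut on the right, so that concatenating the fragments of a
#' digest in order reconstructs the parent top strand exactly. Each end is a
#' list with elements \code{kind} (\code{"blunt"}, \code{"five_prime"},
#' \code{"three_prime"}), \code{overhang} (the single-stranded gap region read
#' on top-strand coordinates; \code{""} for blunt) and \code{enzyme} (name of
#' the generating enzyme, or \code{NA} for a native molecule terminus).
#'
#' @slot bases top-strand string
#' @slot left_end,right_end end-chemistry lists
#' @exportClass Fragment
setClass("Fragment",
  representation(bases = "character", left_end = "list", right_end = "list"))

setValidity("Fragment", function(object) {
  ok_end <- function(e)
    is.list(e) && all(c("kind", "overhang") %in% names(e)) &&
      e$kind %in% c("blunt", "five_prime", "three_prime") &&
      (e$kind != "blunt" || !nzchar(e$overhang)) &&
      nchar(e$overhang) <= 4L
  msg <- character()
  if (!nzchar(object@bases)) msg <- c(msg, "fragment bases must be non-empty")
  if (!ok_end(object@left_end)) msg <- c(msg, "malformed left_end")
  if (!ok_end(object@right_end)) msg <- c(msg, "malformed right_end")
  if (length(msg)) msg else TRUE
})

.fragment <- function(bases, left_end, right_end)
  new("Fragment", bases = bases, left_end = left_end, right_end = right_end)

.blunt_end <- function() list(kind = "blunt", overhang = "", enzyme = NA_character_)

#' A BglBrick standard part
#'
#' A part is an insert free of the four BglBrick recognition sites, flanked
#' by a prefix carrying EcoRI then BglII and a suffix carrying BamHI then
#' XhoI. Composites produced by \code{\link{assembleParts}} are themselves
#' valid parts (idempotent assembly).
#'
#' @slot prefix,insert,suffix uppercase DNA strings
#' @exportClass BglBrickPart
setClass("BglBrickPart",
  representation(prefix = "character", insert = "character",
                 suffix = "character"))

setValidity("BglBrickPart", function(object) {
  rep <- validatePart(object)
  if (rep$valid) TRUE else paste(rep$problems, collapse = "; ")
})

#' A pBb expression vector
#'
#' Circular sequence assembled from three modules in fixed order
#' (expression: AatII to AvrII; origin: AvrII to SacI; marker: SacI back to
#' AatII) with a single BglII/BamHI gene cassette inside the expression
#' module, plus the parsed components of its systematic name.
#'
#' @slot sequence circular \linkS4class{DnaSeq}
#' @slot origin_code,promoter_code,marker_code,payload_label name components
#' @exportClass PbbVector
setClass("PbbVector",
  representation(sequence = "DnaSeq", origin_code = "character",
                 promoter_code = "integer", marker_code = "character",
                 payload_label = "character"))

setValidity("PbbVector", function(object) {
  msg <- character()
  if (seqTopology(object@sequence) != "circular")
    msg <- c(msg, "vector sequence must be circular")
  for (enz in c("AatII", "AvrII", "SacI", "BglII", "BamHI")) {
    n <- nrow(findSites(object@sequence, enz))
    if (n != 1L) msg <- c(msg, sprintf("expected exactly one %s site, found %d", enz, n))
  }
  if (length(msg)) msg else TRUE
})

#' A swappable pBb vector module
#'
#' @slot kind \code{"expression"}, \code{"origin"} or \code{"marker"}
#' @slot payload linear \linkS4class{DnaSeq}; the sequence between the two
#'   boundary recognition sites (sites themselves excluded)
#' @exportClass VectorModule
setClass("VectorModule",
  representation(kind = "character", payload = "DnaSeq"))

setValidity("VectorModule", function(object) {
  msg <- character()
  if (!object@kind %in% c("expression", "origin", "marker"))
    msg <- c(msg, "kind must be expression, origin or marker")
  boundary <- c("AatII", "AvrII", "SacI")
  hits <- findSites(object@payload, boundary)
  if (nrow(hits) > 0)
    msg <- c(msg, paste("payload contains internal boundary site(s):",
                        paste(unique(hits$enzyme), collapse = ", ")))
  bgl <- findSites(object@payload, bglBrickEnzymes())
  if (object@kind == "expression") {
    tab <- table(factor(bgl$enzyme, levels = bglBrickEnzymes()))
    if (!(tab[["BglII"]] == 1L && tab[["BamHI"]] == 1L))
      msg <- c(msg, "expression payload must contain exactly one BglII and one BamHI site")
  } else if (nrow(bgl) > 0) {
    msg <- c(msg, paste("payload contains BglBrick site(s):",
                        paste(unique(bgl$enzyme), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})
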