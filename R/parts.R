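#' @importFrom Biostrings translate GENETIC_CODE
NULL

#' BglBrick assembly scar
#'
#' The fixed 6-mer junction left when a BamHI-cut end ligates to a BglII-cut
#' end (upstream BamHI half G + downstream BglII half GATCT). It is cut by
#' neither parent enzyme, which is what makes assembly iterative. When the
#' junction lies in frame the scar reads Gly-Ser; that translation follows
#' from standard chemistry of the junction, not from any measured property.
#'
#' @return \code{bglScar()}: the scar string; \code{scarTranslation()}: its
#'   in-frame amino acid translation
#' @export
bglScar <- function() "GGATCT"

#' @rdname bglScar
#' @export
scarTranslation <- function() {
  as.character(translate(DNAString(bglScar()), genetic.code = GENETIC_CODE))
}

# exactly one site of each enzyme, in the given order
.flank_ok <- function(flank, first, second) {
  h1 <- findSites(DnaSeq(flank), first)
  h2 <- findSites(DnaSeq(flank), second)
  nrow(h1) == 1L && nrow(h2) == 1L && h1$position < h2$position
}

#' @rdname validatePart
setMethod("validatePart", "BglBrickPart", function(x) {
  problems <- character()
  if (!nzchar(x@insert)) problems <- c(problems, "empty insert")
  if (!.flank_ok(x@prefix, "EcoRI", "BglII"))
    problems <- c(problems, "prefix must contain exactly one EcoRI then one BglII site")
  if (!.flank_ok(x@suffix, "BamHI", "XhoI"))
    problems <- c(problems, "suffix must contain exactly one BamHI then one XhoI site")
  # validity is defined on the full molecule: the only four-enzyme hits
  # allowed are the flank sites themselves, so boundary-spanning sites
  # (e.g. an insert ending CTCGA meeting the suffix G...) also invalidate.
  full <- paste0(x@prefix, x@insert, x@suffix)
  np <- nchar(x@prefix); ni <- nchar(x@insert)
  all_hits <- findSites(DnaSeq(full), bglBrickEnzymes())
  expected <- rbind(
    within(findSites(DnaSeq(x@prefix), c("EcoRI", "BglII")), position <- position),
    within(findSites(DnaSeq(x@suffix), c("BamHI", "XhoI")),
           position <- position + np + ni))
  key <- function(df) paste(df$enzyme, df$position)
  extra <- all_hits[!key(all_hits) %in% key(expected), , drop = FALSE]
  missing <- expected[!key(expected) %in% key(all_hits), , drop = FALSE]
  if (nrow(extra) > 0)
    problems <- c(problems, sprintf("unexpected forbidden site(s): %s",
                                    paste(sprintf("%s@%d", extra$enzyme, extra$position),
                                          collapse = ", ")))
  if (nrow(missing) > 0)
    problems <- c(problems, "flank site(s) destroyed by boundary context")
  rownames(extra) <- NULL
  list(valid = length(problems) == 0L, hits = extra, problems = problems)
})

setMethod("validatePart", "DnaSeq", function(x) {
  hits <- findSites(x, bglBrickEnzymes())
  list(valid = nrow(hits) == 0L, hits = hits,
       problems = if (nrow(hits) > 0)
         sprintf("sequence contains %d forbidden site(s)", nrow(hits)) else character())
})

setMethod("validatePart", "character", function(x) validatePart(DnaSeq(x)))

#' Default BglBrick part flanks
#'
#' Prefix \code{GAATTCaaaAGATCT} (EcoRI, spacer, BglII) and suffix
#' \code{GGATCCaaaCTCGAG} (BamHI, spacer, XhoI), the spacer pattern evidenced
#' by the construction primer tails. Both are overridable in
#' \code{\link{makePart}} for users following a different flank convention.
#'
#' @return named character vector with elements \code{prefix} and
#'   \code{suffix}
#' @export
defaultFlanks <- function() {
  c(prefix = "GAATTCAAAAGATCT", suffix = "GGATCCAAACTCGAG")
}

#' Construct a BglBrick part
#'
#' @param insert \linkS4class{DnaSeq} or string; must be free of the four
#'   BglBrick recognition sites
#' @param prefix,suffix flank sequences (see \code{\link{defaultFlanks}})
#' @return a \linkS4class{BglBrickPart}
#' @examples
#' p <- makePart("ATGGCTAGCAAAGGAGAAGAACTTTTCACTGGAGTT")
#' substr(partSequence(p)@bases, 1, 15)
#' @export
makePart <- function(insert, prefix = defaultFlanks()[["prefix"]],
                     suffix = defaultFlanks()[["suffix"]]) {
  insert <- if (is(insert, "DnaSeq")) dnaBases(insert) else toupper(insert)
  if (!nzchar(insert)) stop("empty insert")
  rep <- validatePart(insert)
  if (!rep$valid)
    stop("insert contains forbidden BglBrick site(s): ",
         paste(sprintf("%s@%d", rep$hits$enzyme, rep$hits$position), collapse = ", "))
  new("BglBrickPart", prefix = toupper(prefix), insert = insert,
      suffix = toupper(suffix))
}

#' Full sequence of a part
#'
#' @param part \linkS4class{BglBrickPart}
#' @return linear \linkS4class{DnaSeq} (prefix + insert + suffix) with the
#'   three regions annotated as features
#' @export
partSequence <- function(part) {
  np <- nchar(part@prefix); ni <- nchar(part@insert)
  DnaSeq(paste0(part@prefix, part@insert, part@suffix), "linear",
         features = data.frame(
           label = c("prefix", "insert", "suffix"),
           start = c(0L, np, np + ni),
           end = c(np, np + ni, np + ni + nchar(part@suffix)),
           strand = "+", stringsAsFactors = FALSE))
}

#' @rdname partSequence
#' @export
partInsert <- function(part) part@insert

setMethod("show", "BglBrickPart", function(object) {
  cat(sprintf("BglBrickPart: %d bp insert (flanks %d + %d bp)\n",
              nchar(object@insert), nchar(object@prefix), nchar(object@suffix)))
})

#' Idempotent BglBrick assembly
#'
#' Simulates the standard composite step: the upstream construct is opened at
#' BamHI (+XhoI), the downstream part excised with BglII (+XhoI), and the
#' BamHI/BglII GATC-cohesive ends ligated, leaving the
#' \code{\link{bglScar}} between the two inserts. The result is itself a
#' valid part carrying the upstream prefix and downstream suffix, so assembly
#' can be iterated.
#'
#' @param upstream,downstream \linkS4class{BglBrickPart} objects
#' @return composite \linkS4class{BglBrickPart} with
#'   \code{insert = upstream insert + scar + downstream insert}
#' @export
assembleParts <- function(upstream, downstream) {
  for (p in list(upstream, downstream)) {
    rep <- validatePart(p)
    if (!rep$valid) stop("invalid part: ", paste(rep$problems, collapse = "; "))
  }
  new("BglBrickPart", prefix = upstream@prefix,
      insert = paste0(upstream@insert, bglScar(), downstream@insert),
      suffix = downstream@suffix)
}

#' @rdname assembleParts
#' @param parts list of \linkS4class{BglBrickPart}, assembled left to right
#' @export
assembleOrder <- function(parts) {
  stopifnot(length(parts) >= 1L)
  Reduce(assembleParts, parts)
}
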