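#' pBb nomenclature catalogs
#'
#' The three-letter vector code: origin letter, promoter number, marker
#' letter. Promoter codes 2, 3/4, 5 and 8 are pinned by documented usage
#' (Ptet, the two PprpB variants, PlacUV5, PBAD); the assignment of codes 1,
#' 6, 7 to Ptrc, PLlacO-1 and PT7 (and the Salmonella-vs-E. coli order of the
#' PprpB pair) is the package default and can be overridden by passing a
#' modified catalog wherever one is accepted.
#'
#' @return \code{promoterCatalog}: data.frame (code, promoter, repressor,
#'   inducer, inducer_unit); \code{originCatalog}: data.frame (code, origin,
#'   copy_class, nominal_copy); \code{markerCatalog}: data.frame (code,
#'   marker, gene)
#' @export
promoterCatalog <- function() {
  data.frame(
    code = 1:8,
    promoter = c("Ptrc", "Ptet", "PprpB(S)", "PprpB(E)", "PlacUV5",
                 "PLlacO-1", "PT7", "PBAD"),
    repressor = c("LacIq", "TetR", "PrpR", "PrpR", "LacIq", "LacIq",
                  "LacIq", "AraC"),
    inducer = c("IPTG", "aTc", "propionate", "propionate", "IPTG", "IPTG",
                "IPTG", "arabinose"),
    inducer_unit = c("uM", "nM", "mM", "mM", "uM", "uM", "uM", "mM"),
    stringsAsFactors = FALSE)
}

#' @rdname promoterCatalog
#' @export
originCatalog <- function() {
  data.frame(
    code = c("E", "A", "S", "B"),
    origin = c("ColE1", "p15A", "pSC101**", "pBBR1"),
    copy_class = c("high", "medium", "low", "medium (broad host range)"),
    nominal_copy = c(60, 25, 5, 10),
    stringsAsFactors = FALSE)
}

#' @rdname promoterCatalog
#' @export
markerCatalog <- function() {
  data.frame(
    code = c("a", "c", "k"),
    marker = c("ampicillin", "chloramphenicol", "kanamycin"),
    gene = c("bla", "cat", "nptII"),
    stringsAsFactors = FALSE)
}

#' Format a pBb vector name
#'
#' @param origin_code one of E (ColE1), A (p15A), S (pSC101**), B (pBBR1)
#' @param promoter_code integer 1-8
#' @param marker_code one of a (ampicillin), c (chloramphenicol),
#'   k (kanamycin)
#' @param payload_label gene label appended after the dash
#' @return string such as \code{"pBbE5a-RFP"}
#' @examples
#' formatVectorName("E", 5, "a", "RFP")
#' @export
formatVectorName <- function(origin_code, promoter_code, marker_code,
                             payload_label) {
  if (!origin_code %in% originCatalog()$code)
    stop("unknown origin code: ", origin_code)
  if (!promoter_code %in% promoterCatalog()$code)
    stop("unknown promoter code: ", promoter_code)
  if (!marker_code %in% markerCatalog()$code)
    stop("unknown marker code: ", marker_code)
  paste0("pBb", origin_code, promoter_code, marker_code, "-", payload_label)
}

#' Parse a pBb vector name
#'
#' Accepts plain names (\code{"pBbA8a-CFP"}) and the set notation
#' \code{"pBb{A, E, or S}3a-rfp"}, which expands to one row per listed
#' origin code.
#'
#' @param name vector name string
#' @return data.frame with columns \code{name}, \code{origin_code},
#'   \code{origin}, \code{promoter_code}, \code{promoter}, \code{marker_code},
#'   \code{marker}, \code{payload_label} (one row per expanded name)
#' @export
parseVectorName <- function(name) {
  expanded <- name
  m <- regmatches(name, regexec("^(pBb)\\{([^}]*)\\}(.*)$", name))[[1]]
  if (length(m) > 0) {
    codes <- strsplit(m[3], "(,|\\bor\\b|\\s)+")[[1]]
    codes <- codes[nzchar(codes)]
    expanded <- paste0(m[2], codes, m[4])
  }
  out <- lapply(expanded, function(nm) {
    mm <- regmatches(nm, regexec("^pBb([A-Z])([0-9])([a-z])-(.+)$", nm))[[1]]
    if (length(mm) == 0)
      stop(sprintf("malformed vector name '%s' (expected pBb<Origin><Promoter><marker>-<payload>)", nm))
    oc <- mm[2]; pc <- as.integer(mm[3]); mc <- mm[4]
    ocat <- originCatalog(); pcat <- promoterCatalog(); mcat <- markerCatalog()
    if (!oc %in% ocat$code)
      stop(sprintf("unknown origin code '%s' in '%s' (at position 4)", oc, nm))
    if (!pc %in% pcat$code)
      stop(sprintf("unknown promoter code '%s' in '%s' (at position 5)", mm[3], nm))
    if (!mc %in% mcat$code)
      stop(sprintf("unknown marker code '%s' in '%s' (at position 6)", mc, nm))
    data.frame(name = nm, origin_code = oc,
               origin = ocat$origin[ocat$code == oc],
               promoter_code = pc,
               promoter = pcat$promoter[pcat$code == pc],
               marker_code = mc,
               marker = mcat$marker[mcat$code == mc],
               payload_label = mm[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.boundary_sites <- c(expression = "GACGTC", origin = "CCTAGG", marker = "GAGCTC")
.module_bounds <- list(expression = c("AatII", "AvrII"),
                       origin = c("AvrII", "SacI"),
                       marker = c("SacI", "AatII"))

#' Default synthetic module payload catalog
#'
#' Full parent-plasmid sequences are not bundled; instead the catalog ships
#' synthetic placeholder payloads (unique, boundary- and BglBrick-site-free,
#' length-realistic: origins ~1.2 kb, markers ~0.9 kb, promoter regions
#' ~0.4 kb) with the correct module architecture. Each payload embeds the
#' printed local mutation context where one exists (pSC101** BglII-removed
#' origin, kanamycin and chloramphenicol marker QC contexts, the pBBR1
#' copy-up context), and wild-type variants of those contexts are provided
#' under \code{wildtype} for domestication demos. Real sequences read from
#' GenBank drop into the same structure.
#'
#' @return list with elements \code{origins} (payloads by code E/A/S/B),
#'   \code{promoter_regions} (by code 1-8), \code{markers} (by code a/c/k),
#'   \code{genes} (rfp/gfp/cfp/yfp placeholders), \code{rbs},
#'   \code{terminator}, and \code{wildtype} (pre-domestication payload
#'   variants)
#' @export
defaultModuleCatalog <- function() {
  if (!is.null(.pkg_cache$module_catalog)) return(.pkg_cache$module_catalog)
  all8 <- enzymeTable()$name
  # scrub a payload together with the fixed sequence that will flank it in
  # the assembled vector, so junctions cannot form stray sites either
  scrub_ctx <- function(s, pre, post, protect = NULL) {
    t <- paste0(pre, s, post)
    shield <- data.frame(start = c(0L, nchar(pre) + nchar(s)),
                         end = c(nchar(pre), nchar(t)))
    if (!is.null(protect))
      shield <- rbind(shield, data.frame(start = protect$start + nchar(pre),
                                         end = protect$end + nchar(pre)))
    t <- .scrub_sites(t, all8, protect = shield)
    substr(t, nchar(pre) + 1L, nchar(pre) + nchar(s))
  }
  embed <- function(filler_n1, context, filler_n2, pre, post) {
    ctx <- toupper(context)
    s <- paste0(.random_bases(filler_n1), ctx, .random_bases(filler_n2))
    scrub_ctx(s, pre, post,
              protect = data.frame(start = filler_n1,
                                   end = filler_n1 + nchar(ctx)))
  }
  plain <- function(n, pre, post) scrub_ctx(.random_bases(n), pre, post)
  cat <- .with_seed(20110912, {
    sc101_mut <- "gaatttacagatacccagatcAcccgggaaaagg"
    sc101_wt <- sub("agatcA", "agatcT", sc101_mut)
    kan_mut <- "cctgtctcttgatcagatcAtgatcccctgc"
    kan_wt <- sub("gatcagatcAtg", "gatcagatcTtg", kan_mut)
    cm_mut <- "ctttcattgccatacgAaattccggatgagcattc"
    cm_wt <- sub("catacgAaattc", "catacgGaattc", cm_mut)
    bbr1_up <- "gaccacgtaggccAacacggtgccgg"
    # assembly contexts: origin sits between AvrII and SacI sites, marker
    # between SacI and AatII, promoter region after AatII and before the
    # cassette EcoRI, genes between the RBS and BamHI, terminator between
    # XhoI and AvrII
    rbs <- "TTTAAGAAGGAGATATACAT"
    ori_fill <- list(S = c(560L, 590L), B = c(610L, 560L))
    origins <- list(
      E = plain(1180L, "CCTAGG", "GAGCTC"),
      A = plain(1180L, "CCTAGG", "GAGCTC"),
      S = embed(ori_fill$S[1], sc101_mut, ori_fill$S[2], "CCTAGG", "GAGCTC"),
      B = embed(ori_fill$B[1], bbr1_up, ori_fill$B[2], "CCTAGG", "GAGCTC"))
    S_wt <- paste0(substr(origins$S, 1, ori_fill$S[1]), toupper(sc101_wt),
                   substr(origins$S, ori_fill$S[1] + nchar(sc101_wt) + 1L,
                          nchar(origins$S)))
    markers <- list(
      a = plain(900L, "GAGCTC", "GACGTC"),
      c = embed(400L, cm_mut, 465L, "GAGCTC", "GACGTC"),
      k = embed(380L, kan_mut, 489L, "GAGCTC", "GACGTC"))
    c_wt <- paste0(substr(markers$c, 1, 400L), toupper(cm_wt),
                   substr(markers$c, 400L + nchar(cm_wt) + 1L, nchar(markers$c)))
    k_wt <- paste0(substr(markers$k, 1, 380L), toupper(kan_wt),
                   substr(markers$k, 380L + nchar(kan_wt) + 1L, nchar(markers$k)))
    promoter_regions <- lapply(1:8, function(i)
      plain(380L + 7L * i, "GACGTC", "GAATTC"))
    names(promoter_regions) <- as.character(1:8)
    genes <- list(rfp = plain(678L, rbs, "GGATCC"),
                  gfp = plain(717L, rbs, "GGATCC"),
                  cfp = plain(720L, rbs, "GGATCC"),
                  yfp = plain(723L, rbs, "GGATCC"))
    list(origins = origins, promoter_regions = promoter_regions,
         markers = markers, genes = genes,
         rbs = rbs,
         terminator = plain(120L, "CTCGAG", "CCTAGG"),
         wildtype = list(S = S_wt, c = c_wt, k = k_wt))
  })
  .pkg_cache$module_catalog <- cat
  cat
}

#' Build an expression-module payload
#'
#' Promoter region, then the BglBrick cassette (EcoRI, spacer, BglII, 5'-UTR
#' ribosome binding site, gene, BamHI, spacer, XhoI), then the terminator.
#'
#' @param promoter_code promoter code 1-8
#' @param gene gene payload sequence (site-free)
#' @param catalog module catalog (see \code{\link{defaultModuleCatalog}})
#' @return payload string (no boundary sites)
#' @export
expressionPayload <- function(promoter_code, gene, catalog = defaultModuleCatalog()) {
  paste0(catalog$promoter_regions[[as.character(promoter_code)]],
         "GAATTC", "AAA", "AGATCT", catalog$rbs, toupper(gene),
         "GGATCC", "AAA", "CTCGAG", catalog$terminator)
}

.assemble_vector_bases <- function(expr, ori, marker) {
  paste0("GACGTC", expr, "CCTAGG", ori, "GAGCTC", marker)
}

#' Construct a single pBb vector
#'
#' @inheritParams formatVectorName
#' @param payload_gene gene payload sequence; defaults to the catalog's rfp
#'   placeholder
#' @param catalog module catalog
#' @return a \linkS4class{PbbVector}
#' @export
buildVector <- function(origin_code, promoter_code, marker_code,
                        payload_label = "rfp", payload_gene = NULL,
                        catalog = defaultModuleCatalog()) {
  formatVectorName(origin_code, promoter_code, marker_code, payload_label)
  if (is.null(payload_gene)) {
    payload_gene <- catalog$genes[[payload_label]] %||% catalog$genes$rfp
  }
  expr <- expressionPayload(promoter_code, payload_gene, catalog)
  ori <- catalog$origins[[origin_code]]
  marker <- catalog$markers[[marker_code]]
  for (nm in c("expression", "origin", "marker")) {
    payload <- switch(nm, expression = expr, origin = ori, marker = marker)
    mod <- new("VectorModule", kind = nm, payload = DnaSeq(payload))
    validObject(mod)
  }
  b <- .assemble_vector_bases(expr, ori, marker)
  ne <- nchar(expr); no <- nchar(ori)
  feats <- data.frame(
    label = c("expression_module", "origin_module", "marker_module"),
    start = c(6L, 6L + ne + 6L, 6L + ne + 6L + no + 6L),
    end = c(6L + ne, 6L + ne + 6L + no, nchar(b)),
    strand = "+", stringsAsFactors = FALSE)
  new("PbbVector", sequence = DnaSeq(b, "circular", features = feats),
      origin_code = origin_code, promoter_code = as.integer(promoter_code),
      marker_code = marker_code, payload_label = payload_label)
}

#' @rdname buildVector
#' @param x a \linkS4class{PbbVector}
#' @return \code{vectorName}: the formatted name; \code{vectorSequence}: the
#'   circular \linkS4class{DnaSeq}
#' @export
vectorName <- function(x)
  formatVectorName(x@origin_code, x@promoter_code, x@marker_code,
                   x@payload_label)

#' @rdname buildVector
#' @export
vectorSequence <- function(x) x@sequence

setMethod("show", "PbbVector", function(object) {
  p <- parseVectorName(vectorName(object))
  cat(sprintf("PbbVector %s (%d bp circular)\n  origin %s | promoter %s | marker %s\n",
              vectorName(object), length(object@sequence), p$origin,
              p$promoter, p$marker))
})

#' Combinatorial pBb library generation
#'
#' Crosses every origin with every promoter and marker; with the full
#' catalogs this enumerates the 12 antibiotic-resistance/origin (AR-ori)
#' backbone combinations and produces the complete set of 96 distinct
#' vectors.
#'
#' @param origins origin codes (default all four)
#' @param promoters promoter codes (default 1-8)
#' @param markers marker codes (default all three)
#' @param payload_label gene label for the cassette payload
#' @param catalog module catalog
#' @return named list of \linkS4class{PbbVector}; the AR-ori combinations
#'   are attached as attribute \code{"ar_ori"} (data.frame)
#' @export
buildLibrary <- function(origins = originCatalog()$code,
                         promoters = promoterCatalog()$code,
                         markers = markerCatalog()$code,
                         payload_label = "rfp",
                         catalog = defaultModuleCatalog()) {
  ar_ori <- expand.grid(marker_code = markers, origin_code = origins,
                        stringsAsFactors = FALSE)
  combos <- expand.grid(marker_code = markers, promoter_code = promoters,
                        origin_code = origins, stringsAsFactors = FALSE)
  vectors <- lapply(seq_len(nrow(combos)), function(i)
    buildVector(combos$origin_code[i], combos$promoter_code[i],
                combos$marker_code[i], payload_label, catalog = catalog))
  names(vectors) <- vapply(vectors, vectorName, "")
  if (anyDuplicated(names(vectors))) stop("duplicate vector names generated")
  attr(vectors, "ar_ori") <- ar_ori
  vectors
}

# pick the digest fragment running from the upstream to the downstream
# boundary cut
.module_fragment <- function(frags, upstream, downstream) {
  for (f in frags)
    if (identical(f@left_end$enzyme, upstream) &&
        identical(f@right_end$enzyme, downstream)) return(f)
  stop(sprintf("no fragment with %s left end and %s right end", upstream, downstream))
}

#' Swap one module of a pBb vector
#'
#' Implemented with the digestion/ligation machinery: the vector and a
#' synthetic donor circle carrying the new payload are both digested at the
#' slot's two boundary enzymes, and the backbone is ligated to the donor's
#' module fragment. The other two modules are untouched.
#'
#' @param vector a \linkS4class{PbbVector}
#' @param kind \code{"expression"}, \code{"origin"} or \code{"marker"}
#' @param new_payload payload string/\linkS4class{DnaSeq} for the slot
#' @param new_code updated name letter/number for the slot (NA to keep)
#' @param payload_label updated gene label (expression swaps)
#' @return a new \linkS4class{PbbVector}
#' @export
swapModule <- function(vector, kind, new_payload, new_code = NA,
                       payload_label = NULL) {
  stopifnot(is(vector, "PbbVector"))
  bounds <- .module_bounds[[kind]]
  if (is.null(bounds)) stop("kind must be expression, origin or marker")
  payload <- if (is(new_payload, "DnaSeq")) dnaBases(new_payload) else toupper(new_payload)
  validObject(new("VectorModule", kind = kind, payload = DnaSeq(payload)))
  seqv <- vectorSequence(vector)
  hits <- findSites(seqv, bounds)
  for (enzname in bounds)
    if (sum(hits$enzyme == enzname) != 1L)
      stop("boundary site not unique: ", enzname)
  vfrags <- digestSeq(seqv, bounds)
  backbone <- NULL
  for (f in vfrags)
    if (!(identical(f@left_end$enzyme, bounds[1]) &&
          identical(f@right_end$enzyme, bounds[2]))) backbone <- f
  donor_bases <- paste0(getEnzymes(bounds[1])$recognition, payload,
                        getEnzymes(bounds[2])$recognition,
                        "TTGTTGTTGTTGTTGTTGTTGTTGTTGTTG")
  donor <- DnaSeq(donor_bases, "circular")
  dfrags <- digestSeq(donor, bounds)
  module_frag <- .module_fragment(dfrags, bounds[1], bounds[2])
  joined <- ligateAll(list(module_frag, backbone), circularize = TRUE)
  codes <- list(origin_code = vector@origin_code,
                promoter_code = vector@promoter_code,
                marker_code = vector@marker_code,
                payload_label = vector@payload_label)
  if (!is.na(new_code)) {
    slot_name <- switch(kind, expression = "promoter_code",
                        origin = "origin_code", marker = "marker_code")
    codes[[slot_name]] <- if (kind == "expression") as.integer(new_code) else new_code
  }
  if (!is.null(payload_label)) codes$payload_label <- payload_label
  new("PbbVector", sequence = joined, origin_code = codes$origin_code,
      promoter_code = codes$promoter_code, marker_code = codes$marker_code,
      payload_label = codes$payload_label)
}

#' Replace the BglII/BamHI gene cassette
#'
#' Excises the current cassette payload between the unique BglII and BamHI
#' sites and ligates in a new BglBrick-valid insert (as the middle fragment
#' of a BglII+BamHI digest of the full part), regenerating both sites at the
#' junctions.
#'
#' @param vector a \linkS4class{PbbVector}
#' @param insert new cassette payload (string, \linkS4class{DnaSeq} or
#'   \linkS4class{BglBrickPart})
#' @param payload_label new gene label for the vector name
#' @return a new \linkS4class{PbbVector}
#' @export
insertGene <- function(vector, insert, payload_label) {
  stopifnot(is(vector, "PbbVector"))
  part <- if (is(insert, "BglBrickPart")) insert else makePart(insert)
  pfrags <- digestSeq(partSequence(part), c("BglII", "BamHI"))
  cassette <- .module_fragment(pfrags, "BglII", "BamHI")
  vfrags <- digestSeq(vectorSequence(vector), c("BglII", "BamHI"))
  backbone <- NULL
  for (f in vfrags)
    if (!(identical(f@left_end$enzyme, "BglII") &&
          identical(f@right_end$enzyme, "BamHI"))) backbone <- f
  joined <- ligateAll(list(cassette, backbone), circularize = TRUE)
  new("PbbVector", sequence = joined, origin_code = vector@origin_code,
      promoter_code = vector@promoter_code, marker_code = vector@marker_code,
      payload_label = payload_label)
}
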