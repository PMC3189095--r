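#' @importFrom Biostrings DNAString reverseComplement
NULL

.pkg_cache <- new.env(parent = emptyenv())

#' Bundled restriction enzyme geometry table
#'
#' The eight enzymes of the pBb platform: the four BglBrick assembly enzymes
#' (EcoRI, BglII, BamHI, XhoI) and the three module boundary enzymes (AatII,
#' AvrII, SacI) plus SpeI (AvrII-compatible ends, used to install the pBBR1
#' origin while destroying one junction site). \code{cut_top} and
#' \code{cut_bottom} are offsets into the recognition hexamer of the top- and
#' bottom-strand cuts; the overhang kind and length follow from them.
#'
#' @return data.frame with columns \code{name}, \code{recognition},
#'   \code{cut_top}, \code{cut_bottom}, \code{overhang_kind},
#'   \code{overhang_len}
#' @examples
#' enzymeTable()
#' @export
enzymeTable <- function() {
  if (is.null(.pkg_cache$enzymes)) {
    path <- system.file("extdata", "enzymes.tsv", package = "BglBrickKit",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    tab$overhang_kind <- ifelse(tab$cut_top < tab$cut_bottom, "five_prime",
                          ifelse(tab$cut_top > tab$cut_bottom, "three_prime",
                                 "blunt"))
    tab$overhang_len <- abs(tab$cut_top - tab$cut_bottom)
    .pkg_cache$enzymes <- tab
  }
  .pkg_cache$enzymes
}

#' @rdname enzymeTable
#' @param names character vector of enzyme names
#' @return \code{getEnzymes}: the matching rows of \code{\link{enzymeTable}}
#' @export
getEnzymes <- function(names) {
  tab <- enzymeTable()
  miss <- setdiff(names, tab$name)
  if (length(miss))
    stop("unknown enzyme(s): ", paste(miss, collapse = ", "))
  tab[match(names, tab$name), , drop = FALSE]
}

#' @rdname enzymeTable
#' @return \code{bglBrickEnzymes}: the four BglBrick assembly enzyme names
#' @export
bglBrickEnzymes <- function() c("EcoRI", "BglII", "BamHI", "XhoI")

.revcomp_chr <- function(x) {
  bad <- regexpr("[^ACGTacgt]", x)
  if (bad > 0L)
    stop(sprintf("non-ACGT character '%s' at position %d (0-based %d)",
                 substr(x, bad, bad), bad, bad - 1L))
  as.character(reverseComplement(DNAString(toupper(x))))
}

#' @rdname revComp
setMethod("revComp", "character", function(x) vapply(x, .revcomp_chr, "", USE.NAMES = FALSE))

#' @rdname revComp
setMethod("revComp", "DnaSeq", function(x) {
  len <- nchar(x@bases)
  f <- x@features
  if (nrow(f) > 0) {
    new_start <- len - f$end
    new_end <- len - f$start
    wraps <- f$end <= f$start  # wrapped features stay wrapped
    if (any(wraps)) {
      new_start[wraps] <- (len - f$end[wraps]) %% len
      new_end[wraps] <- (len - f$start[wraps]) %% len
    }
    f <- data.frame(label = f$label, start = as.integer(new_start %% len),
                    end = as.integer(ifelse(new_end == 0L & f$start == 0L, len, new_end)),
                    strand = ifelse(f$strand == "+", "-", "+"),
                    stringsAsFactors = FALSE)
  }
  DnaSeq(.revcomp_chr(x@bases), topology = x@topology, features = f)
})

setMethod("dnaBases", "DnaSeq", function(x) x@bases)
setMethod("seqTopology", "DnaSeq", function(x) x@topology)
setMethod("seqFeatures", "DnaSeq", function(x) x@features)

#' @export
setMethod("length", "DnaSeq", function(x) nchar(x@bases))

setMethod("show", "DnaSeq", function(object) {
  n <- nchar(object@bases)
  preview <- if (n <= 60) object@bases else
    paste0(substr(object@bases, 1, 28), "...", substr(object@bases, n - 27, n))
  cat(sprintf("DnaSeq (%s, %d bp)\n  %s\n", object@topology, n, preview))
  if (nrow(object@features) > 0)
    cat(sprintf("  %d feature(s): %s\n", nrow(object@features),
                paste(utils::head(object@features$label, 5), collapse = ", ")))
})

setMethod("show", "Fragment", function(object) {
  fmt <- function(e) if (e$kind == "blunt") "blunt"
    else sprintf("%s %s", sub("_", "'", sub("five_prime", "5'", sub("three_prime", "3'", e$kind))), e$overhang)
  cat(sprintf("Fragment (%d nt top strand)\n  left: %s | right: %s\n",
              nchar(object@bases), fmt(object@left_end), fmt(object@right_end)))
})

#' Rotate a circular sequence
#'
#' @param x circular \linkS4class{DnaSeq}
#' @param k number of positions to rotate left (new origin at old position k)
#' @return rotated \linkS4class{DnaSeq} (features dropped)
#' @export
rotateSeq <- function(x, k) {
  x <- DnaSeq(x, topology = seqTopology(DnaSeq(x)))
  if (seqTopology(x) != "circular") stop("rotateSeq requires a circular sequence")
  len <- length(x)
  k <- ((k %% len) + len) %% len
  if (k == 0) return(DnaSeq(dnaBases(x), "circular"))
  b <- dnaBases(x)
  DnaSeq(paste0(substr(b, k + 1, len), substr(b, 1, k)), "circular")
}

#' Rotation/reflection equality of circular sequences
#'
#' Two circular molecules are the same plasmid when one is a rotation of the
#' other or of its reverse complement.
#'
#' @param a,b circular \linkS4class{DnaSeq} objects (or strings, coerced)
#' @return logical
#' @export
circularEqual <- function(a, b) {
  a <- if (is(a, "DnaSeq")) a else DnaSeq(a, "circular")
  b <- if (is(b, "DnaSeq")) b else DnaSeq(b, "circular")
  if (seqTopology(a) != "circular" || seqTopology(b) != "circular")
    stop("circularEqual requires circular sequences")
  if (length(a) != length(b)) return(FALSE)
  doubled <- paste0(dnaBases(a), dnaBases(a))
  grepl(dnaBases(b), doubled, fixed = TRUE) ||
    grepl(.revcomp_chr(dnaBases(b)), doubled, fixed = TRUE)
}

#' Scan for restriction sites
#'
#' Reports every occurrence of each enzyme's recognition hexamer on the
#' canonical top strand, including occurrences spanning the origin of a
#' circular molecule. All bundled recognition sequences are palindromic, so
#' no separate bottom-strand hits exist.
#'
#' @param seq \linkS4class{DnaSeq} or DNA string (topology taken from the
#'   object; strings are treated as linear)
#' @param enzymes character vector of enzyme names (see
#'   \code{\link{enzymeTable}})
#' @return data.frame with columns \code{enzyme}, \code{position} (0-based
#'   start of the recognition hexamer) and \code{wraps_origin}, sorted by
#'   position
#' @examples
#' findSites(DnaSeq("aaaAGATCTttt"), "BglII")
#' @export
findSites <- function(seq, enzymes) {
  seq <- if (is(seq, "DnaSeq")) seq else DnaSeq(seq)
  enz <- getEnzymes(enzymes)
  b <- dnaBases(seq)
  len <- nchar(b)
  circular <- seqTopology(seq) == "circular"
  subject <- if (circular) paste0(b, substr(b, 1, min(5L, len))) else b
  out <- lapply(seq_len(nrow(enz)), function(i) {
    pat <- enz$recognition[i]
    starts <- integer()
    from <- 1L
    repeat {
      hit <- regexpr(pat, substr(subject, from, nchar(subject)), fixed = TRUE)
      if (hit < 0L) break
      pos <- from + as.integer(hit) - 1L
      starts <- c(starts, pos)
      from <- pos + 1L
    }
    starts <- starts[starts <= len]  # dedupe doubled-string scan
    if (!length(starts)) return(NULL)
    data.frame(enzyme = enz$name[i], position = starts - 1L,
               wraps_origin = starts - 1L + 6L > len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(enzyme = character(), position = integer(),
                      wraps_origin = logical(), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# substring at circular coordinates [i, j) (0-based); j may exceed len
.circ_substr <- function(b, i, j) {
  len <- nchar(b)
  doubled <- paste0(b, b)
  substr(doubled, i + 1L, j)
}

#' Digest a sequence into end-typed fragments
#'
#' Cuts at every recognition site of the given enzymes. A circular molecule
#' with n cut positions yields n fragments; a linear molecule yields n+1,
#' with native blunt termini at the molecule ends. Each internal end carries
#' the overhang chemistry implied by the generating enzyme's cut offsets
#' (BglII/BamHI: 4-nt 5' overhang GATC; AatII/SacI: 4-nt 3' overhangs).
#'
#' @param seq \linkS4class{DnaSeq}
#' @param enzymes character vector of enzyme names
#' @return list of \linkS4class{Fragment}, in parent order starting from the
#'   first top-strand cut (circular) or the native left end (linear)
#' @export
digestSeq <- function(seq, enzymes) {
  seq <- if (is(seq, "DnaSeq")) seq else DnaSeq(seq)
  hits <- findSites(seq, enzymes)
  if (nrow(hits) == 0)
    stop("no cut: none of the given enzymes has a site in this sequence")
  enz <- enzymeTable()
  b <- dnaBases(seq)
  len <- nchar(b)
  e <- enz[match(hits$enzyme, enz$name), ]
  cuts <- data.frame(
    enzyme = hits$enzyme,
    top = hits$position + e$cut_top,
    oh_start = hits$position + pmin(e$cut_top, e$cut_bottom),
    oh_end = hits$position + pmax(e$cut_top, e$cut_bottom),
    kind = e$overhang_kind,
    stringsAsFactors = FALSE)
  circular <- seqTopology(seq) == "circular"
  if (circular) {
    cuts$top <- cuts$top %% len
  } else if (any(cuts$top > len) || any(cuts$oh_end > len)) {
    stop("cut position beyond the end of a linear sequence")
  }
  cuts <- cuts[order(cuts$top), , drop = FALSE]
  if (anyDuplicated(cuts$top))
    stop("coincident cut positions are not supported")
  ends <- lapply(seq_len(nrow(cuts)), function(i) {
    oh <- if (cuts$kind[i] == "blunt") "" else
      .circ_substr(b, cuts$oh_start[i] %% len,
                   (cuts$oh_start[i] %% len) + (cuts$oh_end[i] - cuts$oh_start[i]))
    list(kind = cuts$kind[i], overhang = oh, enzyme = cuts$enzyme[i])
  })
  n <- nrow(cuts)
  frags <- list()
  if (circular) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      from <- cuts$top[i]
      to <- if (j == 1L) cuts$top[1L] + len else cuts$top[j]
      frags[[i]] <- .fragment(.circ_substr(b, from, to), ends[[i]], ends[[j]])
    }
  } else {
    bounds <- c(0L, cuts$top, len)
    endlist <- c(list(.blunt_end()), ends, list(.blunt_end()))
    for (i in seq_len(n + 1L)) {
      if (bounds[i + 1L] == bounds[i]) stop("zero-length terminal fragment")
      frags[[i]] <- .fragment(substr(b, bounds[i] + 1L, bounds[i + 1L]),
                              endlist[[i]], endlist[[i + 1L]])
    }
  }
  frags
}

#' Ligation compatibility of two fragment ends
#'
#' Ends join iff both are blunt, or both carry the same overhang kind with
#' matching overhang sequence. Cross-enzyme joins are allowed when the
#' chemistry matches (AvrII+SpeI share the 5' CTAG overhang; BglII+BamHI
#' share 5' GATC).
#'
#' @param a_end,b_end end-chemistry lists (see \linkS4class{Fragment})
#' @return list with \code{compatible} (logical) and, when incompatible, a
#'   \code{reason} naming both overhangs
#' @export
ligationCheck <- function(a_end, b_end) {
  if (a_end$kind == "blunt" && b_end$kind == "blunt")
    return(list(compatible = TRUE))
  if (a_end$kind == b_end$kind && identical(a_end$overhang, b_end$overhang))
    return(list(compatible = TRUE))
  list(compatible = FALSE,
       reason = sprintf(
         "incompatible ends: %s [%s] (from %s) vs %s [%s] (from %s)",
         a_end$kind, a_end$overhang,
         if (is.na(a_end$enzyme %||% NA)) "terminus" else a_end$enzyme,
         b_end$kind, b_end$overhang,
         if (is.na(b_end$enzyme %||% NA)) "terminus" else b_end$enzyme),
       a = a_end, b = b_end)
}

#' Join two fragments (right end of a to left end of b)
#'
#' The joined top strand is the concatenation of the two fragment strands, so
#' the junction sequence can be inspected directly (e.g. a BamHI-cut end
#' joined to a BglII-cut end emits the GGATCT scar, cut by neither enzyme).
#'
#' @param a,b \linkS4class{Fragment}
#' @return a \linkS4class{Fragment} spanning both inputs
#' @export
ligateFragments <- function(a, b) {
  chk <- ligationCheck(a@right_end, b@left_end)
  if (!chk$compatible) stop(chk$reason)
  .fragment(paste0(a@bases, b@bases), a@left_end, b@right_end)
}

#' Circularize a fragment by joining its own ends
#'
#' @param f \linkS4class{Fragment}
#' @return circular \linkS4class{DnaSeq}
#' @export
circularizeFragment <- function(f) {
  chk <- ligationCheck(f@right_end, f@left_end)
  if (!chk$compatible) stop(chk$reason)
  DnaSeq(f@bases, "circular")
}

#' Ligate a list of fragments in order
#'
#' @param frags list of \linkS4class{Fragment}
#' @param circularize close the product into a circle (default TRUE)
#' @return circular \linkS4class{DnaSeq} if \code{circularize}, else a
#'   \linkS4class{Fragment}
#' @export
ligateAll <- function(frags, circularize = TRUE) {
  stopifnot(length(frags) >= 1L)
  out <- Reduce(ligateFragments, frags)
  if (circularize) circularizeFragment(out) else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
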