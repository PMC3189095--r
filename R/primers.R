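#' Construct a primer
#'
#' A primer is a 5' tail (non-annealing addition, possibly empty) followed by
#' a 3' annealing region that must match its template exactly. Specificity is
#' "exact match, unique occurrence": mismatch-tolerant annealing is not
#' modeled.
#'
#' @param bases full primer 5'->3' (case-insensitive)
#' @param tail the 5' non-annealing portion (must be a prefix of
#'   \code{bases}); default none
#' @param name optional label
#' @param min_anneal minimum annealing length enforced (default 15)
#' @return a list of class \code{"Primer"} with elements \code{name},
#'   \code{bases}, \code{tail}, \code{anneal}
#' @examples
#' p <- primer("agatcaGACGTCgacaccatcgaatggtgcaaaacc", tail = "agatcaGACGTC")
#' p$anneal
#' @export
primer <- function(bases, tail = "", name = "", min_anneal = 15L) {
  bases <- toupper(bases); tail <- toupper(tail)
  if (!startsWith(bases, tail)) stop("tail must be a prefix of the primer")
  anneal <- substr(bases, nchar(tail) + 1L, nchar(bases))
  if (nchar(anneal) < min_anneal)
    stop(sprintf("annealing region too short (%d < %d)", nchar(anneal), min_anneal))
  structure(list(name = name, bases = bases, tail = tail, anneal = anneal),
            class = "Primer")
}

#' @export
print.Primer <- function(x, ...) {
  cat(sprintf("Primer %s: 5'-%s|%s-3' (tail %d nt, anneal %d nt, Tm %.1f C)\n",
              x$name, tolower(x$tail), x$anneal, nchar(x$tail), nchar(x$anneal),
              primerTm(x$anneal)))
  invisible(x)
}

# unique occurrence positions (0-based) of pattern on the top strand;
# circular templates are scanned across the origin
.anneal_loci <- function(template, pattern) {
  hits <- findSites_pattern(dnaBases(template), pattern,
                            circular = seqTopology(template) == "circular")
  hits
}

# generic exact-substring scan used by primer annealing (patterns are not
# restricted to enzyme hexamers)
findSites_pattern <- function(b, pattern, circular = FALSE) {
  len <- nchar(b)
  subject <- if (circular) paste0(b, substr(b, 1, min(nchar(pattern) - 1L, len))) else b
  starts <- integer(); from <- 1L
  repeat {
    hit <- regexpr(pattern, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (hit < 0L) break
    pos <- from + as.integer(hit) - 1L
    starts <- c(starts, pos)
    from <- pos + 1L
  }
  starts[starts <= len] - 1L
}

#' Simulate a PCR amplification
#'
#' The forward annealing region must occur exactly once on the top strand and
#' the reverse annealing region exactly once on the bottom strand; the
#' product is \code{fwd tail + template span + revcomp(rev tail)}. On a
#' circular template an amplicon spanning the origin is permitted.
#'
#' @param template \linkS4class{DnaSeq} or string
#' @param fwd,rev \code{\link{primer}} objects
#' @return linear \linkS4class{DnaSeq}
#' @export
simulatePcr <- function(template, fwd, rev) {
  template <- if (is(template, "DnaSeq")) template else DnaSeq(template)
  b <- dnaBases(template)
  len <- nchar(b)
  f_loci <- .anneal_loci(template, fwd$anneal)
  r_pat <- .revcomp_chr(rev$anneal)
  r_loci <- .anneal_loci(template, r_pat)
  if (length(f_loci) != 1L)
    stop(sprintf("forward primer anneals at %d loci (top strand): [%s]",
                 length(f_loci), paste(f_loci, collapse = ", ")))
  if (length(r_loci) != 1L)
    stop(sprintf("reverse primer anneals at %d loci (bottom strand): [%s]",
                 length(r_loci), paste(r_loci, collapse = ", ")))
  start <- f_loci
  end <- r_loci + nchar(r_pat)  # 0-based exclusive
  circular <- seqTopology(template) == "circular"
  if (end <= start) {
    if (!circular)
      stop("forward locus must lie upstream of the reverse locus on a linear template")
    end <- end + len
  }
  span <- .circ_substr(b, start, end)
  DnaSeq(paste0(fwd$tail, span, .revcomp_chr(rev$tail)), "linear")
}

#' Design a mutagenic primer pair
#'
#' QuikChange-style: the forward primer copies the template across
#' \code{position} with the substituted base at its center and \code{arm_len}
#' matching bases on each side; the reverse primer is its exact reverse
#' complement, mirroring the printed site-removal pairs.
#'
#' @param template \linkS4class{DnaSeq} or string
#' @param position 0-based position of the base to substitute
#' @param alt_base replacement base
#' @param arm_len matching bases on each side of the mutation (>= 10); a
#'   length-2 vector \code{c(left, right)} gives asymmetric arms, matching
#'   the geometry of the printed site-removal primers (capital base roughly
#'   but not exactly centered, total ~26-34 nt)
#' @return list with \code{fwd} and \code{rev} \code{\link{primer}} objects
#'   and \code{mut_offset} (0-based offset of the mutation in the forward
#'   primer)
#' @export
designMutagenicPair <- function(template, position, alt_base, arm_len = 13L) {
  template <- if (is(template, "DnaSeq")) template else DnaSeq(template)
  arm <- rep(as.integer(arm_len), length.out = 2L)
  if (any(arm < 10L)) stop("arm_len must be at least 10")
  b <- dnaBases(template)
  len <- nchar(b)
  circular <- seqTopology(template) == "circular"
  if (!circular && (position - arm[1] < 0L || position + arm[2] >= len))
    stop("position too close to the end of a linear template for the requested arms")
  lo <- (position - arm[1]) %% len
  window <- .circ_substr(b, lo, lo + arm[1] + arm[2] + 1L)
  substr(window, arm[1] + 1L, arm[1] + 1L) <- toupper(alt_base)
  list(fwd = primer(window, name = "mut_F"),
       rev = primer(.revcomp_chr(window), name = "mut_R"),
       mut_offset = arm[1])
}

#' Apply a mutagenic primer pair to its template
#'
#' Locates the two annealing arms of the forward primer on the template and
#' substitutes the center base, i.e. the in silico outcome of whole-plasmid
#' mutagenesis with \code{\link{designMutagenicPair}} primers.
#'
#' @param template \linkS4class{DnaSeq} or string
#' @param fwd forward mutagenic primer, or the pair list from
#'   \code{\link{designMutagenicPair}}
#' @param mut_offset 0-based offset of the mutation in the forward primer;
#'   defaults to the pair's recorded offset, or the center for a bare primer
#' @return mutated sequence, same topology
#' @export
simulateMutagenesis <- function(template, fwd, mut_offset = NULL) {
  template <- if (is(template, "DnaSeq")) template else DnaSeq(template)
  if (is.list(fwd) && !inherits(fwd, "Primer") && !is.null(fwd$fwd)) {
    mut_offset <- mut_offset %||% fwd$mut_offset
    fwd <- fwd$fwd
  }
  bases <- if (inherits(fwd, "Primer")) fwd$bases else toupper(fwd)
  n <- nchar(bases)
  if (is.null(mut_offset)) {
    if (n %% 2L == 0L)
      stop("mutation offset required for an even-length mutagenic primer")
    mut_offset <- (n - 1L) %/% 2L
  }
  arm <- as.integer(mut_offset)
  left <- substr(bases, 1L, arm)
  right <- substr(bases, arm + 2L, n)
  alt <- substr(bases, arm + 1L, arm + 1L)
  b <- dnaBases(template)
  # exact-context scan with one free center base
  len <- nchar(b)
  subject <- if (seqTopology(template) == "circular") paste0(b, substr(b, 1L, n - 1L)) else b
  m <- gregexpr(paste0(left, "[ACGT]", right), subject)[[1]]
  loci <- as.integer(m[m > 0L])
  loci <- unique((loci[loci <= len] - 1L) %% len)
  if (length(loci) != 1L)
    stop(sprintf("mutagenic primer context found at %d loci", length(loci)))
  pos <- (loci + arm) %% len
  substr(b, pos + 1L, pos + 1L) <- alt
  DnaSeq(b, topology = seqTopology(template), features = seqFeatures(template))
}

#' Design a splice-overlap-extension (SOE) fusion
#'
#' Plans the PCRs that fuse two or more segments into one product, optionally
#' introducing point mutations near the junctions (carried by the inner
#' primer pairs, which are mutual reverse complements) and outer 5' tails.
#' The expected product is pure sequence algebra: the concatenation of the
#' (possibly mutated) segments with the outer tails.
#'
#' @param segments list of \linkS4class{DnaSeq} or strings, fused in order
#' @param mutations optional data.frame with columns \code{position} (0-based
#'   in fused coordinates) and \code{alt}
#' @param outer_tails character vector \code{c(fwd = , rev = )} of 5' tails
#'   for the outermost primers (reverse tail given 5'->3' on the bottom
#'   strand)
#' @param arm overlap half-width at each junction (default 15; overlap length
#'   is \code{2 * arm})
#' @return list of class \code{"SoePlan"}: \code{segments} (mutated),
#'   \code{fused}, \code{junctions} (fused coordinates), \code{inner_primers}
#'   (per junction, \code{fwd}/\code{rev}), \code{outer} primers,
#'   \code{steps} (per-segment expected products) and \code{warnings}
#' @export
designSoeFusion <- function(segments, mutations = NULL,
                            outer_tails = c(fwd = "", rev = ""), arm = 15L) {
  if (length(segments) < 1L) stop("at least one segment required")
  segs <- vapply(segments, function(s)
    if (is(s, "DnaSeq")) dnaBases(s) else toupper(s), "")
  lens <- nchar(segs)
  fused <- paste(segs, collapse = "")
  if (!is.null(mutations) && nrow(mutations) > 0) {
    for (i in seq_len(nrow(mutations))) {
      p <- as.integer(mutations$position[i])
      substr(fused, p + 1L, p + 1L) <- toupper(mutations$alt[i])
    }
  }
  junctions <- cumsum(lens)[-length(lens)]
  warnings <- character()
  inner <- lapply(junctions, function(j) {
    lo <- max(0L, j - arm); hi <- min(nchar(fused), j + arm)
    ov <- substr(fused, lo + 1L, hi)
    if (nchar(ov) < 15L)
      warnings <<- c(warnings, sprintf("junction at %d: overlap shorter than 15 nt", j))
    if (nrow(findSites(DnaSeq(ov), bglBrickEnzymes())) > 0)
      warnings <<- c(warnings,
                     sprintf("junction at %d: overlap contains a forbidden BglBrick site", j))
    list(fwd = primer(ov, name = sprintf("soe_%d_F", j), min_anneal = min(15L, nchar(ov))),
         rev = primer(.revcomp_chr(ov), name = sprintf("soe_%d_R", j),
                      min_anneal = min(15L, nchar(ov))))
  })
  if (!is.null(mutations) && nrow(mutations) > 0) {
    for (i in seq_len(nrow(mutations))) {
      p <- as.integer(mutations$position[i])
      covered <- length(junctions) == 0L ||
        any(abs(p - junctions) <= arm)
      if (!covered)
        warnings <- c(warnings, sprintf("mutation at %d lies outside every junction overlap", p))
    }
  }
  tails <- c(fwd = toupper(outer_tails[["fwd"]] %||% ""),
             rev = toupper(outer_tails[["rev"]] %||% ""))
  bounds <- c(0L, junctions, nchar(fused))
  steps <- lapply(seq_along(segs), function(i) {
    lo <- max(0L, bounds[i] - if (i > 1L) arm else 0L)
    hi <- min(nchar(fused), bounds[i + 1L] + if (i < length(segs)) arm else 0L)
    prod <- substr(fused, lo + 1L, hi)
    if (i == 1L) prod <- paste0(tails[["fwd"]], prod)
    if (i == length(segs)) prod <- paste0(prod, .revcomp_chr(tails[["rev"]]))
    list(segment = i, product = prod)
  })
  structure(list(segments = segs, fused = fused, junctions = junctions,
                 inner_primers = inner, outer_tails = tails, steps = steps,
                 warnings = warnings),
            class = "SoePlan")
}

#' Simulate a SOE fusion plan
#'
#' @param plan a \code{"SoePlan"} from \code{\link{designSoeFusion}}
#' @return linear \linkS4class{DnaSeq}: outer forward tail + fused segments +
#'   revcomp(outer reverse tail)
#' @export
simulateSoe <- function(plan) {
  stopifnot(inherits(plan, "SoePlan"))
  DnaSeq(paste0(plan$outer_tails[["fwd"]], plan$fused,
                .revcomp_chr(plan$outer_tails[["rev"]])), "linear")
}

#' Primer melting temperature
#'
#' Wallace rule \code{2(A+T) + 4(G+C)} for annealing regions shorter than 14
#' nt; the simple GC formula \code{64.9 + 41 (GC - 16.4) / N} otherwise.
#' Deterministic and dependency-free; both conventions are documented so the
#' formula can be swapped.
#'
#' @param anneal annealing sequence (>= 8 nt)
#' @return temperature in degrees Celsius
#' @examples
#' primerTm("AAAATTTT")  # 16
#' @export
primerTm <- function(anneal) {
  anneal <- toupper(anneal)
  n <- nchar(anneal)
  if (n < 8L) stop("annealing region too short for a Tm estimate (< 8 nt)")
  chars <- strsplit(anneal, "")[[1]]
  gc <- sum(chars %in% c("G", "C"))
  at <- sum(chars %in% c("A", "T"))
  if (n < 14L) 2 * at + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
}
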