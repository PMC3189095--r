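#' Bundled E. coli K-12 codon usage
#'
#' Standard published codon frequencies (occurrences per 1000 codons),
#' normalized within each amino acid to give the relative synonymous-codon
#' frequency used to rank silent substitutions. The table is swappable: any
#' data.frame with columns \code{codon}, \code{aa}, \code{rel_freq} covering
#' the 61 sense codons works.
#'
#' @return data.frame with columns \code{codon}, \code{aa}, \code{per1000},
#'   \code{rel_freq}
#' @export
codonUsageTable <- function() {
  if (is.null(.pkg_cache$codon_usage)) {
    path <- system.file("extdata", "codon_usage_ecoli_k12.tsv",
                        package = "BglBrickKit", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    tab$rel_freq <- stats::ave(tab$per1000, tab$aa, FUN = function(x) x / sum(x))
    .pkg_cache$codon_usage <- tab
  }
  .pkg_cache$codon_usage
}

.translate_chr <- function(x) {
  as.character(translate(DNAString(x), genetic.code = GENETIC_CODE,
                         if.fuzzy.codon = "error"))
}

# all forbidden-site positions, as a canonical key set
.site_keys <- function(seq, enzymes) {
  h <- findSites(seq, enzymes)
  paste(h$enzyme, h$position)
}

#' Propose single-base substitutions that remove a restriction site
#'
#' Enumerates every single-nucleotide substitution inside the recognition
#' hexamer that (a) destroys the target site and (b) creates no new site
#' from the forbidden enzyme set. In CDS mode only synonymous substitutions
#' (translation of the annotated reading frame unchanged) qualify, ranked by
#' the relative codon usage of the new codon, descending. In noncoding mode
#' candidates are ranked by distance from annotated features (farther first,
#' ties by position ascending); regulatory activity effects of such edits are
#' not modeled and the plan is flagged accordingly.
#'
#' @param seq \linkS4class{DnaSeq}
#' @param position 0-based start of the target recognition hexamer
#' @param enzyme name of the enzyme whose site is to be removed
#' @param region either \code{"noncoding"} or a list
#'   \code{list(type = "cds", start, end)} giving the 0-based half-open
#'   top-strand coordinates of the open reading frame containing the site
#' @param usage codon usage table (see \code{\link{codonUsageTable}})
#' @param enzymes forbidden enzyme set (default the four BglBrick enzymes)
#' @return data.frame of mutation plans with columns \code{position} (0-based
#'   edit position), \code{ref_base}, \code{alt_base}, \code{enzyme},
#'   \code{site_position}, \code{context}, \code{synonymous},
#'   \code{codon_before}, \code{codon_after}, \code{usage_score},
#'   \code{regulatory_note}; zero rows with attribute
#'   \code{undomesticable = TRUE} when no substitution qualifies
#' @export
proposeRemoval <- function(seq, position, enzyme, region = "noncoding",
                           usage = codonUsageTable(),
                           enzymes = bglBrickEnzymes()) {
  seq <- if (is(seq, "DnaSeq")) seq else DnaSeq(seq)
  b <- dnaBases(seq)
  enz <- getEnzymes(enzyme)
  site <- substr(b, position + 1L, position + 6L)
  if (!identical(site, enz$recognition))
    stop(sprintf("no %s site at position %d (found '%s')", enzyme, position, site))
  before_keys <- .site_keys(seq, enzymes)
  target_key <- paste(enzyme, position)
  is_cds <- is.list(region) && identical(region$type, "cds")
  if (is_cds) {
    if ((region$end - region$start) %% 3L != 0L)
      stop("cds region length must be a multiple of 3")
    if (position < region$start || position + 6L > region$end)
      stop("site does not lie within the annotated cds region")
    orf_before <- substr(b, region$start + 1L, region$end)
    aa_before <- .translate_chr(orf_before)
  }
  plans <- list()
  for (off in 0:5) {
    pos <- position + off
    ref <- substr(b, pos + 1L, pos + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      nb <- b
      substr(nb, pos + 1L, pos + 1L) <- alt
      nseq <- DnaSeq(nb, topology = seqTopology(seq), features = seqFeatures(seq))
      after_keys <- .site_keys(nseq, enzymes)
      if (target_key %in% after_keys) next            # site survives
      if (length(setdiff(after_keys, before_keys)) > 0) next  # new site created
      if (is_cds) {
        orf_after <- substr(nb, region$start + 1L, region$end)
        if (!identical(.translate_chr(orf_after), aa_before)) next
        frame_off <- (pos - region$start) %% 3L
        cstart <- pos - frame_off
        codon_before <- substr(b, cstart + 1L, cstart + 3L)
        codon_after <- substr(nb, cstart + 1L, cstart + 3L)
        score <- usage$rel_freq[match(codon_after, usage$codon)]
        plans[[length(plans) + 1L]] <- data.frame(
          position = pos, ref_base = ref, alt_base = alt, enzyme = enzyme,
          site_position = position, context = "cds", synonymous = TRUE,
          codon_before = codon_before, codon_after = codon_after,
          usage_score = score, regulatory_note = NA_character_,
          stringsAsFactors = FALSE)
      } else {
        f <- seqFeatures(seq)
        dist <- if (nrow(f) == 0) NA_real_ else
          min(pmax(0, pmax(f$start - pos, pos - (f$end - 1L))))
        plans[[length(plans) + 1L]] <- data.frame(
          position = pos, ref_base = ref, alt_base = alt, enzyme = enzyme,
          site_position = position, context = "noncoding", synonymous = NA,
          codon_before = NA_character_, codon_after = NA_character_,
          usage_score = dist,
          regulatory_note = "regulatory context - effect not modeled",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, plans)
  if (is.null(out) || nrow(out) == 0) {
    out <- data.frame(position = integer(), ref_base = character(),
                      alt_base = character(), enzyme = character(),
                      site_position = integer(), context = character(),
                      synonymous = logical(), codon_before = character(),
                      codon_after = character(), usage_score = numeric(),
                      regulatory_note = character(), stringsAsFactors = FALSE)
    attr(out, "undomesticable") <- TRUE
    return(out)
  }
  ord <- if (is_cds) order(-out$usage_score, out$position)
         else order(-ifelse(is.na(out$usage_score), Inf, out$usage_score), out$position)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "undomesticable") <- FALSE
  out
}

#' Apply a mutation plan
#'
#' @param seq \linkS4class{DnaSeq}
#' @param plan one row of the data.frame returned by
#'   \code{\link{proposeRemoval}} (or any list with \code{position},
#'   \code{ref_base}, \code{alt_base})
#' @param enzymes forbidden enzyme set used for the post-condition check
#' @return edited \linkS4class{DnaSeq}; length unchanged, forbidden-site
#'   count strictly decreased
#' @export
applyPlan <- function(seq, plan, enzymes = bglBrickEnzymes()) {
  seq <- if (is(seq, "DnaSeq")) seq else DnaSeq(seq)
  if (is.data.frame(plan)) {
    stopifnot(nrow(plan) == 1L)
    plan <- as.list(plan)
  }
  b <- dnaBases(seq)
  pos <- as.integer(plan$position)
  ref <- substr(b, pos + 1L, pos + 1L)
  if (!identical(ref, toupper(plan$ref_base)))
    stop(sprintf("stale plan: expected %s at position %d, found %s",
                 plan$ref_base, pos, ref))
  substr(b, pos + 1L, pos + 1L) <- toupper(plan$alt_base)
  out <- DnaSeq(b, topology = seqTopology(seq), features = seqFeatures(seq))
  n_before <- length(.site_keys(seq, enzymes))
  n_after <- length(.site_keys(out, enzymes))
  if (n_after >= n_before)
    stop("plan does not reduce the forbidden-site count")
  out
}

#' Iteratively domesticate a sequence
#'
#' Applies the top-ranked removal plan for each forbidden site in turn until
#' none remain or a site is undomesticable by single substitution. A sequence
#' with k forbidden sites terminates in at most k applications.
#'
#' @inheritParams proposeRemoval
#' @param regions optional list of cds region descriptors (each
#'   \code{list(type = "cds", start, end)}); sites falling inside one are
#'   treated as coding
#' @return list with \code{seq} (edited \linkS4class{DnaSeq}),
#'   \code{plans} (data.frame of applied plans) and \code{complete} (logical;
#'   FALSE when some site was undomesticable)
#' @export
domesticateSeq <- function(seq, regions = list(), usage = codonUsageTable(),
                           enzymes = bglBrickEnzymes()) {
  seq <- if (is(seq, "DnaSeq")) seq else DnaSeq(seq)
  applied <- list()
  k <- nrow(findSites(seq, enzymes))
  for (step in seq_len(max(k, 0L))) {
    hits <- findSites(seq, enzymes)
    if (nrow(hits) == 0) break
    hit <- hits[1L, ]
    region <- "noncoding"
    for (r in regions) {
      if (hit$position >= r$start && hit$position + 6L <= r$end) { region <- r; break }
    }
    plans <- proposeRemoval(seq, hit$position, hit$enzyme, region = region,
                            usage = usage, enzymes = enzymes)
    if (nrow(plans) == 0)
      return(list(seq = seq, plans = do.call(rbind, applied),
                  complete = FALSE))
    seq <- applyPlan(seq, plans[1L, ], enzymes = enzymes)
    applied[[length(applied) + 1L]] <- plans[1L, ]
  }
  list(seq = seq, plans = do.call(rbind, applied),
       complete = nrow(findSites(seq, enzymes)) == 0)
}

#' Bundled mutagenesis quality-control primer pairs
#'
#' The six site-removal primer pairs used during vector construction, read
#' from the packaged construction-primer table. The capitalized base in each
#' printed primer is the introduced mutation.
#'
#' @return data.frame with columns \code{pair}, \code{fwd_name},
#'   \code{rev_name}, \code{fwd}, \code{rev}, \code{enzyme}, \code{component}
#' @export
qcPrimerPairs <- function() {
  pairs <- utils::read.delim(system.file("extdata", "qc_primer_pairs.tsv",
                                         package = "BglBrickKit", mustWork = TRUE),
                             stringsAsFactors = FALSE)
  prim <- constructionPrimers()
  pairs$fwd <- prim$sequence[match(pairs$fwd_name, prim$name)]
  pairs$rev <- prim$sequence[match(pairs$rev_name, prim$name)]
  pairs
}

#' Full construction primer table
#'
#' @return data.frame with columns \code{name}, \code{sequence} (mixed case
#'   as printed: capitals mark mutations or added restriction-site tails) and
#'   \code{description}
#' @export
constructionPrimers <- function() {
  utils::read.delim(system.file("extdata", "construction_primers.tsv",
                                package = "BglBrickKit", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Verify the bundled site-removal primer pairs
#'
#' For each mutagenesis QC pair, checks that (a) forward and reverse primers
#' are mutual reverse complements, (b) the capitalized base is the unique
#' difference from the implied wild-type context, and (c) the implied
#' wild-type contains the named recognition site while the mutant does not.
#' The wild-type base is recovered by requiring the named site to exist at
#' the capital position (only mutant primers are printed).
#'
#' @return data.frame, one row per pair, with logical columns
#'   \code{revcomp_ok}, \code{single_diff_ok}, \code{wt_has_site},
#'   \code{mutant_clean}, plus \code{wt_base} and \code{mut_base}
#' @export
checkQcPrimers <- function() {
  pairs <- qcPrimerPairs()
  enz <- enzymeTable()
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    fwd <- pairs$fwd[i]; rev <- pairs$rev[i]
    site <- enz$recognition[enz$name == pairs$enzyme[i]]
    cap <- regexpr("[A-Z]", fwd)
    mut_base <- substr(fwd, cap, cap)
    fu <- toupper(fwd)
    wt_base <- NA_character_
    for (bse in setdiff(c("A", "C", "G", "T"), mut_base)) {
      cand <- fu
      substr(cand, cap, cap) <- bse
      lo <- max(1L, as.integer(cap) - 5L)
      window <- substr(cand, lo, min(nchar(cand), as.integer(cap) + 5L))
      if (grepl(site, window, fixed = TRUE)) { wt_base <- bse; break }
    }
    wt <- fu
    if (!is.na(wt_base)) substr(wt, cap, cap) <- wt_base
    data.frame(
      pair = pairs$pair[i], enzyme = pairs$enzyme[i],
      revcomp_ok = identical(.revcomp_chr(fu), toupper(rev)),
      single_diff_ok = sum(strsplit(fu, "")[[1]] != strsplit(wt, "")[[1]]) == 1L,
      wt_has_site = !is.na(wt_base) && grepl(site, wt, fixed = TRUE),
      mutant_clean = !grepl(site, fu, fixed = TRUE),
      wt_base = wt_base, mut_base = mut_base, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
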