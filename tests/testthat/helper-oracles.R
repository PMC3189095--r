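# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the package's own scanning/digestion code paths:
# site scanning is done by doubled-string substring comparison, overhang
# chemistry by direct cut-offset string surgery.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force site scan: compare every rotation window of the (doubled)
# string against the recognition hexamer
oracle_scan <- function(bases, recognition, circular = FALSE) {
  len <- nchar(bases)
  subject <- if (circular) paste0(bases, bases) else bases
  k <- nchar(recognition)
  hits <- integer()
  upper <- if (circular) len else len - k + 1L
  for (i in seq_len(max(upper, 0L))) {
    if (substr(subject, i, i + k - 1L) == recognition) hits <- c(hits, i - 1L)
  }
  hits
}

# cut-offset oracle: cut the top strand at site+cut_top and the bottom
# strand (as top-strand coordinates) at site+cut_bottom; the overhang is
# the region between the two cuts, 5' when the top cut comes first
oracle_overhang <- function(bases, site_pos, cut_top, cut_bottom) {
  a <- site_pos + min(cut_top, cut_bottom)
  b <- site_pos + max(cut_top, cut_bottom)
  list(kind = if (cut_top < cut_bottom) "five_prime"
              else if (cut_top > cut_bottom) "three_prime" else "blunt",
       overhang = if (cut_top == cut_bottom) "" else substr(bases, a + 1L, b))
}

# ligation-junction oracle: join the upstream half (up to the top cut of
# enzyme A's site) with the downstream half (from the top cut of enzyme B's
# site); emits the junction hexamer context
oracle_junction <- function(up_bases, up_site, enz_a, down_bases, down_site, enz_b) {
  ea <- getEnzymes(enz_a); eb <- getEnzymes(enz_b)
  left <- substr(up_bases, 1, up_site + ea$cut_top)
  right <- substr(down_bases, down_site + eb$cut_top + 1L, nchar(down_bases))
  paste0(left, right)
}

# exhaustive single-edit oracle for site removal: every substitution in the
# hexamer, filtered by (destroys site, creates no new forbidden site,
# synonymous if coding)
oracle_removal <- function(bases, site_pos, recognition, enzymes,
                           cds = NULL) {
  recs <- getEnzymes(enzymes)$recognition
  count_sites <- function(s)
    sum(vapply(recs, function(r) length(oracle_scan(s, r)), 0L))
  keys <- function(s)
    unlist(lapply(recs, function(r) {
      h <- oracle_scan(s, r)
      if (length(h)) paste(r, h) else character(0)
    }))
  translate_orf <- function(s, cds)
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(s, cds$start + 1L, cds$end))))
  out <- list()
  for (off in 0:5) {
    pos <- site_pos + off
    ref <- substr(bases, pos + 1L, pos + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      nb <- bases
      substr(nb, pos + 1L, pos + 1L) <- alt
      if (substr(nb, site_pos + 1L, site_pos + 6L) == recognition) next
      if (length(setdiff(keys(nb), keys(bases))) > 0) next
      if (!is.null(cds) && translate_orf(nb, cds) != translate_orf(bases, cds)) next
      out[[length(out) + 1L]] <- data.frame(position = pos, ref_base = ref,
                                            alt_base = alt,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(position = integer(), ref_base = character(),
                  alt_base = character(), stringsAsFactors = FALSE)
}

# a random valid BglBrick part (rejection sampling against full-molecule
# validity, i.e. including boundary-spanning contexts)
random_part <- function(n = 60L) {
  repeat {
    s <- random_dna(n)
    p <- tryCatch(makePart(s), error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

# a random circular sequence guaranteed to contain at least one site of the
# given enzymes (planted at a random rotation)
random_circular_with_sites <- function(n, enzymes, n_plant = 2L) {
  recs <- getEnzymes(enzymes)$recognition
  s <- random_dna(n)
  for (i in seq_len(n_plant)) {
    pos <- sample.int(n - 6L, 1L)
    substr(s, pos, pos + 5L) <- sample(recs, 1L)
  }
  DnaSeq(s, "circular")
}
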