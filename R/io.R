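#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
NULL

#' Read and write DNA FASTA
#'
#' FASTA has no topology slot, so circular molecules carry a
#' \code{[circular]} token in the description line.
#'
#' @param path file path
#' @return \code{readDnaFasta}: named list of \linkS4class{DnaSeq}
#' @export
readDnaFasta <- function(path) {
  set <- readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    nm <- names(set)[i]
    topo <- if (grepl("[circular]", nm, fixed = TRUE)) "circular" else "linear"
    DnaSeq(as.character(set[[i]]), topology = topo)
  })
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' @rdname readDnaFasta
#' @param seqs named list of \linkS4class{DnaSeq} (or a single one)
#' @export
writeDnaFasta <- function(seqs, path) {
  if (is(seqs, "DnaSeq")) seqs <- list(seq = seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  labels <- vapply(seq_along(seqs), function(i) {
    paste0(names(seqs)[i],
           if (seqTopology(seqs[[i]]) == "circular") " [circular]" else "")
  }, "")
  set <- DNAStringSet(vapply(seqs, dnaBases, ""))
  names(set) <- labels
  writeXStringSet(set, path)
  invisible(path)
}

#' Write a GenBank flat file
#'
#' Minimal writer oriented at round-tripping the package's own records:
#' LOCUS line with the topology field, misc_feature entries for annotations
#' (converted from the internal 0-based half-open convention to GenBank
#' 1-based inclusive; features wrapping a circular origin use the
#' \code{join()} form), and the ORIGIN sequence block.
#'
#' @param seq \linkS4class{DnaSeq}
#' @param path output path
#' @param name LOCUS name
#' @export
writeGenBank <- function(seq, path, name = "record") {
  seq <- DnaSeq(seq, topology = seqTopology(DnaSeq(seq)))
  b <- dnaBases(seq)
  len <- nchar(b)
  lines <- sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN",
                   gsub("\\s", "_", name), len, seqTopology(seq))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  f <- seqFeatures(seq)
  if (nrow(f) > 0) {
    for (i in seq_len(nrow(f))) {
      wraps <- f$end[i] <= f$start[i]
      loc <- if (!wraps) sprintf("%d..%d", f$start[i] + 1L, f$end[i])
             else sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, len, f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines,
                 sprintf("     misc_feature    %s", loc),
                 sprintf("                     /label=\"%s\"", f$label[i]))
    }
  }
  lines <- c(lines, "ORIGIN")
  for (off in seq(1L, len, by = 60L)) {
    chunk <- substr(b, off, min(off + 59L, len))
    groups <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
    lines <- c(lines, sprintf("%9d %s", off, tolower(paste(groups, collapse = " "))))
  }
  lines <- c(lines, "//")
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname writeGenBank
#' @return \code{readGenBank}: a \linkS4class{DnaSeq}
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("not a GenBank record: no LOCUS line")
  topo <- if (grepl("circular", locus, ignore.case = TRUE)) "circular" else "linear"
  ostart <- grep("^ORIGIN", lines)[1]
  if (is.na(ostart)) stop("no ORIGIN block")
  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  bases <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feats <- .empty_features()
  fidx <- grep("^\\s{5}\\S", lines)
  fidx <- fidx[fidx < ostart]
  for (i in fidx) {
    loc <- sub("^\\s+\\S+\\s+", "", lines[i])
    strand <- "+"
    if (grepl("^complement\\(", loc)) {
      strand <- "-"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("^join\\(", loc)) {
      parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
      a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
      bnd <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
      start <- a[1] - 1L; end <- bnd[2]
    } else {
      ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
      start <- ab[1] - 1L; end <- ab[2]
    }
    label <- NA_character_
    if (i + 1L <= length(lines) && grepl("/label=", lines[i + 1L]))
      label <- sub(".*/label=\"([^\"]*)\".*", "\\1", lines[i + 1L])
    feats <- rbind(feats, data.frame(label = label, start = start,
                                     end = end %% max(nchar(bases), 1L),
                                     strand = strand, stringsAsFactors = FALSE))
  }
  # end == 0 after modulo means the feature runs to the sequence end
  if (nrow(feats) > 0)
    feats$end[feats$end == 0L] <- nchar(bases)
  DnaSeq(bases, topology = topo, features = feats)
}
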