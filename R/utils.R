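# run code with a local RNG state so generators are pure functions of
# (parameters, seed) and never disturb the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

.random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministically repair forbidden hexamers outside protected ranges;
# protect is a data.frame(start, end) of 0-based half-open ranges
.scrub_sites <- function(s, enzymes, protect = NULL, circular = FALSE) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  for (round in 1:50) {
    hits <- findSites(DnaSeq(s, if (circular) "circular" else "linear"), enzymes)
    if (!is.null(protect) && nrow(hits) > 0) {
      shielded <- vapply(hits$position, function(p)
        any(p >= protect$start & p + 6L <= protect$end), TRUE)
      hits <- hits[!shielded, , drop = FALSE]
    }
    if (nrow(hits) == 0) return(s)
    for (p in hits$position) {
      for (off in 0:5) {
        q <- (p + off) %% nchar(s)
        inside <- !is.null(protect) &&
          any(q >= protect$start & q < protect$end)
        if (!inside) {
          base <- substr(s, q + 1L, q + 1L)
          substr(s, q + 1L, q + 1L) <- rot[[base]]
          break
        }
      }
    }
  }
  stop("could not scrub forbidden sites")
}
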