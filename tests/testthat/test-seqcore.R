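test_that("DnaSeq canonicalizes and rejects bad alphabet with position", {
  s <- DnaSeq("acgtACGT", "circular")
  expect_equal(dnaBases(s), "ACGTACGT")
  expect_equal(seqTopology(s), "circular")
  err <- tryCatch(DnaSeq("ACGNXACGT"), error = function(e) conditionMessage(e))
  expect_match(err, "non-ACGT")
  expect_match(err, "position 4")
  expect_error(DnaSeq(""), "non-empty")
})

test_that("revComp is an involution, fixes palindromes, and matches a printed primer pair", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(10:200, 1))
    expect_identical(revComp(revComp(s)), s)
  }
  expect_identical(revComp("GAATTC"), "GAATTC")
  prim <- constructionPrimers()
  f1 <- prim$sequence[prim$name == "pSC101QC F1"]
  r1 <- prim$sequence[prim$name == "pSC101QC R1"]
  expect_identical(revComp(toupper(f1)), toupper(r1))
})

test_that("revComp on DnaSeq preserves topology and remaps features", {
  s <- DnaSeq("AAACGTTTTT", features = data.frame(label = "x", start = 3, end = 6,
                                                  strand = "+"))
  rc <- revComp(s)
  f <- seqFeatures(rc)
  expect_equal(f$start, 4L)   # length 10: [3,6) -> [4,7)
  expect_equal(f$end, 7L)
  expect_equal(f$strand, "-")
  expect_equal(substr(dnaBases(rc), 5, 7), revComp(substr(dnaBases(s), 4, 6)))
})

test_that("findSites reports printed-primer sites and empty scans", {
  rfp_f1 <- "aaaAGATCTtttaagaaggagatatacatATGgcgagtagcgaagacgttatc"
  hits <- findSites(DnaSeq(rfp_f1), "BglII")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 3L)
  expect_false(hits$wraps_origin)
  all8 <- enzymeTable()$name
  expect_equal(nrow(findSites(DnaSeq("AAAAAAAA"), all8)), 0L)
})

test_that("findSites on circular sequences matches the doubled-string oracle", {
  # a site spanning the index-0 junction is found exactly once
  circ <- DnaSeq(paste0("TCTAAGGGCCCAAATTTGGGAGA"), "circular")  # AGATCT wraps
  hits <- findSites(circ, "BglII")
  expect_equal(nrow(hits), 1L)
  expect_true(hits$wraps_origin)
  expect_equal(hits$position, 20L)
  set.seed(21)
  all8 <- enzymeTable()
  for (i in 1:40) {
    s <- random_circular_with_sites(120L, all8$name)
    for (j in seq_len(nrow(all8))) {
      got <- findSites(s, all8$name[j])$position
      want <- oracle_scan(dnaBases(s), all8$recognition[j], circular = TRUE)
      expect_equal(got, want)
    }
  }
})

test_that("digest fragment counts follow topology", {
  # circular with one AatII and one AvrII site -> 2 fragments
  circ <- DnaSeq(paste0("GACGTC", strrep("AT", 20), "CCTAGG", strrep("TC", 15)),
                 "circular")
  expect_length(digestSeq(circ, c("AatII", "AvrII")), 2L)
  lin <- DnaSeq(dnaBases(circ), "linear")
  expect_length(digestSeq(lin, c("AatII", "AvrII")), 3L)
  expect_error(digestSeq(DnaSeq("AAAA"), "BglII"), "no cut")
})

test_that("digest overhang chemistry matches the cut-offset oracle for all enzymes", {
  enz <- enzymeTable()
  for (i in seq_len(nrow(enz))) {
    s <- paste0("TTTTTTTTTT", enz$recognition[i], "AAAAAAAAAA")
    frags <- digestSeq(DnaSeq(s), enz$name[i])
    want <- oracle_overhang(s, 10L, enz$cut_top[i], enz$cut_bottom[i])
    expect_equal(frags[[1]]@right_end$kind, want$kind, info = enz$name[i])
    expect_equal(frags[[1]]@right_end$overhang, want$overhang, info = enz$name[i])
    expect_equal(frags[[2]]@left_end$overhang, want$overhang, info = enz$name[i])
  }
  # the documented facts implied by the cloning steps
  expect_equal(digestSeq(DnaSeq("TTAGATCTAA"), "BglII")[[1]]@right_end$overhang, "GATC")
  expect_equal(digestSeq(DnaSeq("TTGGATCCAA"), "BamHI")[[1]]@right_end$overhang, "GATC")
  expect_equal(digestSeq(DnaSeq("TTCCTAGGAA"), "AvrII")[[1]]@right_end$overhang, "CTAG")
  expect_equal(digestSeq(DnaSeq("TTACTAGTAA"), "SpeI")[[1]]@right_end$overhang, "CTAG")
  aat <- digestSeq(DnaSeq("TTGACGTCAA"), "AatII")[[1]]@right_end
  sac <- digestSeq(DnaSeq("TTGAGCTCAA"), "SacI")[[1]]@right_end
  expect_equal(aat, list(kind = "three_prime", overhang = "ACGT", enzyme = "AatII"))
  expect_equal(sac$overhang, "AGCT")
})

test_that("re-ligating a digest in order reconstructs the parent", {
  lin <- DnaSeq("TTAGATCTAAGGATCCTT")
  frags <- digestSeq(lin, c("BglII", "BamHI"))
  expect_length(frags, 3L)
  expect_identical(ligateAll(frags, circularize = FALSE)@bases, dnaBases(lin))
  circ <- random_circular_with_sites(150L, c("BglII", "AatII"))
  cfr <- digestSeq(circ, c("BglII", "AatII"))
  expect_true(circularEqual(ligateAll(cfr), circ))
})

test_that("cohesive-end compatibility follows overhang kind and sequence", {
  bgl <- digestSeq(DnaSeq("TTAGATCTAA"), "BglII")
  bam <- digestSeq(DnaSeq("GGGGATCCTT"), "BamHI")
  # BamHI-cut upstream end + BglII-cut downstream end -> GGATCT junction
  joined <- ligateFragments(bam[[1]], bgl[[2]])
  expect_match(joined@bases, "GGATCT", fixed = TRUE)
  expect_equal(nrow(findSites(DnaSeq(joined@bases), c("BglII", "BamHI"))), 0L)
  # AvrII + SpeI share CTAG; junction cut by neither
  avr <- digestSeq(DnaSeq("TTCCTAGGAA"), "AvrII")
  spe <- digestSeq(DnaSeq("GGACTAGTCC"), "SpeI")
  j2 <- ligateFragments(avr[[1]], spe[[2]])
  expect_match(j2@bases, "CCTAGT", fixed = TRUE)
  expect_equal(nrow(findSites(DnaSeq(j2@bases), c("AvrII", "SpeI"))), 0L)
  # AatII 3' ACGT vs SacI 3' AGCT -> structured incompatibility
  aat <- digestSeq(DnaSeq("TTGACGTCAA"), "AatII")
  sac <- digestSeq(DnaSeq("TTGAGCTCAA"), "SacI")
  chk <- ligationCheck(aat[[1]]@right_end, sac[[2]]@left_end)
  expect_false(chk$compatible)
  expect_match(chk$reason, "ACGT")
  expect_match(chk$reason, "AGCT")
  expect_error(ligateFragments(aat[[1]], sac[[2]]), "incompatible")
  # kind mismatch: 5' vs 3'
  expect_false(ligationCheck(bgl[[1]]@right_end, aat[[2]]@left_end)$compatible)
})

test_that("circularEqual accepts rotations and reverse complements only", {
  set.seed(5)
  s <- DnaSeq(random_dna(200), "circular")
  for (k in c(0, 1, 37, 199)) expect_true(circularEqual(s, rotateSeq(s, k)))
  expect_true(circularEqual(s, revComp(rotateSeq(s, 55))))
  b <- dnaBases(s)
  substr(b, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(b, 100, 100))[1]
  expect_false(circularEqual(s, DnaSeq(b, "circular")))
  expect_error(circularEqual(s, DnaSeq("ACGT", "linear")), "circular")
  # all-rotations brute-force oracle on random pairs
  for (i in 1:20) {
    a <- random_dna(200)
    rot <- sample(0:199, 1)
    b2 <- paste0(substr(a, rot + 1, 200), substr(a, 1, rot))
    expect_true(circularEqual(DnaSeq(a, "circular"), DnaSeq(b2, "circular")))
    c2 <- random_dna(200)
    brute <- any(vapply(0:199, function(k)
      paste0(substr(a, k + 1, 200), substr(a, 1, k)) == c2 ||
      paste0(substr(a, k + 1, 200), substr(a, 1, k)) == revComp(c2), TRUE))
    expect_equal(circularEqual(DnaSeq(a, "circular"), DnaSeq(c2, "circular")), brute)
  }
})

test_that("enzyme recognitions are their own reverse complements", {
  enz <- enzymeTable()
  expect_equal(nrow(enz), 8L)
  for (i in seq_len(nrow(enz)))
    expect_identical(revComp(enz$recognition[i]), enz$recognition[i])
  expect_true(all(enz$cut_top >= 0 & enz$cut_top <= 6))
  expect_equal(enz$overhang_len, abs(enz$cut_top - enz$cut_bottom))
})
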