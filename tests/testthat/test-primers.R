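test_that("primer objects split into tail and anneal", {
  p <- primer("agatcaGACGTCgacaccatcgaatggtgcaaaacc", tail = "agatcaGACGTC",
              name = "pTrc F1")
  expect_identical(p$tail, "AGATCAGACGTC")
  expect_identical(p$anneal, "GACACCATCGAATGGTGCAAAACC")
  expect_error(primer("ACGTACGT", tail = "TTT"), "prefix")
  expect_error(primer("ACGTACGTACGT"), "too short")
})

test_that("simulatePcr amplifies the declared span and appends tails", {
  template <- DnaSeq("ATGCCCGGGTTT")
  fwd <- primer("ATGCCCGGG", min_anneal = 9)
  rev <- primer(revComp("CCCGGGTTT"), min_anneal = 9)
  expect_identical(dnaBases(simulatePcr(template, fwd, rev)), "ATGCCCGGGTTT")
  # a tailed forward primer introduces an AatII site absent from the template
  fwd2 <- primer(paste0("agatcaGACGTC", "ATGCCCGGG"), tail = "agatcaGACGTC",
                 min_anneal = 9)
  prod <- simulatePcr(template, fwd2, rev)
  expect_true(startsWith(dnaBases(prod), "AGATCAGACGTC"))
  expect_equal(nrow(findSites(template, "AatII")), 0L)
  expect_equal(nrow(findSites(prod, "AatII")), 1L)
})

test_that("simulatePcr is strand-symmetric and enforces unique annealing", {
  set.seed(41)
  t_b <- random_dna(300)
  template <- DnaSeq(t_b)
  fwd <- primer(substr(t_b, 21, 40), min_anneal = 15)
  rev <- primer(revComp(substr(t_b, 241, 260)), min_anneal = 15)
  prod <- simulatePcr(template, fwd, rev)
  # mirrored design on the revcomp template gives the revcomp product
  mirror <- simulatePcr(revComp(template), rev, fwd)
  expect_identical(dnaBases(mirror), revComp(dnaBases(prod)))
  # non-unique annealing raises a specificity error listing loci
  t2 <- DnaSeq(paste0(substr(t_b, 21, 40), "TTTT", t_b))
  expect_error(simulatePcr(t2, fwd, rev), "2 loci")
  expect_error(simulatePcr(template, primer(random_dna(20)), rev), "0 loci")
})

test_that("simulatePcr spans the origin of circular templates", {
  set.seed(43)
  b <- random_dna(200)
  circ <- DnaSeq(b, "circular")
  fwd <- primer(substr(b, 151, 170), min_anneal = 15)
  rev <- primer(revComp(substr(b, 31, 50)), min_anneal = 15)
  prod <- simulatePcr(circ, fwd, rev)
  expect_identical(dnaBases(prod), paste0(substr(b, 151, 200), substr(b, 1, 50)))
})

test_that("designMutagenicPair reproduces the printed pSC101 pair from its wild-type context", {
  prim <- constructionPrimers()
  f1 <- toupper(prim$sequence[prim$name == "pSC101QC F1"])
  r1 <- toupper(prim$sequence[prim$name == "pSC101QC R1"])
  # wild-type local window: the capital A at 0-based 21 reverts to T
  wt <- f1; substr(wt, 22, 22) <- "T"
  template <- DnaSeq(paste0("GGGTTT", wt, "ACCGGT"))  # pad so arms fit
  pair <- designMutagenicPair(template, 6L + 21L, "A", arm_len = c(21L, 12L))
  expect_identical(pair$fwd$bases, f1)
  expect_identical(pair$rev$bases, r1)
  expect_identical(pair$rev$bases, revComp(pair$fwd$bases))
  # applying the pair equals applying the equivalent mutation plan
  mut <- simulateMutagenesis(template, pair)
  plan <- list(position = 6L + 21L, ref_base = "T", alt_base = "A")
  via_plan <- applyPlan(template, plan, enzymes = "BglII")
  expect_identical(dnaBases(mut), dnaBases(via_plan))
})

test_that("designMutagenicPair guards its arms", {
  expect_error(designMutagenicPair(DnaSeq(random_dna(100)), 3L, "A"),
               "too close")
  expect_error(designMutagenicPair(DnaSeq(random_dna(100)), 50L, "A",
                                   arm_len = 5L), "at least 10")
})

test_that("SOE fusion plans carry revcomp inner pairs and reduce to sequence algebra", {
  set.seed(47)
  segs <- list(random_dna(120), random_dna(90), random_dna(70))
  tails <- c(fwd = "AGATCAGACGTC", rev = "AGATCAACTAGT")
  plan <- designSoeFusion(segs, outer_tails = tails)
  prod <- simulateSoe(plan)
  expect_identical(dnaBases(prod),
                   paste0(tails[["fwd"]], paste(unlist(segs), collapse = ""),
                          revComp(tails[["rev"]])))
  expect_equal(length(prod), sum(lengths(lapply(segs, function(s)
    seq_len(nchar(s))))) + sum(nchar(tails)))
  for (ip in plan$inner_primers)
    expect_identical(ip$rev$bases, revComp(ip$fwd$bases))
  # consecutive step products share the junction overlap
  for (i in seq_len(length(plan$steps) - 1)) {
    a <- plan$steps[[i]]$product; b <- plan$steps[[i + 1]]$product
    ov <- substr(b, 1, 30)
    expect_identical(substr(a, nchar(a) - 29, nchar(a)), ov)
  }
})

test_that("a junction mutation lands once in the fused product", {
  set.seed(49)
  seg1 <- random_dna(100); seg2 <- random_dna(100)
  # mutate 3 bases before the junction (inside the overlap)
  plan <- designSoeFusion(list(seg1, seg2),
                          mutations = data.frame(position = 97L, alt = "A"))
  fused <- dnaBases(simulateSoe(plan))
  want <- paste0(seg1, seg2)
  substr(want, 98, 98) <- "A"
  expect_identical(fused, want)
  # the inner primers carry the mutation
  expect_match(plan$inner_primers[[1]]$fwd$bases,
               substr(want, 96, 100), fixed = TRUE)
  # a degenerate one-segment plan is plain amplification with tails
  p1 <- designSoeFusion(list(seg1), outer_tails = c(fwd = "TTTGG", rev = "CCAAA"))
  fwd <- primer(paste0("TTTGG", substr(seg1, 1, 20)), tail = "TTTGG")
  rev <- primer(paste0("CCAAA", revComp(substr(seg1, 81, 100))), tail = "CCAAA")
  expect_identical(dnaBases(simulateSoe(p1)),
                   dnaBases(simulatePcr(DnaSeq(seg1), fwd, rev)))
})

test_that("the printed pBBR1 copy-up primers are mutual revcomps with one capital difference", {
  prim <- constructionPrimers()
  f <- prim$sequence[prim$name == "pBBR1 mut F1"]
  r <- prim$sequence[prim$name == "pBBR1 mut R1"]
  expect_identical(revComp(toupper(f)), toupper(r))
  expect_equal(regexpr("[A-Z]", f), regexpr("[A-Z]", "gaccacgtaggccAacacggtgccgg"))
})

test_that("primerTm follows the documented formulas and symmetries", {
  expect_equal(primerTm("AAAATTTT"), 16)
  expect_equal(primerTm("GGGGCCCC"), 32)
  set.seed(53)
  for (i in 1:20) {
    s <- random_dna(sample(c(8:13, 14:30), 1))
    expect_equal(primerTm(s), primerTm(revComp(s)))
  }
  # monotone non-decreasing in GC count at fixed length
  for (len in c(10L, 20L)) {
    tms <- vapply(0:len, function(g)
      primerTm(paste0(strrep("G", g), strrep("A", len - g))), 0)
    expect_true(all(diff(tms) >= 0))
  }
  expect_error(primerTm("ACGTACG"), "too short")
})
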