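test_that("vector names format and parse per the nomenclature", {
  expect_identical(formatVectorName("E", 5, "a", "RFP"), "pBbE5a-RFP")
  expect_identical(formatVectorName("S", 2, "k", "RFP"), "pBbS2k-RFP")
  p <- parseVectorName("pBbA8a-CFP")
  expect_identical(p$origin, "p15A")
  expect_identical(p$promoter, "PBAD")
  expect_identical(p$marker, "ampicillin")
  b <- parseVectorName("pBbB3a-gfp")
  expect_identical(b$origin, "pBBR1")
  expect_identical(promoterCatalog()$inducer[b$promoter_code], "propionate")
  expect_error(parseVectorName("pXx9z-foo"), "malformed")
  expect_error(parseVectorName("pBbZ5a-x"), "unknown origin code")
  expect_error(formatVectorName("E", 9, "a", "x"), "unknown promoter")
})

test_that("set notation expands to one name per origin code", {
  p <- parseVectorName("pBb{A, E, or S}3a-rfp")
  expect_equal(nrow(p), 3L)
  expect_setequal(p$origin_code, c("A", "E", "S"))
  expect_true(all(p$promoter_code == 3L))
  expect_true(all(p$payload_label == "rfp"))
})

test_that("round trip: parse(format(x)) recovers the components", {
  set.seed(61)
  for (i in 1:15) {
    oc <- sample(originCatalog()$code, 1)
    pc <- sample(1:8, 1)
    mc <- sample(markerCatalog()$code, 1)
    nm <- formatVectorName(oc, pc, mc, "rfp")
    p <- parseVectorName(nm)
    expect_identical(p$origin_code, oc)
    expect_equal(p$promoter_code, pc)
    expect_identical(p$marker_code, mc)
  }
})

test_that("catalogs have the documented cardinalities", {
  expect_equal(nrow(promoterCatalog()), 8L)
  expect_false(anyDuplicated(promoterCatalog()$code) > 0)
  expect_equal(nrow(originCatalog()), 4L)
  expect_equal(nrow(markerCatalog()), 3L)
  expect_length(bglBrickEnzymes(), 4L)
})

test_that("a single-combination library equals manual assembly of the three modules", {
  cat <- defaultModuleCatalog()
  lib <- buildLibrary(origins = "E", promoters = 5, markers = "a")
  expect_length(lib, 1L)
  expect_identical(names(lib), "pBbE5a-rfp")
  manual <- DnaSeq(paste0("GACGTC", expressionPayload(5, cat$genes$rfp),
                          "CCTAGG", cat$origins$E, "GAGCTC", cat$markers$a),
                   "circular")
  expect_true(circularEqual(vectorSequence(lib[[1]]), manual))
})

test_that("vectors satisfy the architecture invariants", {
  v <- buildVector("S", 2, "k", "rfp")
  seqv <- vectorSequence(v)
  for (enz in c("AatII", "AvrII", "SacI", "BglII", "BamHI"))
    expect_equal(nrow(findSites(seqv, enz)), 1L, info = enz)
  # traversal from AatII meets AvrII then SacI then wraps back to AatII
  aat <- findSites(seqv, "AatII")$position
  rot <- rotateSeq(seqv, aat)
  avr <- findSites(rot, "AvrII")$position
  sac <- findSites(rot, "SacI")$position
  expect_true(0 < avr && avr < sac)
  # the gene cassette sits between the BglII and BamHI sites
  bgl <- findSites(rot, "BglII")$position
  bam <- findSites(rot, "BamHI")$position
  expect_true(bgl > 0 && bgl < bam && bam < avr)
})

test_that("swapping a module for itself is the identity and cross-checks the build route", {
  cat <- defaultModuleCatalog()
  v <- buildVector("E", 5, "a", "rfp")
  same <- swapModule(v, "origin", cat$origins$E)
  expect_true(circularEqual(vectorSequence(same), vectorSequence(v)))
  # expression swap 5 -> 2 reproduces the built pBbE2a vector
  sw <- swapModule(v, "expression", expressionPayload(2, cat$genes$rfp),
                   new_code = 2)
  expect_identical(vectorName(sw), "pBbE2a-rfp")
  expect_true(circularEqual(vectorSequence(sw),
                            vectorSequence(buildVector("E", 2, "a", "rfp"))))
  # marker and origin swaps update the name
  sw2 <- swapModule(v, "marker", cat$markers$k, new_code = "k")
  expect_identical(vectorName(sw2), "pBbE5k-rfp")
})

test_that("any library vector is reachable from any other by at most 3 swaps", {
  cat <- defaultModuleCatalog()
  from <- buildVector("E", 5, "a", "rfp")
  to <- buildVector("S", 2, "k", "rfp")
  step1 <- swapModule(from, "expression", expressionPayload(2, cat$genes$rfp),
                      new_code = 2)
  step2 <- swapModule(step1, "origin", cat$origins$S, new_code = "S")
  step3 <- swapModule(step2, "marker", cat$markers$k, new_code = "k")
  expect_true(circularEqual(vectorSequence(step3), vectorSequence(to)))
  expect_identical(vectorName(step3), vectorName(to))
})

test_that("an AvrII/SpeI ligation destroys the junction site for the pBBR1-style install", {
  set.seed(67)
  # backbone opened at its unique AvrII site; insert carries AvrII and SpeI
  backbone <- DnaSeq(paste0("CCTAGG", dnaBases(genSequences(150, seed = 1,
                            enzymes = enzymeTable()$name)[[1]])), "circular")
  ins_core <- dnaBases(genSequences(100, seed = 2,
                                    enzymes = enzymeTable()$name)[[1]])
  insert <- DnaSeq(paste0("TTCCTAGG", ins_core, "ACTAGTAA"))
  bfrag <- digestSeq(backbone, "AvrII")[[1]]
  mid <- digestSeq(insert, c("AvrII", "SpeI"))[[2]]
  expect_identical(mid@left_end$enzyme, "AvrII")
  expect_identical(mid@right_end$enzyme, "SpeI")
  product <- ligateAll(list(bfrag, mid), circularize = TRUE)
  # AvrII restored at the AvrII/AvrII junction; AvrII/SpeI junction cut by neither
  expect_equal(nrow(findSites(product, "AvrII")), 1L)
  expect_equal(nrow(findSites(product, "SpeI")), 0L)
})

test_that("insertGene swaps the cassette, renames, and round-trips", {
  cat <- defaultModuleCatalog()
  v <- buildVector("E", 5, "a", "rfp")
  v_gfp <- insertGene(v, paste0(cat$rbs, cat$genes$gfp), "gfp")
  expect_identical(vectorName(v_gfp), "pBbE5a-gfp")
  expect_equal(nrow(findSites(vectorSequence(v_gfp), "BglII")), 1L)
  expect_equal(nrow(findSites(vectorSequence(v_gfp), "BamHI")), 1L)
  back <- insertGene(v_gfp, paste0(cat$rbs, cat$genes$rfp), "rfp")
  expect_true(circularEqual(vectorSequence(back), vectorSequence(v)))
  expect_error(insertGene(v, "AAAGAATTCAAA", "bad"), "forbidden")
})
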