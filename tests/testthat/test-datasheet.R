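make_toy_plate <- function(sf_by_conc, times = c(0, 30000, 64770, 73800),
                           od = 0.5) {
  rows <- list()
  i <- 0
  for (conc in names(sf_by_conc)) {
    for (r in 1:3) {
      i <- i + 1
      rows[[i]] <- data.frame(
        well = sprintf("W%02d", i), time_s = times, od600 = od,
        fluor = sf_by_conc[[conc]] * od, channel = "584/607",
        vector = "pBbE5a-RFP", strain = "BLR(DE3)", medium = "LB",
        inducer = "IPTG", conc = as.numeric(conc), conc_unit = "uM",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("specific fluorescence is the pointwise ratio with an OD floor mask", {
  plate <- data.frame(well = "A1", time_s = c(0, 570), od600 = c(0.02, 0.5),
                      fluor = c(50, 1000), channel = "584/607",
                      vector = "v", strain = "s", medium = "LB",
                      inducer = "IPTG", conc = 0, conc_unit = "uM")
  out <- specificFluorescence(plate)
  expect_true(is.na(out$sf[1]))     # below the 0.05 floor: masked, not divided
  expect_equal(out$sf[2], 2000)
  # scale invariance: doubling F and OD leaves SF unchanged
  plate2 <- plate; plate2$od600 <- plate2$od600 * 2; plate2$fluor <- plate2$fluor * 2
  expect_equal(specificFluorescence(plate2)$sf[2], out$sf[2])
  expect_warning(specificFluorescence(data.frame(plate[1, ], row.names = NULL)),
                 "OD floor")
})

test_that("doseResponse summarizes at the nearest timepoint and normalizes against controls", {
  plate <- make_toy_plate(list(`0` = 100, `10` = 400, `100` = 1600))
  ctrl <- make_toy_plate(list(`100` = 800))
  ctrl$well <- sub("W", "C", ctrl$well)
  dr <- doseResponse(rbind(plate, ctrl), control_wells = unique(ctrl$well))
  expect_equal(attr(dr, "summary_time_s"), 64770)  # nearest to 18 h among times
  expect_equal(dr$mean_sf, c(100, 400, 1600))
  expect_equal(dr$sd_sf, c(0, 0, 0))
  expect_equal(dr$n, c(3L, 3L, 3L))
  expect_equal(dr$norm_sf, c(100, 400, 1600) / 800)
  # control wells normalized against themselves give 1.0
  expect_warning(doseResponse(plate, control_wells = character()),
                 "control normalization skipped")
  dr_self <- doseResponse(rbind(ctrl, ctrl2 <- {x <- ctrl; x$well <- sub("C", "D", x$well); x}),
                          control_wells = unique(ctrl$well))
  expect_equal(dr_self$norm_sf, 1)
  # monotone input stays monotone after normalization (positive scaling)
  expect_true(all(diff(dr$norm_sf) > 0))
})

test_that("fitHill recovers noiseless parameters and flags flat data", {
  doses <- c(0, 5, 10, 25, 50, 100, 250, 500)
  truth <- 120 + 2400 * ifelse(doses > 0, doses^2 / (50^2 + doses^2), 0)
  fit <- fitHill(doses, truth)
  expect_true(fit$converged)
  expect_equal(fit$K, 50, tolerance = 1e-3)
  expect_equal(fit$n, 2, tolerance = 1e-3)
  expect_equal(fit$basal, 120, tolerance = 1e-3)
  flat <- fitHill(doses, rep(500, length(doses)))
  expect_lt(abs(flat$span), 1)
  expect_error(fitHill(c(0, 1, 2), c(1, 2, 3)), "at least 4")
  expect_error(fitHill(c(1, 2, 3, 4), c(1, 2, 3, 4)), "including 0")
})

test_that("crosstalk and repression conventions match the reported phrasing", {
  expect_equal(crosstalkRatio(1.0, 1.0), 0)
  expect_equal(crosstalkRatio(1.0, 1.4), 40)   # "30-40% increase"
  expect_equal(repressionRatio(0.8, 1.0), -20) # "about 20% less"
  expect_equal(repressionRatio(1.0, 1.0), 0)
  expect_error(crosstalkRatio(0, 1), "undefined")
  # gain invariance: common positive rescaling leaves the ratios unchanged
  set.seed(71)
  for (i in 1:10) {
    a <- runif(1, 100, 5000); b <- runif(1, 100, 5000); g <- runif(1, 0.1, 50)
    expect_equal(crosstalkRatio(a, b), crosstalkRatio(g * a, g * b))
    expect_equal(repressionRatio(a, b), repressionRatio(g * a, g * b))
  }
})

test_that("standard curves reproduce the closed-form efficiency identities", {
  # perfect doubling: Ct falls by exactly 1 per 2-fold dilution
  q <- 4^-(0:6)
  ct_perfect <- 20 - log10(q) / log10(2)
  curve <- fitStandardCurve(q, ct_perfect)
  expect_equal(curve$slope, -log2(10), tolerance = 1e-12)
  expect_equal(curve$efficiency, 1, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1)
  # duplicate identical points at two dilutions: exact line through them
  curve2 <- fitStandardCurve(c(1, 1, 0.25, 0.25), c(20, 20, 22, 22))
  expect_equal(unname(curve2$intercept), 20)
  expect_equal(unname(curve2$slope), 2 / log10(0.25))
  # unit relabeling shifts only the intercept
  curve3 <- fitStandardCurve(q * 1e3, ct_perfect)
  expect_equal(curve3$slope, curve$slope)
  expect_equal(curve3$efficiency, curve$efficiency)
  expect_false(isTRUE(all.equal(curve3$intercept, curve$intercept)))
  expect_error(fitStandardCurve(q, rev(ct_perfect)), "inverted")
  expect_error(fitStandardCurve(c(1, 0.5), c(1, 2)), "at least 3")
})

test_that("copy number follows the dual-ratio arithmetic", {
  q <- 4^-(0:6)
  curve_n <- fitStandardCurve(q, 20 - log10(q) / log10(2))
  curve_s <- fitStandardCurve(q, 14 - log10(q) / log10(2))
  ref <- c(nptII = 25, rrs16S = 15)
  # reference vs itself is exactly 1
  r <- copyNumber(ref, ref, curve_n, curve_s)
  expect_identical(r$copy_number, 1)
  # equal 16S, nptII lower by log2(10)*1 cycles -> copy number 10
  smp <- c(nptII = 25 - log2(10), rrs16S = 15)
  r10 <- copyNumber(smp, ref, curve_n, curve_s)
  expect_equal(r10$copy_number, 10, tolerance = 1e-9)
  expect_warning(
    copyNumber(c(nptII = 35, rrs16S = 15), ref, curve_n, curve_s),
    "extrapolated")
})

test_that("datasheet rendering round-trips numbers exactly and marks missing panels", {
  dr <- data.frame(conc = c(0, 100), conc_unit = "uM",
                   mean_sf = c(101.25, 2048.5), sd_sf = c(3.5, 10.25),
                   n = c(3L, 3L), norm_sf = c(0.0494384765625, 1))
  sheet <- renderDatasheet("pBbE5a-RFP", dose_response = dr,
                           crosstalk = data.frame(noncognate_inducer = "aTc",
                                                  percent_change = 38.5),
                           copy_number = 58.75)
  path <- file.path(tempdir(), "sheet.json")
  writeDatasheetJson(sheet, path)
  back <- readDatasheetJson(path)
  expect_equal(back$dose_response$mean_sf, dr$mean_sf)
  expect_equal(back$dose_response$norm_sf, dr$norm_sf)
  expect_equal(back$copy_number, 58.75)
  expect_identical(back$vector$name, "pBbE5a-RFP")
  txt <- renderDatasheetText(sheet)
  expect_true(any(grepl("not measured", txt)))       # media panel absent
  expect_true(any(grepl("58.8 plasmids", txt)))
  empty <- renderDatasheet("pBbE5a-RFP")
  txt2 <- renderDatasheetText(empty)
  expect_true(sum(grepl("not measured", txt2)) >= 4)
})

test_that("CSV schemas are validated on read", {
  p <- file.path(tempdir(), "bad_plate.csv")
  utils::write.csv(data.frame(well = "A1", time_s = 0), p, row.names = FALSE)
  expect_error(readPlateCsv(p), "missing column")
  q <- file.path(tempdir(), "bad_qpcr.csv")
  utils::write.csv(data.frame(sample = "s", target = "nptII", replicate = 1,
                              ct = 20, role = "oops", dilution = 1),
                   q, row.names = FALSE)
  expect_error(readQpcrCsv(q), "role")
})
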