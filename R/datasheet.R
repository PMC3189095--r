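#' @importFrom stats lm coef sd setNames
#' @importFrom minpack.lm nlsLM
NULL

.plate_cols <- c("well", "time_s", "od600", "fluor", "channel", "vector",
                 "strain", "medium", "inducer", "conc", "conc_unit")
.qpcr_cols <- c("sample", "target", "replicate", "ct", "role", "dilution")

#' Read characterization CSV inputs
#'
#' Plate schema: well, time_s, od600, fluor, channel, vector, strain, medium,
#' inducer, conc, conc_unit. qPCR schema: sample, target, replicate, ct, role
#' (unknown / standard / reference), dilution.
#'
#' @param path CSV path
#' @return data.frame with the validated schema
#' @export
readPlateCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.plate_cols, names(df))
  if (length(miss)) stop("plate CSV missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname readPlateCsv
#' @export
readQpcrCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.qpcr_cols, names(df))
  if (length(miss)) stop("qPCR CSV missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$role %in% c("unknown", "standard", "reference")))
    stop("qPCR role must be unknown, standard or reference")
  df
}

#' Specific fluorescence (fluorescence per OD600)
#'
#' Pointwise ratio of (optionally blank-subtracted) fluorescence to OD600.
#' Wells below the OD floor are masked (NA), not divided, to avoid ratio
#' blow-up at low biomass.
#'
#' @param plate plate data.frame (see \code{\link{readPlateCsv}})
#' @param od_floor minimum OD600 for a usable timepoint (default 0.05)
#' @param blank optional list \code{list(od600 = , fluor = )} of medium-blank
#'   values subtracted before the ratio
#' @return the plate data.frame with an added \code{sf} column
#' @export
specificFluorescence <- function(plate, od_floor = 0.05, blank = NULL) {
  od <- plate$od600
  fl <- plate$fluor
  if (!is.null(blank)) {
    od <- od - (blank$od600 %||% 0)
    fl <- fl - (blank$fluor %||% 0)
  }
  sf <- ifelse(od > od_floor, fl / od, NA_real_)
  if (all(is.na(sf)))
    warning("all timepoints below the OD floor; specific fluorescence is empty")
  plate$sf <- sf
  plate
}

# rows at the measured timepoint nearest target_s (no interpolation)
.nearest_time <- function(plate, target_s) {
  times <- sort(unique(plate$time_s))
  t0 <- times[which.min(abs(times - target_s))]
  plate[plate$time_s == t0, , drop = FALSE]
}

#' Dose-response summary at a single timepoint
#'
#' Mean and sd of specific fluorescence per inducer concentration at the
#' measured timepoint nearest \code{summary_time_s} (cadence 570 s keeps the
#' offset under 285 s; no interpolation). When control wells are given, a
#' control-normalized value (mean SF over mean control SF) is added;
#' otherwise normalization is skipped with a warning and absolute values are
#' still reported.
#'
#' @param plate plate data.frame (an \code{sf} column is computed if absent)
#' @param summary_time_s summary timepoint in seconds post induction
#'   (default 18 h)
#' @param control_wells character vector of control well ids (may be empty)
#' @param od_floor passed to \code{\link{specificFluorescence}}
#' @return data.frame with columns \code{conc}, \code{conc_unit},
#'   \code{mean_sf}, \code{sd_sf}, \code{n}, \code{norm_sf}
#' @export
doseResponse <- function(plate, summary_time_s = 18 * 3600,
                         control_wells = character(), od_floor = 0.05) {
  if (is.null(plate$sf)) plate <- specificFluorescence(plate, od_floor = od_floor)
  at <- .nearest_time(plate, summary_time_s)
  ctrl <- at[at$well %in% control_wells, , drop = FALSE]
  meas <- at[!at$well %in% control_wells, , drop = FALSE]
  if (nrow(meas) == 0) stop("no measurement wells at the summary timepoint")
  agg <- do.call(rbind, lapply(split(meas, meas$conc), function(g)
    data.frame(conc = g$conc[1], conc_unit = g$conc_unit[1],
               mean_sf = mean(g$sf, na.rm = TRUE),
               sd_sf = sd(g$sf, na.rm = TRUE), n = sum(!is.na(g$sf)),
               stringsAsFactors = FALSE)))
  agg <- agg[order(agg$conc), , drop = FALSE]
  if (nrow(ctrl) == 0) {
    warning("no control wells present; control normalization skipped")
    agg$norm_sf <- NA_real_
  } else {
    agg$norm_sf <- agg$mean_sf / mean(ctrl$sf, na.rm = TRUE)
  }
  rownames(agg) <- NULL
  attr(agg, "summary_time_s") <- unique(at$time_s)[1]
  agg
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of \code{SF(c) = basal + span c^n / (K^n + c^n)} with
#' deterministic initialization (basal = min, span = max - min, K = geometric
#' mean of the nonzero doses, n = 1). Non-convergence is reported in the
#' diagnostics rather than raised.
#'
#' @param doses inducer concentrations (>= 4 distinct values including 0)
#' @param sf specific fluorescence at each dose
#' @return list of class \code{"HillFit"}: \code{basal}, \code{span},
#'   \code{K}, \code{n}, \code{residual_norm}, \code{converged}
#' @export
fitHill <- function(doses, sf) {
  stopifnot(length(doses) == length(sf))
  if (length(unique(doses)) < 4L || !any(doses == 0))
    stop("need at least 4 distinct doses including 0")
  basal0 <- min(sf)
  span0 <- max(sf) - min(sf)
  k0 <- exp(mean(log(doses[doses > 0])))
  df <- data.frame(c = doses, y = sf)
  fit <- tryCatch(
    nlsLM(y ~ basal + span * ifelse(c > 0, c^n / (K^n + c^n), 0), data = df,
          start = list(basal = basal0, span = max(span0, 1e-9), K = k0, n = 1),
          lower = c(-Inf, 0, 1e-12, 0.05),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(basal = basal0, span = span0, K = k0, n = 1,
                          residual_norm = NA_real_, converged = FALSE),
                     class = "HillFit"))
  }
  cf <- coef(fit)
  structure(list(basal = unname(cf["basal"]), span = unname(cf["span"]),
                 K = unname(cf["K"]), n = unname(cf["n"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 converged = TRUE),
            class = "HillFit")
}

#' @export
print.HillFit <- function(x, ...) {
  cat(sprintf("Hill fit: basal %.4g + span %.4g * c^%.3g / (K^%.3g + c^%.3g), K = %.4g%s\n",
              x$basal, x$span, x$n, x$n, x$n, x$K,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Inducer crosstalk percent change
#'
#' \code{100 (SF_both - SF_cognate) / SF_cognate}: the percent change in
#' expression when a non-cognate inducer is added on top of the cognate one.
#' Positive values are enhancement, negative repression (a 1.4-fold level
#' reads +40).
#'
#' @param sf_cognate specific fluorescence with the cognate inducer only
#' @param sf_both specific fluorescence with cognate plus non-cognate inducer
#' @return percent change (scalar)
#' @export
crosstalkRatio <- function(sf_cognate, sf_both) {
  if (sf_cognate <= 0) stop("undefined ratio: cognate-only specific fluorescence must be positive")
  100 * (sf_both - sf_cognate) / sf_cognate
}

#' Catabolite repression percent change
#'
#' \code{100 (SF_glucose - SF_no_glucose) / SF_no_glucose}; the glucose
#' condition sits in the numerator role so repression reads negative (a 0.8
#' ratio reads -20).
#'
#' @param sf_glucose specific fluorescence with 1\% glucose
#' @param sf_no_glucose specific fluorescence without added glucose
#' @return percent change (scalar)
#' @export
repressionRatio <- function(sf_glucose, sf_no_glucose) {
  if (sf_no_glucose <= 0) stop("undefined ratio: reference specific fluorescence must be positive")
  100 * (sf_glucose - sf_no_glucose) / sf_no_glucose
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 quantity over a dilution series
#' (>= 3 points). Amplification efficiency is \code{10^(-1/slope) - 1}; a
#' perfect doubling per cycle gives slope \code{-log2(10)} (about -3.3219)
#' and efficiency 1. Efficiency and slope are invariant under rescaling the
#' arbitrary quantity units (only the intercept shifts).
#'
#' @param q known relative quantities (strictly positive)
#' @param ct threshold cycles
#' @return list of class \code{"StandardCurve"}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{efficiency}, \code{ct_range}
#' @export
fitStandardCurve <- function(q, ct) {
  stopifnot(length(q) == length(ct))
  if (length(q) < 3L) stop("need at least 3 dilution points")
  if (any(q <= 0)) stop("quantities must be strictly positive")
  fit <- lm(ct ~ log10(q))
  m <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  if (is.na(m) || m >= 0)
    stop("positive standard-curve slope: dilution direction looks inverted")
  structure(list(slope = m, intercept = b,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 efficiency = 10^(-1 / m) - 1,
                 ct_range = range(ct)),
            class = "StandardCurve")
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("Standard curve: Ct = %.4f + %.4f log10(Q), R2 = %.4f, efficiency = %.3f\n",
              x$intercept, x$slope, x$r_squared, x$efficiency))
  invisible(x)
}

#' Quantity read off a standard curve
#'
#' @param curve a \code{"StandardCurve"}
#' @param ct observed threshold cycle(s)
#' @return relative quantity in the curve's units
#' @export
quantityFromCt <- function(curve, ct) 10^((ct - curve$intercept) / curve$slope)

#' Plasmid copy number per chromosomal equivalent
#'
#' Quantities for the plasmid-borne single-copy nptII target and the
#' chromosomal multi-copy 16S rDNA normalizer are read off their fitted
#' standard curves for both the sample and a reference strain carrying a
#' single chromosomally integrated nptII; the copy number is
#' \code{(Q_nptII / Q_16S)_sample / (Q_nptII / Q_16S)_reference}, so the
#' reference strain maps to exactly 1.
#'
#' @param sample_ct named list/vector with \code{nptII} and \code{rrs16S}
#'   Cts for the sample
#' @param reference_ct same for the reference strain
#' @param curve_nptII,curve_16S fitted \code{"StandardCurve"} objects
#' @return list of class \code{"CopyNumberResult"}: \code{copy_number},
#'   component quantities, and \code{extrapolated} (TRUE when any Ct fell
#'   outside its curve's calibrated range)
#' @export
copyNumber <- function(sample_ct, reference_ct, curve_nptII, curve_16S) {
  need <- c("nptII", "rrs16S")
  for (x in list(sample_ct, reference_ct))
    if (!all(need %in% names(x))) stop("Cts must be named nptII and rrs16S")
  outside <- function(curve, ct) ct < curve$ct_range[1] || ct > curve$ct_range[2]
  extrapolated <- outside(curve_nptII, sample_ct[["nptII"]]) ||
    outside(curve_nptII, reference_ct[["nptII"]]) ||
    outside(curve_16S, sample_ct[["rrs16S"]]) ||
    outside(curve_16S, reference_ct[["rrs16S"]])
  q <- list(
    sample_nptII = quantityFromCt(curve_nptII, sample_ct[["nptII"]]),
    sample_16S = quantityFromCt(curve_16S, sample_ct[["rrs16S"]]),
    reference_nptII = quantityFromCt(curve_nptII, reference_ct[["nptII"]]),
    reference_16S = quantityFromCt(curve_16S, reference_ct[["rrs16S"]]))
  cn <- (q$sample_nptII / q$sample_16S) / (q$reference_nptII / q$reference_16S)
  if (extrapolated)
    warning("a Ct lies outside the calibrated standard-curve range; quantity extrapolated")
  structure(c(list(copy_number = cn, extrapolated = extrapolated), q),
            class = "CopyNumberResult")
}

#' @export
print.CopyNumberResult <- function(x, ...) {
  cat(sprintf("Plasmid copy number: %.2f per chromosomal equivalent%s\n",
              x$copy_number, if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}

#' qPCR copy-number pipeline from a table
#'
#' Fits per-target standard curves from the \code{standard} rows of a qPCR
#' table, averages replicate Cts of the \code{unknown} and \code{reference}
#' rows, and computes the copy number of each unknown sample.
#'
#' @param qpcr qPCR data.frame (see \code{\link{readQpcrCsv}})
#' @param reference_sample optional name restricting which reference rows
#'   are used (default: all reference rows)
#' @return list with \code{curves} (per target) and \code{copy_numbers}
#'   (data.frame sample, copy_number, extrapolated)
#' @export
copyNumberFromTable <- function(qpcr, reference_sample = NULL) {
  std <- qpcr[qpcr$role == "standard", , drop = FALSE]
  if (nrow(std) == 0) stop("no standard rows in qPCR table")
  curves <- lapply(split(std, std$target), function(g)
    fitStandardCurve(g$dilution, g$ct))
  if (!all(c("nptII", "rrs16S") %in% names(curves)))
    stop("standards must cover targets nptII and rrs16S")
  mean_ct <- function(df) {
    agg <- tapply(df$ct, df$target, mean)
    setNames(as.numeric(agg), names(agg))
  }
  refs <- qpcr[qpcr$role == "reference", , drop = FALSE]
  if (nrow(refs) == 0) stop("no reference rows in qPCR table")
  if (!is.null(reference_sample))
    refs <- refs[refs$sample == reference_sample, , drop = FALSE]
  ref_ct <- mean_ct(refs)
  unk <- qpcr[qpcr$role == "unknown", , drop = FALSE]
  res <- do.call(rbind, lapply(split(unk, unk$sample), function(g) {
    r <- copyNumber(mean_ct(g), ref_ct, curves$nptII, curves$rrs16S)
    data.frame(sample = g$sample[1], copy_number = r$copy_number,
               extrapolated = r$extrapolated, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  list(curves = curves, copy_numbers = res)
}

#' Assemble a datasheet report
#'
#' Collects the computed panels (dose response, strain/medium summary,
#' crosstalk, catabolite repression, copy number) for one vector into a
#' machine-readable structure; \code{writeDatasheetJson} serializes it and
#' \code{renderDatasheetText} prints the panel layout, with missing panels
#' rendered as "not measured".
#'
#' @param vector_name pBb vector name
#' @param dose_response data.frame from \code{\link{doseResponse}}
#' @param media_panel optional data.frame (strain, medium, mean_sf)
#' @param crosstalk optional data.frame (noncognate_inducer, percent_change)
#' @param repression optional data.frame (medium, percent_change)
#' @param copy_number optional scalar or \code{"CopyNumberResult"}
#' @return list of class \code{"Datasheet"}
#' @export
renderDatasheet <- function(vector_name, dose_response = NULL,
                            media_panel = NULL, crosstalk = NULL,
                            repression = NULL, copy_number = NULL) {
  meta <- tryCatch(as.list(parseVectorName(vector_name)),
                   error = function(e) list(name = vector_name))
  if (inherits(copy_number, "CopyNumberResult"))
    copy_number <- copy_number$copy_number
  structure(list(schema_version = "1.0", vector = meta,
                 dose_response = dose_response, media_panel = media_panel,
                 crosstalk = crosstalk, repression = repression,
                 copy_number = copy_number),
            class = "Datasheet")
}

#' @rdname renderDatasheet
#' @param sheet a \code{"Datasheet"}
#' @param path output path
#' @export
writeDatasheetJson <- function(sheet, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(unclass(sheet), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname renderDatasheet
#' @export
readDatasheetJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "Datasheet")
}

#' @rdname renderDatasheet
#' @export
renderDatasheetText <- function(sheet) {
  out <- c(sprintf("== Datasheet: %s ==", sheet$vector$name %||% "unnamed"))
  panel <- function(title, df, fmt) {
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0))
      return(c(title, "  not measured"))
    c(title, fmt(df))
  }
  out <- c(out,
    panel("-- Dose response (18 h) --", sheet$dose_response, function(d)
      sprintf("  %g %s: SF %.1f +/- %.1f (n=%d)%s", d$conc, d$conc_unit,
              d$mean_sf, d$sd_sf, d$n,
              ifelse(is.na(d$norm_sf), "", sprintf(", %.2fx control", d$norm_sf)))),
    panel("-- Strain / medium --", sheet$media_panel, function(d)
      sprintf("  %s in %s: SF %.1f", d$strain, d$medium, d$mean_sf)),
    panel("-- Inducer crosstalk --", sheet$crosstalk, function(d)
      sprintf("  + %s: %+.1f%%", d$noncognate_inducer, d$percent_change)),
    panel("-- Catabolite repression (1% glucose) --", sheet$repression, function(d)
      sprintf("  %s: %+.1f%%", d$medium, d$percent_change)))
  out <- c(out, "-- Copy number --",
           if (is.null(sheet$copy_number)) "  not measured"
           else sprintf("  %.1f plasmids per chromosomal equivalent", sheet$copy_number))
  out
}

#' @export
print.Datasheet <- function(x, ...) {
  writeLines(renderDatasheetText(x))
  invisible(x)
}
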