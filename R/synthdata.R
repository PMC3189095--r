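#' @importFrom stats rnorm
NULL

#' Logistic growth model
#'
#' \code{OD(t) = K / (1 + ((K - OD0)/OD0) exp(-r t))}; monotone increasing
#' for positive parameters. Defaults emulate a microplate culture induced at
#' low density and saturating below OD 1.
#'
#' @param od0 OD600 at induction (t = 0)
#' @param k_cap carrying capacity (OD600)
#' @param r growth rate per second
#' @return list of class \code{"GrowthModel"}
#' @export
growthModel <- function(od0 = 0.1, k_cap = 0.9, r = 1.6e-4) {
  stopifnot(od0 > 0, k_cap > od0, r > 0)
  structure(list(od0 = od0, k_cap = k_cap, r = r), class = "GrowthModel")
}

#' @rdname growthModel
#' @param model a \code{"GrowthModel"}
#' @param t time in seconds since induction
#' @export
odAt <- function(model, t) {
  with(model, k_cap / (1 + ((k_cap - od0) / od0) * exp(-r * t)))
}

#' Promoter expression model
#'
#' Hill dose response plus multiplicative modifiers: per-non-cognate-inducer
#' crosstalk coefficients (fractional change, e.g. +0.4 for a 40 percent
#' enhancement), a glucose catabolite-repression factor (e.g. 0.8 for 20
#' percent less output in 1 percent glucose), and log-normal multiplicative
#' noise on fluorescence.
#'
#' @param basal specific fluorescence at zero inducer (a.u./OD)
#' @param span inducible span above basal (a.u./OD)
#' @param K half-maximal inducer concentration (declared units)
#' @param n Hill coefficient
#' @param crosstalk named numeric of fractional changes per non-cognate
#'   inducer
#' @param glucose_factor multiplicative factor under 1 percent glucose
#' @param noise_sd sd of Gaussian noise on the log of fluorescence
#' @return list of class \code{"ExpressionModel"}
#' @export
expressionModel <- function(basal = 150, span = 3000, K = 50, n = 2,
                            crosstalk = c(), glucose_factor = 1,
                            noise_sd = 0.05) {
  stopifnot(basal >= 0, span >= 0, K > 0, n > 0)
  structure(list(basal = basal, span = span, K = K, n = n,
                 crosstalk = crosstalk, glucose_factor = glucose_factor,
                 noise_sd = noise_sd),
            class = "ExpressionModel")
}

#' @rdname expressionModel
#' @param model an \code{"ExpressionModel"}
#' @param conc cognate inducer concentration
#' @export
hillAt <- function(model, conc) {
  with(model, basal + span * ifelse(conc > 0, conc^n / (K^n + conc^n), 0))
}

# expression ramps to its plateau within ramp_s and holds there, so the
# plateau specific fluorescence equals the Hill value exactly in the
# noiseless limit
.sf_at <- function(model, conc, t, ramp_s = 6 * 3600) {
  hillAt(model, conc) * pmin(1, t / ramp_s)
}

#' Generate a plate-reader kinetic dataset
#'
#' Seeded generator for dose-response plates: triplicate wells per inducer
#' concentration plus three control wells (the reference vector at the
#' control concentration), read every \code{cadence_s} seconds for
#' \code{duration_s} seconds. Returns the data with its generating ground
#' truth as a sidecar list so tests never re-derive truth from the data.
#'
#' @param model \code{"ExpressionModel"} for the vector under test
#' @param doses inducer concentrations to test
#' @param seed integer seed (the generator is a pure function of its
#'   arguments and this seed)
#' @param vector_name,inducer,conc_unit well metadata
#' @param growth \code{"GrowthModel"}
#' @param replicates wells per dose (default 3)
#' @param cadence_s measurement interval (default 570)
#' @param duration_s total runtime (default 73800, i.e. 20.5 h)
#' @param control list describing the control wells (vector, conc, n,
#'   model); default three wells of pBbE5a-RFP at 100 uM IPTG
#' @param condition_factor multiplicative expression modifier applied to the
#'   measurement wells (not the controls), e.g. \code{1 + crosstalk
#'   coefficient} for a non-cognate inducer condition or the glucose
#'   repression factor for a catabolite-repression condition
#' @param channel excitation/emission label
#' @return list with \code{plate} (data.frame in the plate CSV schema) and
#'   \code{truth} (generating parameters)
#' @export
genPlate <- function(model, doses, seed,
                     vector_name = "pBbA5a-RFP", inducer = "IPTG",
                     conc_unit = "uM", growth = growthModel(),
                     replicates = 3L, cadence_s = 570L, duration_s = 73800L,
                     control = list(vector = "pBbE5a-RFP", conc = 100,
                                    n = 3L, model = NULL),
                     condition_factor = 1,
                     channel = "584/607") {
  times <- seq(0L, duration_s, by = cadence_s)
  ctrl_model <- control$model %||% model
  wells <- list()
  idx <- 0L
  add_well <- function(conc, vec, mdl, role) {
    idx <<- idx + 1L
    id <- sprintf("%s%02d", LETTERS[(idx - 1L) %/% 12L + 2L], (idx - 1L) %% 12L + 2L)
    list(well = id, conc = conc, vector = vec, model = mdl, role = role)
  }
  for (d in doses)
    for (r in seq_len(replicates))
      wells[[length(wells) + 1L]] <- add_well(d, vector_name, model, "measurement")
  for (r in seq_len(control$n %||% 3L))
    wells[[length(wells) + 1L]] <- add_well(control$conc, control$vector,
                                            ctrl_model, "control")
  plate <- .with_seed(seed, {
    do.call(rbind, lapply(wells, function(w) {
      od <- odAt(growth, times)
      sf <- .sf_at(w$model, w$conc, times) *
        if (w$role == "measurement") condition_factor else 1
      noise <- if (w$model$noise_sd > 0)
        exp(rnorm(length(times), 0, w$model$noise_sd)) else 1
      data.frame(well = w$well, time_s = times, od600 = od,
                 fluor = sf * od * noise, channel = channel,
                 vector = w$vector, strain = "BLR(DE3)", medium = "LB",
                 inducer = inducer, conc = w$conc, conc_unit = conc_unit,
                 stringsAsFactors = FALSE)
    }))
  })
  control_wells <- unique(vapply(wells, function(w)
    if (w$role == "control") w$well else NA_character_, ""))
  control_wells <- control_wells[!is.na(control_wells)]
  list(plate = plate,
       truth = list(model = model, growth = growth, doses = doses,
                    seed = seed, cadence_s = cadence_s,
                    duration_s = duration_s, control_wells = control_wells,
                    control_conc = control$conc,
                    condition_factor = condition_factor,
                    plateau_sf = setNames(
                      hillAt(model, doses) * condition_factor,
                      as.character(doses))))
}

#' qPCR amplification model
#'
#' \code{Ct = intercept - log10(Q) / log10(1 + E)} plus Gaussian Ct noise.
#'
#' @param efficiency amplification efficiency E in (0.8, 1]
#' @param intercept Ct at Q = 1
#' @param ct_sd Ct noise sd
#' @return list of class \code{"QpcrModel"}
#' @export
qpcrModel <- function(efficiency = 0.95, intercept = 18, ct_sd = 0.1) {
  stopifnot(efficiency > 0.8, efficiency <= 1, ct_sd >= 0)
  structure(list(efficiency = efficiency, intercept = intercept,
                 ct_sd = ct_sd), class = "QpcrModel")
}

.ct_at <- function(model, q) model$intercept - log10(q) / log10(1 + model$efficiency)

#' Generate a qPCR copy-number dataset
#'
#' Standards: a \code{dilution_factor}-fold series of \code{dilution_points}
#' dilutions of reference-strain total DNA, measured for both the nptII and
#' 16S targets in \code{replicates} replicates. Unknowns: a plasmid-bearing
#' sample whose nptII quantity reflects the planted copy number, plus the
#' single-integration reference strain (copy number 1 by construction).
#'
#' @param copy_number planted plasmids per chromosomal equivalent
#' @param seed integer seed
#' @param model_nptII,model_16S \code{"QpcrModel"} per target
#' @param dilution_points,dilution_factor standard-curve design (defaults 7
#'   and 4)
#' @param replicates replicate reactions per point (default 2)
#' @param s16_multiplicity 16S gene copies per chromosome (scale constant;
#'   absorbed by the standard curve)
#' @param sample_amount,reference_amount relative DNA input of the unknown
#'   and reference reactions (top standard = 1)
#' @return list with \code{qpcr} (data.frame in the qPCR CSV schema) and
#'   \code{truth}
#' @export
genQpcr <- function(copy_number, seed,
                    model_nptII = qpcrModel(0.95, 18, 0.1),
                    model_16S = qpcrModel(0.93, 12, 0.1),
                    dilution_points = 7L, dilution_factor = 4L,
                    replicates = 2L, s16_multiplicity = 7,
                    sample_amount = 0.01, reference_amount = 0.05) {
  dil <- dilution_factor^(-(seq_len(dilution_points) - 1L))
  models <- list(nptII = model_nptII, rrs16S = model_16S)
  # absolute per-reaction quantities; standards from reference-strain DNA
  qty <- function(target, chrom_amount, copies)
    if (target == "nptII") copies * chrom_amount
    else s16_multiplicity * chrom_amount
  rows <- list()
  emit <- function(sample, target, role, q_abs, dilution) {
    for (rep in seq_len(replicates))
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, target = target, replicate = rep,
        ct = .ct_at(models[[target]], q_abs), role = role,
        dilution = dilution, stringsAsFactors = FALSE)
  }
  for (target in names(models))
    for (d in dil)
      emit("standard_series", target, "standard", qty(target, d, 1), d)
  for (target in names(models)) {
    emit("plasmid_sample", target, "unknown",
         qty(target, sample_amount, copy_number), NA_real_)
    emit("reference_strain", target, "reference",
         qty(target, reference_amount, 1), NA_real_)
  }
  qpcr <- do.call(rbind, rows)
  qpcr <- .with_seed(seed, {
    sds <- vapply(qpcr$target, function(t) models[[t]]$ct_sd, 0)
    qpcr$ct <- qpcr$ct + rnorm(nrow(qpcr), 0, sds)
    qpcr
  })
  list(qpcr = qpcr,
       truth = list(copy_number = copy_number, seed = seed,
                    efficiency = c(nptII = model_nptII$efficiency,
                                   rrs16S = model_16S$efficiency),
                    expected_slope = c(
                      nptII = -1 / log10(1 + model_nptII$efficiency),
                      rrs16S = -1 / log10(1 + model_16S$efficiency))))
}

#' Generate random DNA sequences
#'
#' Uniform random ACGT with optional deterministic rejection of forbidden
#' recognition hexamers (used to build parts and module payloads that pass
#' validation by construction).
#'
#' @param lengths integer vector of sequence lengths
#' @param seed integer seed
#' @param site_free reject the forbidden hexamers (default TRUE)
#' @param enzymes enzyme set whose sites are rejected when \code{site_free}
#' @return named list of \linkS4class{DnaSeq} (linear)
#' @export
genSequences <- function(lengths, seed, site_free = TRUE,
                         enzymes = bglBrickEnzymes()) {
  stopifnot(all(lengths > 0))
  .with_seed(seed, {
    out <- lapply(seq_along(lengths), function(i) {
      s <- .random_bases(lengths[i])
      if (site_free && lengths[i] >= 6L) s <- .scrub_sites(s, enzymes)
      DnaSeq(s)
    })
    names(out) <- sprintf("synthetic_seq_%d", seq_along(lengths))
    out
  })
}
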