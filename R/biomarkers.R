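#' Dimensionless Buckingham-Pi biomarkers
#'
#' The six dimensionless groups built from the personalised model's scalar
#' quantities (all inputs in coherent SI units, so each term is
#' dimensionless by construction):
#' \deqn{\pi_1 = R_{ut}/R_{periph}, \quad \pi_2 = SV^2/A^3, \quad
#'       \pi_3 = CO \, R_{periph}/P_{syst},}
#' \deqn{\pi_4 = C_{syst} P_{syst}/A^{3/2}, \quad
#'       \pi_5 = R_{periph} A \, PWV / P_{syst}, \quad
#'       \pi_6 = \Delta P_{pulse}/P_{syst}.}
#'
#' @param inputs a `uf_biomarker_inputs` list (see
#'   [extract_biomarker_inputs()]) or any list with fields `R_ut`,
#'   `R_periph`, `SV`, `CO`, `C_syst`, `PWV`, `P_syst`, `dP_pulse`, `A` in
#'   SI units
#' @return named numeric vector `pi1` ... `pi6`
#' @export
#' @examples
#' x <- list(R_ut = 5e9, R_periph = 1.7e8, SV = 5e-5, CO = 7.7e-5,
#'           C_syst = 1e-8, PWV = 7.3, P_syst = 17851, dP_pulse = 5906,
#'           A = 7e-4)
#' pi_terms(x)
pi_terms <- function(inputs) {
  req <- c("R_ut", "R_periph", "SV", "CO", "C_syst", "PWV", "P_syst",
           "dP_pulse", "A")
  v <- unlist(inputs[req])
  if (length(v) != length(req) || any(!is.finite(v)))
    stop("pi_terms: missing or non-finite input")
  if (any(v <= 0)) stop("pi_terms: all inputs must be > 0")
  with(inputs, c(
    pi1 = R_ut / R_periph,
    pi2 = SV^2 / A^3,
    pi3 = CO * R_periph / P_syst,
    pi4 = C_syst * P_syst / A^(3 / 2),
    pi5 = R_periph * A * PWV / P_syst,
    pi6 = dP_pulse / P_syst
  ))
}

#' Pressure pulsatility index
#'
#' `PPI = (P_max - P_min)/P_mean` of a pressure waveform in a selected
#' utero-ovarian vessel; the pressure analogue of the Doppler pulsatility
#' index. `P_mean` is the time-average over one period.
#'
#' @param stats a [waveform_stats()] result (fields `P_max`, `P_min`,
#'   `P_mean`), or three numbers
#' @param P_min,P_mean optional when `stats` is given as `P_max`
#' @return PPI (dimensionless, >= 0)
#' @export
#' @examples
#' ppi(list(P_max = 100, P_min = 60, P_mean = 80))  # 0.5
ppi <- function(stats, P_min = NULL, P_mean = NULL) {
  if (is.list(stats)) {
    P_max <- stats$P_max; P_min <- stats$P_min; P_mean <- stats$P_mean
  } else P_max <- stats
  if (!(P_mean > 0)) stop("ppi: P_mean must be > 0")
  (P_max - P_min) / P_mean
}

#' Resistance index of a velocity waveform
#'
#' `RI = (V_max - V_min)/V_max`; in `[0, 1]` whenever `V_min >= 0`.
#'
#' @param stats a [waveform_stats()] result (fields `V_max`, `V_min`), or
#'   `V_max` as a number
#' @param V_min optional when `stats` is a number
#' @return RI
#' @export
#' @examples
#' ri(list(V_max = 60, V_min = 15))  # 0.75
ri <- function(stats, V_min = NULL) {
  if (is.list(stats)) { V_max <- stats$V_max; V_min <- stats$V_min }
  else V_max <- stats
  if (!(V_max > 0)) stop("ri: V_max must be > 0")
  (V_max - V_min) / V_max
}

#' Pulsatility index of a velocity waveform
#'
#' `PI = (V_max - V_min)/V_mean`, the standard Doppler pulsatility index
#' with `V_mean` the time-average over one period.
#'
#' @param stats a [waveform_stats()] result (fields `V_max`, `V_min`,
#'   `V_mean`), or `V_max` as a number
#' @param V_min,V_mean optional when `stats` is a number
#' @return PI
#' @export
#' @examples
#' pi_index(list(V_max = 60, V_min = 15, V_mean = 30))  # 1.5
pi_index <- function(stats, V_min = NULL, V_mean = NULL) {
  if (is.list(stats)) {
    V_max <- stats$V_max; V_min <- stats$V_min; V_mean <- stats$V_mean
  } else V_max <- stats
  if (!(V_mean > 0)) stop("pi_index: V_mean must be > 0")
  (V_max - V_min) / V_mean
}

#' Per-patient biomarker vector from a calibrated twin
#'
#' Computes the full candidate-classifier row for one patient: the six Pi
#' terms, PPI and RI at the arcuate and radial/spiral compartments of the
#' simulated cascade (analysis side), the Doppler-derived PI and RI of the
#' measured uterine waveform, and the clinical SBP/DBP.
#'
#' @param twin a `uf_twin` from [calibrate()]
#' @param record the patient record
#' @param side analysis side (default "right", with the left stored for
#'   symmetry checks)
#' @param allow_nonconverged passed to [extract_biomarker_inputs()]
#' @return a one-row data.frame with the 14 classifier columns
#' @export
biomarker_vector <- function(twin, record, side = "right",
                             allow_nonconverged = FALSE) {
  inputs <- extract_biomarker_inputs(twin, record, side = side,
                                     allow_nonconverged = allow_nonconverged)
  pis <- pi_terms(inputs)
  row <- as.data.frame(as.list(pis))
  for (s2 in c(side)) {
    arc <- waveform_stats(twin$result$sites[[paste0("arcuate_", s2)]])
    rad <- waveform_stats(twin$result$sites[[paste0("radial_", s2)]])
    row$PPI_arc <- ppi(arc)
    row$RI_arc <- ri(arc)
    row$PPI_rad <- ppi(rad)
    row$RI_rad <- ri(rad)
  }
  # Doppler-derived indices of the measured (template) uterine waveform
  S <- record[[paste0("S_", side, "_cm_per_s")]]
  D <- record[[paste0("D_", side, "_cm_per_s")]]
  w <- generate_uterine_waveform(S, D, record$HR_bpm)
  st <- waveform_stats(w$velocity_cm_per_s)
  row$PI <- pi_index(st)
  row$RI <- ri(st)
  row$SBP <- record$SBP_mmHg
  row$DBP <- record$DBP_mmHg
  row
}

#' Assemble the cohort feature table
#'
#' Calibrates (or accepts pre-calibrated) twins for every patient and stacks
#' the per-patient biomarker vectors into the classifier feature matrix.
#' Patients whose calibration did not converge are excluded and listed in
#' the `excluded` attribute (with a message).
#'
#' @param cohort a `uf_cohort` data frame
#' @param twins optional list of `uf_twin` objects matching the cohort rows;
#'   when `NULL` each patient is calibrated here
#' @param settings,max_iter,topology calibration controls (used when `twins`
#'   is `NULL`)
#' @param rel_tol per-target relative tolerance for calibration
#' @param side analysis side
#' @return a `uf_features` data.frame: `id`, `group`, then the 14 classifier
#'   columns; attribute `excluded` lists dropped patients
#' @export
feature_table <- function(cohort, twins = NULL,
                          settings = solver_settings(), max_iter = 12L,
                          topology = "full", rel_tol = 0.02,
                          side = "right") {
  validate_cohort(cohort)
  rows <- list(); excluded <- character()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    tw <- if (!is.null(twins)) twins[[i]] else
      suppressWarnings(calibrate(measurement_targets(rec, rel_tol = rel_tol),
                                 settings = settings, max_iter = max_iter,
                                 topology = topology))
    if (!tw$converged) {
      excluded <- c(excluded, rec$id)
      next
    }
    row <- biomarker_vector(tw, rec, side = side)
    rows[[length(rows) + 1]] <- cbind(data.frame(id = rec$id,
                                                 group = rec$group,
                                                 stringsAsFactors = FALSE),
                                      row)
  }
  if (length(excluded))
    message("feature_table: excluded non-converged patient(s): ",
            paste(excluded, collapse = ", "))
  if (!length(rows)) stop("feature_table: no patient converged")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("uf_features", "data.frame")
  out
}

#' Classifier column names of the feature table
#' @return character vector of the 14 feature columns
#' @export
feature_columns <- function() {
  c(paste0("pi", 1:6), "PPI_arc", "RI_arc", "PPI_rad", "RI_rad",
    "PI", "RI", "SBP", "DBP")
}
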