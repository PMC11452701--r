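#' Measurement targets for personalisation
#'
#' The non-invasive observables the calibration loop must reproduce:
#' brachial systolic/diastolic pressure, heart rate, cardiac output, pulse
#' wave velocity, and the uterine Doppler envelope (S, D) per side. The
#' uterine waveform template converts S/D into the two quantities the model
#' is matched against: cycle-mean velocity and resistance index.
#'
#' @param record one-row `uf_cohort` data frame (or a list with the same
#'   fields)
#' @param rel_tol relative tolerance per target (default 0.02)
#' @return a `uf_targets` list
#' @export
measurement_targets <- function(record, rel_tol = 0.02) {
  if (is.data.frame(record) && nrow(record) != 1)
    stop("measurement_targets: 'record' must be a single patient")
  r <- as.list(record)
  if (!(r$SBP_mmHg > r$DBP_mmHg)) stop("measurement_targets: SBP must exceed DBP")
  if (r$DBP_mmHg <= 0 || r$HR_bpm <= 0 || r$CO_L_per_min <= 0 ||
      r$PWV_m_per_s <= 0)
    stop("measurement_targets: all measurements must be positive")
  sides <- list()
  for (side in c("left", "right")) {
    S <- r[[paste0("S_", side, "_cm_per_s")]]
    D <- r[[paste0("D_", side, "_cm_per_s")]]
    if (S < D) stop("measurement_targets: S must be >= D (", side, ")")
    w <- generate_uterine_waveform(S, D, r$HR_bpm)
    sides[[side]] <- list(S = S, D = D,
                          U_mean_cm_s = mean(w$velocity_cm_per_s),
                          RI = if (S > 0) (S - D) / S else 0)
  }
  pp <- r$SBP_mmHg - r$DBP_mmHg
  structure(list(
    SBP_mmHg = r$SBP_mmHg, DBP_mmHg = r$DBP_mmHg,
    MAP_mmHg = r$DBP_mmHg + pp / 3, PP_mmHg = pp,
    HR_bpm = r$HR_bpm, CO_L_per_min = r$CO_L_per_min,
    PWV_m_per_s = r$PWV_m_per_s, uterine = sides, rel_tol = rel_tol
  ), class = "uf_targets")
}

#' Initial parameter guess for calibration
#'
#' Closed-form seeds for the fixed-point loop: total peripheral resistance
#' from `MAP/CO` (MAP by the one-third rule), total systemic compliance from
#' `SV/PP`, the stiffness multiplier from inverting the tube-law wave speed
#' at the measured PWV on the reference aortic area, and uterine resistance
#' from an assumed per-side uterine flow fraction of CO (default 3% at
#' mid-gestation).
#'
#' @param record one-row patient record
#' @param uterine_flow_fraction assumed fraction of CO per uterine side
#' @return list with `R_periph` (Pa s/m^3), `C_syst` (m^3/Pa), `k_beta`,
#'   `R_ut` (Pa s/m^3), plus the clinical-unit equivalents
#' @export
initial_guess <- function(record, uterine_flow_fraction = 0.03) {
  d <- derive_fields(record)
  if (!(d$pulse_pressure_mmHg > 0)) stop("initial_guess: non-physical record")
  CO <- lmin_to_m3s(record$CO_L_per_min)
  MAP <- mmhg_to_pa(d$MAP_mmHg)
  R_periph <- MAP / CO
  C_syst <- (d$SV_mL * 1e-6) / mmhg_to_pa(d$pulse_pressure_mmHg)
  # invert c = sqrt(k beta0 sqrt(A)/(2 rho)) at the reference ascending
  # aorta of the default network
  base <- build_default_network()
  asc <- base$segments[base$segments$name == "asc_aorta", ]
  A_ref <- 0.5 * (asc$A0_prox + asc$A0_dist)
  c0 <- wave_speed(asc$beta, A_ref, base$blood$rho)
  k_beta <- (record$PWV_m_per_s / c0)^2
  R_ut <- MAP / (uterine_flow_fraction * CO)
  list(R_periph = R_periph, C_syst = C_syst, k_beta = k_beta, R_ut = R_ut,
       R_periph_mmHg_s_mL = d$MAP_mmHg / (CO * 1e6),
       C_syst_mL_mmHg = (d$SV_mL) / d$pulse_pressure_mmHg)
}

# model observables extracted from a periodic solve
model_observables <- function(result, network) {
  root <- waveform_stats(result$sites$aortic_root)
  A_mean <- mean(result$sites$asc_aorta_mid$A)
  asc_beta <- network$segments$beta[network$segments$name == "asc_aorta"]
  obs <- list(
    SBP_mmHg = pa_to_mmhg(root$P_max), DBP_mmHg = pa_to_mmhg(root$P_min),
    MAP_mmHg = pa_to_mmhg(root$P_mean),
    PP_mmHg = pa_to_mmhg(root$P_max - root$P_min),
    A_m2 = A_mean,
    PWV_m_per_s = wave_speed(asc_beta, A_mean, network$blood$rho),
    uterine = list()
  )
  for (side in c("left", "right")) {
    st <- waveform_stats(result$sites[[paste0("uterine_inlet_", side)]])
    obs$uterine[[side]] <- list(U_mean_cm_s = 100 * st$V_mean,
                                RI = (st$V_max - st$V_min) / st$V_max)
  }
  obs
}

calib_residuals <- function(obs, targets) {
  res <- c(
    MAP = abs(obs$MAP_mmHg / targets$MAP_mmHg - 1),
    PP = abs(obs$PP_mmHg / targets$PP_mmHg - 1),
    PWV = abs(obs$PWV_m_per_s / targets$PWV_m_per_s - 1),
    U_left = abs(obs$uterine$left$U_mean_cm_s /
                   targets$uterine$left$U_mean_cm_s - 1),
    U_right = abs(obs$uterine$right$U_mean_cm_s /
                    targets$uterine$right$U_mean_cm_s - 1),
    RI_left = abs(obs$uterine$left$RI / targets$uterine$left$RI - 1),
    RI_right = abs(obs$uterine$right$RI / targets$uterine$right$RI - 1)
  )
  res
}

#' Calibrate the network model to one patient ("digital twin")
#'
#' Damped multiplicative fixed-point iteration: after each periodic solve the
#' total Windkessel resistance is scaled by `(MAP_target/MAP_model)`, the
#' lumped compliances by `(PP_model/PP_target)`, the global stiffness
#' multiplier by `(PWV_target/PWV_model)^2`, each side's utero-ovarian chain
#' resistance by `(U_model/U_target)` (cycle-mean uterine velocity) and its
#' distal-resistance fraction by `(RI_target/RI_model)` — each update raised
#' to a damping exponent (default 0.7) — until every relative residual (MAP,
#' PP, PWV, per-side uterine mean velocity and RI) is below `rel_tol` or
#' `max_iter` is reached. Non-convergence returns the best iterate, flagged.
#'
#' @param targets a [measurement_targets()] object (or a one-row cohort
#'   record, which is converted)
#' @param settings solver settings used for each periodic solve
#' @param max_iter maximum fixed-point iterations
#' @param damping damping exponent on each multiplicative update
#' @param uterine_flow_fraction passed to [initial_guess()]
#' @param topology network topology, see [build_default_network()]
#' @param verbose print per-iteration residuals
#' @return a `uf_twin`: calibrated parameters (`R_periph`, `C_syst`,
#'   `k_beta`, per-side `R_ut`), the calibrated `network`, final `result`,
#'   `A` (time-averaged ascending-aorta area), `PWV_model`, `converged`,
#'   `residuals` and the iteration `log`
#' @export
calibrate <- function(targets, settings = solver_settings(),
                      max_iter = 15L, damping = 0.7,
                      uterine_flow_fraction = 0.03,
                      topology = "full", verbose = FALSE) {
  if (inherits(targets, "uf_cohort") || is.data.frame(targets) ||
      (is.list(targets) && !inherits(targets, "uf_targets")))
    targets <- measurement_targets(targets)
  record_like <- list(SBP_mmHg = targets$SBP_mmHg, DBP_mmHg = targets$DBP_mmHg,
                      HR_bpm = targets$HR_bpm,
                      CO_L_per_min = targets$CO_L_per_min,
                      PWV_m_per_s = targets$PWV_m_per_s)
  g <- initial_guess(record_like, uterine_flow_fraction)
  inflow <- inflow_waveform(targets$CO_L_per_min, targets$HR_bpm)
  # seed the lumped states near the target MAP so large-compliance iterates
  # do not spend the whole run in a slow Windkessel transient
  settings$p_init_mmHg <- max(50, targets$DBP_mmHg - 5)
  settings$p_wk_init_mmHg <- targets$MAP_mmHg

  # state of the fixed-point loop
  R_total <- g$R_periph
  C_wk <- 0.8 * g$C_syst   # the 1D tree supplies the remaining compliance
  k_beta <- g$k_beta
  r_ut <- c(left = 1, right = 1)
  phi <- c(left = 0.65, right = 0.65)
  L_ut <- c(left = 0, right = 0)
  area_scale <- 1

  log <- list()
  best <- NULL
  log_maxres_prev <- Inf
  prev <- list(x = list(), y = list())
  for (iter in seq_len(max_iter)) {
    net <- build_default_network(R_total = R_total, C_wk = C_wk,
                                 k_beta = k_beta,
                                 uterine_flow_fraction = uterine_flow_fraction,
                                 r_ut_scale = r_ut,
                                 cascade_distal_fraction = phi,
                                 cascade_inertance = L_ut,
                                 area_scale = area_scale,
                                 topology = topology)
    result <- NULL
    set_try <- settings
    for (attempt in 1:3) {
      result <- tryCatch(
        withCallingHandlers(
          solve_network(net, inflow, set_try),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (!inherits(result, "error")) break
      # extreme intermediate parameter sets can break the CFL headroom of
      # the automatic time step; retry with a smaller one
      set_try$cfl <- set_try$cfl / 2
    }
    if (inherits(result, "error")) {
      if (is.null(best)) stop(result)
      warning("calibrate: solver failed at iteration ", iter,
              " (", conditionMessage(result), "); keeping best iterate")
      break
    }
    obs <- model_observables(result, net)
    res <- calib_residuals(obs, targets)
    log[[iter]] <- data.frame(iteration = iter, t(res),
                              R_total = R_total, C_wk = C_wk, k_beta = k_beta,
                              r_ut_left = r_ut[["left"]],
                              r_ut_right = r_ut[["right"]])
    if (verbose)
      message(sprintf("iter %d: max residual %.4f", iter, max(res)))
    if (is.null(best) || max(res) < best$maxres)
      best <- list(net = net, result = result, obs = obs, res = res,
                   maxres = max(res),
                   pars = list(R_total = R_total, C_wk = C_wk,
                               k_beta = k_beta, r_ut = r_ut, phi = phi,
                               L_ut = L_ut, area_scale = area_scale))
    if (max(res) <= targets$rel_tol) break
    # infeasible-target bailout: no meaningful progress and far from
    # tolerance after a reasonable number of iterations
    if (iter >= 7 && best$maxres > 5 * targets$rel_tol &&
        max(res) > 0.95 * log_maxres_prev) break
    log_maxres_prev <- max(res)
    # damped multiplicative updates; for the weak-leverage handles the local
    # log-log sensitivity |d log y / d log x| is estimated by secant and the
    # update exponent inverted (safeguarded to [1/8, 8] of nominal)
    secant_expo <- function(key, x_now, y_now, default_g) {
      g <- default_g
      if (!is.null(prev$x[[key]]) &&
          abs(log(x_now / prev$x[[key]])) > 1e-6) {
        gs <- abs(log(y_now / prev$y[[key]]) / log(x_now / prev$x[[key]]))
        if (is.finite(gs) && gs > 0.02) g <- gs
      }
      prev$x[[key]] <<- x_now
      prev$y[[key]] <<- y_now
      min(1 / g, 8) * damping
    }
    R_total <- R_total * (targets$MAP_mmHg / obs$MAP_mmHg)^0.9
    R_total <- min(5 * g$R_periph, max(0.2 * g$R_periph, R_total))
    g_pp <- NA_real_
    if (!is.null(prev$x$PP) && abs(log(C_wk / prev$x$PP)) > 1e-6)
      g_pp <- abs(log(obs$PP_mmHg / prev$y$PP) / log(C_wk / prev$x$PP))
    e_pp <- secant_expo("PP", C_wk, obs$PP_mmHg, 0.7)
    C_wk <- C_wk * (obs$PP_mmHg / targets$PP_mmHg)^e_pp
    C_wk <- min(1.2e-7, max(5e-10, C_wk))
    # compliance loses leverage once the terminals are anechoic and the root
    # pulse is the incident wave Z_c * Qmax; then the vessel-size scale takes
    # over (larger area -> lower characteristic impedance -> lower pulse)
    if ((is.finite(g_pp) && g_pp < 0.12) || C_wk >= 1.19e-7 ||
        C_wk <= 5.1e-10) {
      area_scale <- area_scale * (obs$PP_mmHg / targets$PP_mmHg)^(0.6 * damping)
      area_scale <- min(2.4, max(0.5, area_scale))
    }
    # d log PWV / d log k_beta = 1/2 exactly, so the inverse update is ^2
    k_beta <- min(8, max(0.3, k_beta *
      (targets$PWV_m_per_s / obs$PWV_m_per_s)^2))
    for (side in c("left", "right")) {
      e_u <- min(secant_expo(paste0("U_", side), r_ut[[side]],
                             obs$uterine[[side]]$U_mean_cm_s, 0.9), 1.5)
      r_ut[[side]] <- r_ut[[side]] *
        (obs$uterine[[side]]$U_mean_cm_s /
           targets$uterine[[side]]$U_mean_cm_s)^e_u
      r_ut[[side]] <- min(12, max(0.08, r_ut[[side]]))
      # RI handle: distal fraction phi, updated multiplicatively on the
      # odds phi/(1-phi) with a secant-estimated gain
      odds <- phi[[side]] / (1 - phi[[side]])
      e_ri <- min(secant_expo(paste0("RI_", side), odds,
                              obs$uterine[[side]]$RI, 0.3), 6)
      odds <- odds * (targets$uterine[[side]]$RI /
                        obs$uterine[[side]]$RI)^e_ri
      phi[[side]] <- min(0.97, max(0.08, odds / (1 + odds)))
      # below the resistive floor (phi at its lower clamp and RI still too
      # high) an entry inertance attenuates the pulsatile flow
      ri_ratio <- obs$uterine[[side]]$RI / targets$uterine[[side]]$RI
      if (phi[[side]] <= 0.1 && ri_ratio > 1) {
        if (L_ut[[side]] == 0) L_ut[[side]] <- 2e8
        else {
          e_l <- min(secant_expo(paste0("L_", side), L_ut[[side]],
                                 obs$uterine[[side]]$RI, 0.4), 4)
          L_ut[[side]] <- L_ut[[side]] * ri_ratio^e_l
        }
        L_ut[[side]] <- min(6e9, L_ut[[side]])
      } else if (L_ut[[side]] > 0 && phi[[side]] > 0.15) {
        L_ut[[side]] <- L_ut[[side]] * 0.3
        if (L_ut[[side]] < 1e7) L_ut[[side]] <- 0
      }
    }
  }
  net <- best$net; result <- best$result; obs <- best$obs
  converged <- best$maxres <= targets$rel_tol
  if (!converged)
    warning("calibrate: not converged (max residual ",
            signif(best$maxres, 3), " > ", targets$rel_tol, ")")
  CO <- lmin_to_m3s(targets$CO_L_per_min)
  # total compliance of the calibrated model: Windkessel + cascade + 1D
  s <- net$segments
  A_op <- 0.5 * (s$A0_prox + s$A0_dist)   # 1D compliance at reference area
  C_1d <- sum(2 * sqrt(A_op) / s$beta * s$length_m)
  C_lumped <- sum(s$C, na.rm = TRUE) +
    sum(vapply(net$cascades, function(cc) cc$C_arc + cc$C_rad, 0))
  structure(list(
    R_periph = mmhg_to_pa(obs$MAP_mmHg) / CO,
    C_syst = C_1d + C_lumped,
    k_beta = best$pars$k_beta,
    R_ut = vapply(net$cascades, function(cc) cc$R_ut + cc$R_arc + cc$R_rad, 0),
    A = obs$A_m2,
    PWV_model = obs$PWV_m_per_s,
    observables = obs, targets = targets,
    network = net, result = result,
    converged = converged, residuals = best$res,
    log = do.call(rbind, log), iterations = length(log)
  ), class = "uf_twin")
}

#' Assemble biomarker inputs from a calibrated twin
#'
#' Collects, in coherent SI units, the scalar quantities the dimensionless
#' biomarkers are built from: calibrated uterine resistance (analysis side),
#' total peripheral resistance, stroke volume, cardiac output, systemic
#' compliance, measured PWV, systolic pressure, pulse pressure and the
#' time-averaged ascending-aorta area.
#'
#' @param model a `uf_twin` from [calibrate()]
#' @param record the patient record the twin was calibrated to (for measured
#'   SBP/DBP/PWV/CO/HR)
#' @param side analysis side for `R_ut` (default "right")
#' @param allow_nonconverged proceed even if the twin did not converge
#' @return a `uf_biomarker_inputs` list
#' @export
extract_biomarker_inputs <- function(model, record, side = "right",
                                     allow_nonconverged = FALSE) {
  if (!inherits(model, "uf_twin")) stop("extract_biomarker_inputs: need a uf_twin")
  if (!model$converged && !allow_nonconverged)
    stop("extract_biomarker_inputs: twin did not converge; ",
         "set allow_nonconverged = TRUE to override")
  CO <- lmin_to_m3s(record$CO_L_per_min)
  SV <- CO * 60 / record$HR_bpm
  out <- list(
    R_ut = model$R_ut[[side]],
    R_periph = model$R_periph,
    SV = SV, CO = CO,
    C_syst = model$C_syst,
    PWV = record$PWV_m_per_s,
    P_syst = mmhg_to_pa(record$SBP_mmHg),
    dP_pulse = mmhg_to_pa(record$SBP_mmHg - record$DBP_mmHg),
    A = model$A
  )
  stopifnot(all(unlist(out) > 0), out$dP_pulse < out$P_syst)
  structure(out, class = "uf_biomarker_inputs")
}
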