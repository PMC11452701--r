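#' Truncated-normal parameter description
#'
#' One marginal sampling distribution of a cohort parameter: a normal with
#' mean `mean` and standard deviation `sd`, truncated to `(lower, upper)`.
#' Bounds default wide enough that truncation bias is negligible for the
#' built-in cohort but keep every draw physiological.
#'
#' @param mean distribution mean
#' @param sd standard deviation, `>= 0` (0 gives a constant)
#' @param lower,upper truncation bounds, `lower < upper`
#' @return a `uf_param` list
#' @export
cohort_param <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (!is.finite(mean)) stop("cohort_param: 'mean' must be finite")
  if (!is.finite(sd) || sd < 0) stop("cohort_param: 'sd' must be >= 0")
  if (!(lower < upper)) stop("cohort_param: bounds must satisfy lower < upper")
  structure(list(mean = mean, sd = sd, lower = lower, upper = upper),
            class = "uf_param")
}

# Inverse-CDF truncated-normal sampler: deterministic given the uniforms,
# which keeps Gaussian-copula coupling of left/right Doppler draws simple.
qtnorm <- function(u, p) {
  if (p$sd == 0) return(rep(p$mean, length(u)))
  pa <- stats::pnorm(p$lower, p$mean, p$sd)
  pb <- stats::pnorm(p$upper, p$mean, p$sd)
  stats::qnorm(pa + u * (pb - pa), p$mean, p$sd)
}

rtnorm <- function(n, p) qtnorm(stats::runif(n), p)

#' Cohort generator specification
#'
#' Describes the statistical structure of a two-group (NPE / PE) synthetic
#' cohort: group sizes and, per group, an independent truncated normal for
#' each measured parameter. The defaults reproduce the published group
#' means/SDs of the pilot cohort this package emulates (12 NPE, 9 PE).
#'
#' Uterine Doppler peak systolic velocity `S` is not part of the published
#' summary table; its default (65 +/- 15 cm/s) is a literature-typical
#' mid-gestation value. End-diastolic velocity is derived as
#' `D = S * (1 - RI)` so the resistance index of each record is exact by
#' construction. Left and right sides are coupled through a Gaussian copula
#' with correlation `lr_correlation`.
#'
#' @param n_npe,n_pe group sizes (non-negative integers)
#' @param npe,pe named lists of [cohort_param()] objects; entries override the
#'   group defaults. Required names: GA_weeks, parity, BMI, SBP_mmHg,
#'   DBP_mmHg, HR_bpm, CO_L_per_min, PWV_m_per_s, age_years, weight_kg, PI, RI.
#' @param s_peak [cohort_param()] for peak systolic uterine velocity (cm/s)
#' @param lr_correlation copula correlation between left and right Doppler
#'   draws (default 0.9)
#' @param bp_correlation copula correlation between the SBP and DBP draws
#'   (default 0.6, the clinically observed coupling; 0 gives independent
#'   marginals, which can produce pulse pressures no sphygmomanometer ever
#'   records)
#' @param effect_config list; `r_ut_multiplier` is a multiplicative shift on
#'   utero-ovarian resistance applied to PE records in forward simulations
#' @param seed integer seed stored with the spec; [generate_cohort()] uses it
#' @return a `uf_cohort_spec` object
#' @export
cohort_spec <- function(n_npe = 12L, n_pe = 9L,
                        npe = list(), pe = list(),
                        s_peak = cohort_param(65, 15, 20, 150),
                        lr_correlation = 0.9, bp_correlation = 0.6,
                        effect_config = list(r_ut_multiplier = 1.5),
                        seed = 1L) {
  defaults_npe <- list(
    GA_weeks     = cohort_param(23.3, 0.7, 16, 34),
    parity       = cohort_param(1.7, 1.4, 0, 8),
    BMI          = cohort_param(29.6, 7.3, 15, 60),
    SBP_mmHg     = cohort_param(133.9, 13, 80, 220),
    DBP_mmHg     = cohort_param(89.6, 8.2, 40, 140),
    HR_bpm       = cohort_param(91.6, 11.9, 40, 160),
    CO_L_per_min = cohort_param(4.6, 1.4, 1.5, 12),
    PWV_m_per_s  = cohort_param(7.3, 1.7, 3, 16),
    age_years    = cohort_param(32.2, 3.7, 16, 55),
    weight_kg    = cohort_param(79, 22.6, 40, 180),
    PI           = cohort_param(0.9, 0.2, 0.2, 3.5),
    RI           = cohort_param(0.5, 0.1, 0.28, 0.92)
  )
  defaults_pe <- list(
    GA_weeks     = cohort_param(25.2, 2, 16, 34),
    parity       = cohort_param(0.7, 0.9, 0, 8),
    BMI          = cohort_param(28.3, 3.2, 15, 60),
    SBP_mmHg     = cohort_param(140.9, 17.6, 80, 220),
    DBP_mmHg     = cohort_param(90.7, 12.2, 40, 140),
    HR_bpm       = cohort_param(81.9, 11.3, 40, 160),
    CO_L_per_min = cohort_param(6.1, 1.1, 1.5, 12),
    PWV_m_per_s  = cohort_param(8.9, 1.5, 3, 16),
    age_years    = cohort_param(34.1, 4.6, 16, 55),
    weight_kg    = cohort_param(75.8, 8.5, 40, 180),
    PI           = cohort_param(1.7, 0.7, 0.2, 3.5),
    RI           = cohort_param(0.7, 0.1, 0.28, 0.92)
  )
  check_group <- function(user, defaults, label) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop("cohort_spec: unknown parameter(s) in '", label, "': ",
           paste(bad, collapse = ", "))
    for (nm in names(user))
      if (!inherits(user[[nm]], "uf_param"))
        stop("cohort_spec: '", label, "$", nm, "' must be a cohort_param")
    utils::modifyList(defaults, user)
  }
  n_npe <- as.integer(n_npe); n_pe <- as.integer(n_pe)
  if (is.na(n_npe) || n_npe < 0) stop("cohort_spec: 'n_npe' must be >= 0")
  if (is.na(n_pe) || n_pe < 0) stop("cohort_spec: 'n_pe' must be >= 0")
  if (!is.numeric(lr_correlation) || lr_correlation < -1 || lr_correlation > 1)
    stop("cohort_spec: 'lr_correlation' must be in [-1, 1]")
  if (!inherits(s_peak, "uf_param")) stop("cohort_spec: 's_peak' must be a cohort_param")
  structure(list(
    n_npe = n_npe, n_pe = n_pe,
    npe = check_group(npe, defaults_npe, "npe"),
    pe = check_group(pe, defaults_pe, "pe"),
    s_peak = s_peak,
    lr_correlation = lr_correlation, bp_correlation = bp_correlation,
    effect_config = effect_config,
    seed = as.integer(seed)
  ), class = "uf_cohort_spec")
}

sample_group <- function(n, params, s_peak, rho, rho_bp, group, id0,
                         r_ut_mult) {
  if (n == 0L) return(NULL)
  draw <- function(nm) rtnorm(n, params[[nm]])
  draw_bp <- function(n) {
    z1 <- stats::rnorm(n)
    z2 <- rho_bp * z1 + sqrt(1 - rho_bp^2) * stats::rnorm(n)
    list(sbp = qtnorm(stats::pnorm(z1), params$SBP_mmHg),
         dbp = qtnorm(stats::pnorm(z2), params$DBP_mmHg))
  }
  bp <- draw_bp(n)
  rec <- data.frame(
    id = sprintf("%s%d", group, seq_len(n) + id0),
    group = rep(group, n),
    GA_weeks = draw("GA_weeks"),
    parity = round(draw("parity")),
    BMI = draw("BMI"),
    SBP_mmHg = bp$sbp,
    DBP_mmHg = bp$dbp,
    HR_bpm = draw("HR_bpm"),
    CO_L_per_min = draw("CO_L_per_min"),
    PWV_m_per_s = draw("PWV_m_per_s"),
    age_years = draw("age_years"),
    weight_kg = draw("weight_kg"),
    stringsAsFactors = FALSE
  )
  # enforce SBP > DBP by jointly resampling the offending pairs
  for (iter in 1:1000) {
    bad <- which(rec$SBP_mmHg <= rec$DBP_mmHg)
    if (!length(bad)) break
    bp <- draw_bp(length(bad))
    rec$SBP_mmHg[bad] <- bp$sbp
    rec$DBP_mmHg[bad] <- bp$dbp
  }
  if (any(rec$SBP_mmHg <= rec$DBP_mmHg))
    stop("generate_cohort: could not satisfy SBP > DBP after resampling")

  # right side is the analysis side; left coupled via a Gaussian copula
  z_ri_r <- stats::rnorm(n); z_ri_l <- rho * z_ri_r + sqrt(1 - rho^2) * stats::rnorm(n)
  z_s_r <- stats::rnorm(n);  z_s_l <- rho * z_s_r + sqrt(1 - rho^2) * stats::rnorm(n)
  ri_r <- qtnorm(stats::pnorm(z_ri_r), params$RI)
  ri_l <- qtnorm(stats::pnorm(z_ri_l), params$RI)
  s_r <- qtnorm(stats::pnorm(z_s_r), s_peak)
  s_l <- qtnorm(stats::pnorm(z_s_l), s_peak)
  rec$S_left_cm_per_s <- s_l
  rec$D_left_cm_per_s <- s_l * (1 - ri_l)
  rec$S_right_cm_per_s <- s_r
  rec$D_right_cm_per_s <- s_r * (1 - ri_r)
  rec$PI <- draw("PI")
  rec$RI <- ri_r
  rec$r_ut_mult <- rep(r_ut_mult, n)
  rec
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_npe + n_pe` patient records from the per-group truncated-normal
#' marginals of a [cohort_spec()]. Sampling is fully reproducible for a fixed
#' `spec$seed`. Each record satisfies `SBP > DBP` (offending pairs are
#' resampled), `S >= D >= 0` on both sides, and `RI == (S - D)/S` on the
#' right (analysis) side by construction.
#'
#' @param spec a [cohort_spec()]
#' @return a `data.frame` of patient records (class `uf_cohort`), one row per
#'   patient
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 42))
#' table(coh$group)
generate_cohort <- function(spec) {
  if (!inherits(spec, "uf_cohort_spec")) stop("generate_cohort: 'spec' must be a uf_cohort_spec")
  mult <- spec$effect_config$r_ut_multiplier
  if (is.null(mult)) mult <- 1
  cohort <- withr_seed(spec$seed, {
    rbind(
      sample_group(spec$n_npe, spec$npe, spec$s_peak, spec$lr_correlation,
                   spec$bp_correlation, "NPE", 0L, 1),
      sample_group(spec$n_pe, spec$pe, spec$s_peak, spec$lr_correlation,
                   spec$bp_correlation, "PE", 0L, mult)
    )
  })
  if (is.null(cohort))
    cohort <- empty_cohort()
  rownames(cohort) <- NULL
  class(cohort) <- c("uf_cohort", "data.frame")
  validate_cohort(cohort)
  cohort
}

empty_cohort <- function() {
  data.frame(id = character(), group = character(), GA_weeks = numeric(),
             parity = numeric(), BMI = numeric(), SBP_mmHg = numeric(),
             DBP_mmHg = numeric(), HR_bpm = numeric(),
             CO_L_per_min = numeric(), PWV_m_per_s = numeric(),
             age_years = numeric(), weight_kg = numeric(),
             S_left_cm_per_s = numeric(), D_left_cm_per_s = numeric(),
             S_right_cm_per_s = numeric(), D_right_cm_per_s = numeric(),
             PI = numeric(), RI = numeric(), r_ut_mult = numeric(),
             stringsAsFactors = FALSE)
}

# run expr under a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Validate a cohort of patient records
#'
#' Checks the per-record invariants (`SBP > DBP > 0`, positive HR/CO/PWV,
#' `S >= D >= 0` both sides, right-side `RI` consistent with `(S - D)/S` to
#' 1e-9). Errors name the offending row and column.
#'
#' @param cohort a `uf_cohort` data frame
#' @return the cohort, invisibly
#' @export
validate_cohort <- function(cohort) {
  req <- names(empty_cohort())
  missing <- setdiff(req, names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  fail <- function(rows, what) {
    if (length(rows))
      stop("invalid patient record (row ", rows[1], ", id ",
           cohort$id[rows[1]], "): ", what)
  }
  with(cohort, {
    fail(which(!(SBP_mmHg > DBP_mmHg)), "SBP_mmHg must exceed DBP_mmHg")
    fail(which(!(DBP_mmHg > 0)), "DBP_mmHg must be > 0")
    fail(which(!(HR_bpm > 0)), "HR_bpm must be > 0")
    fail(which(!(CO_L_per_min > 0)), "CO_L_per_min must be > 0")
    fail(which(!(PWV_m_per_s > 0)), "PWV_m_per_s must be > 0")
    fail(which(!(S_left_cm_per_s >= D_left_cm_per_s & D_left_cm_per_s >= 0)),
         "left S_cm_per_s >= D_cm_per_s >= 0 violated")
    fail(which(!(S_right_cm_per_s >= D_right_cm_per_s & D_right_cm_per_s >= 0)),
         "right S_cm_per_s >= D_cm_per_s >= 0 violated")
    ok <- S_right_cm_per_s > 0
    fail(which(ok & abs(RI - (S_right_cm_per_s - D_right_cm_per_s) /
                          S_right_cm_per_s) > 1e-9),
         "RI inconsistent with (S - D)/S on the right side")
    invisible(NULL)
  })
  invisible(cohort)
}

#' Derived per-beat quantities
#'
#' Stroke volume, pulse pressure and mean arterial pressure from the measured
#' fields: `SV = CO/HR`, `PP = SBP - DBP`, `MAP = DBP + PP/3` (the standard
#' clinical one-third rule).
#'
#' @param record a `uf_cohort` data frame (any number of rows)
#' @return a data frame with columns `SV_mL`, `pulse_pressure_mmHg`,
#'   `MAP_mmHg`
#' @export
derive_fields <- function(record) {
  pp <- record$SBP_mmHg - record$DBP_mmHg
  data.frame(
    SV_mL = record$CO_L_per_min * 1000 / record$HR_bpm,
    pulse_pressure_mmHg = pp,
    MAP_mmHg = record$DBP_mmHg + pp / 3
  )
}

#' Parametric uterine Doppler waveform
#'
#' Builds one cardiac period of a uterine-artery velocity waveform with the
#' prescribed peak systolic velocity `S` and end-diastolic velocity `D`:
#' a half-sine systolic rise from `D` at `t = 0` to `S` at the systolic peak,
#' followed by an exponential diastolic decay rescaled to close the period
#' exactly at `D` (so the waveform is periodic and its extrema are exactly
#' `S` and `D`). Only `S`, `D` and the derived indices enter the analysis;
#' the template shape stands in for the unparameterised clinical waveform.
#'
#' @param S peak systolic velocity, cm/s
#' @param D end-diastolic velocity, cm/s (`0 <= D <= S`)
#' @param HR heart rate, beats/min
#' @param t_peak_frac systolic time-to-peak as a fraction of the period
#' @param tau_frac diastolic decay time constant as a fraction of the period
#' @param n number of uniform samples over one period
#' @return a `uf_doppler` list: `time_s`, `velocity_cm_per_s`, `S`, `D`,
#'   `period_s`
#' @export
#' @examples
#' w <- generate_uterine_waveform(60, 15, 90)
#' max(w$velocity_cm_per_s)  # 60
generate_uterine_waveform <- function(S, D, HR, t_peak_frac = 0.15,
                                      tau_frac = 0.25, n = 201L) {
  if (!(HR > 0)) stop("generate_uterine_waveform: HR must be > 0")
  if (D < 0) stop("generate_uterine_waveform: D must be >= 0")
  if (S < D) stop("generate_uterine_waveform: S must be >= D")
  if (n < 5) stop("generate_uterine_waveform: n must be >= 5")
  period <- 60 / HR
  t <- seq(0, period, length.out = n)
  ip <- max(2L, min(n - 1L, round(t_peak_frac * (n - 1)) + 1L))
  tp <- t[ip]
  tau <- tau_frac * period
  w <- numeric(n)
  rise <- t <= tp
  w[rise] <- sin(pi * t[rise] / (2 * tp))
  dec <- exp(-(t[!rise] - tp) / tau)
  dec_end <- exp(-(period - tp) / tau)
  w[!rise] <- (dec - dec_end) / (1 - dec_end)
  v <- D + (S - D) * w
  structure(list(time_s = t, velocity_cm_per_s = v, S = S, D = D,
                 period_s = period), class = "uf_doppler")
}

#' Write a Doppler waveform to CSV
#'
#' Two columns: `time_s`, `velocity_cm_per_s`.
#'
#' @param waveform a `uf_doppler` from [generate_uterine_waveform()]
#' @param path file path
#' @return the path, invisibly
#' @export
write_waveform <- function(waveform, path) {
  utils::write.csv(data.frame(time_s = waveform$time_s,
                              velocity_cm_per_s = waveform$velocity_cm_per_s),
                   path, row.names = FALSE)
  invisible(path)
}
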