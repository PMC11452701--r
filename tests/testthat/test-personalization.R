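test_that("initial guess matches the closed-form seeds", {
  rec <- npe_mean_record()
  g <- initial_guess(rec)
  # R_periph0 = MAP/CO  (~1.36 mmHg s/mL on the clinical scale)
  MAP <- 89.6 + 44.3 / 3
  expect_equal(g$R_periph, mmhg_to_pa(MAP) / lmin_to_m3s(4.6),
               tolerance = 1e-12)
  expect_equal(g$R_periph_mmHg_s_mL, MAP / (lmin_to_m3s(4.6) * 1e6),
               tolerance = 1e-12)
  expect_equal(round(g$R_periph_mmHg_s_mL, 2), 1.36)
  # C_syst0 = SV/PP (~1.13 mL/mmHg)
  SV_mL <- 4600 / 91.6
  expect_equal(g$C_syst_mL_mmHg, SV_mL / 44.3, tolerance = 1e-12)
  expect_equal(round(g$C_syst_mL_mmHg, 2), 1.13)
  # monotonicity: higher CO at fixed pressures lowers R_periph0
  rec2 <- rec; rec2$CO_L_per_min <- 6
  expect_lt(initial_guess(rec2)$R_periph, g$R_periph)
  # k_beta inverts the wave-speed relation at the measured PWV
  expect_gt(g$k_beta, 0)
})

test_that("infeasible targets are rejected before any solve", {
  rec <- npe_mean_record()
  rec$DBP_mmHg <- rec$SBP_mmHg + 5
  expect_error(measurement_targets(rec), "SBP must exceed DBP")
  rec2 <- npe_mean_record()
  rec2$S_right_cm_per_s <- 10; rec2$D_right_cm_per_s <- 40
  expect_error(measurement_targets(rec2), "S must be >= D")
  rec3 <- npe_mean_record(); rec3$CO_L_per_min <- -1
  expect_error(measurement_targets(rec3), "positive")
})

test_that("calibration converges on the group-mean patient and logs sensibly", {
  tw <- suppressWarnings(calibrate(measurement_targets(npe_mean_record()),
                                   settings = fast_settings(),
                                   max_iter = 14))
  expect_true(tw$converged)
  expect_true(all(tw$residuals <= 0.02 + 1e-12))
  expect_true(all(unlist(tw[c("R_periph", "C_syst", "k_beta", "A")]) > 0))
  expect_true(all(tw$R_ut > 0))
  # convergence log covers every iteration with residual columns
  expect_true(is.data.frame(tw$log))
  expect_equal(nrow(tw$log), tw$iterations)
  expect_true(all(c("MAP", "PP", "PWV", "RI_right") %in% names(tw$log)))
  # model observables honour the targets
  expect_lt(abs(tw$observables$MAP_mmHg / (89.6 + 44.3 / 3) - 1), 0.02)
  expect_lt(abs(tw$observables$PWV_m_per_s / 7.3 - 1), 0.02)
})

test_that("a converged twin is a fixed point: its parameters reproduce its observables", {
  tw <- suppressWarnings(calibrate(measurement_targets(npe_mean_record()),
                                   settings = fast_settings(),
                                   max_iter = 14))
  res2 <- solve_network(tw$network,
                        inflow_waveform(4.6, 91.6),
                        fast_settings())
  obs2 <- uteroflow:::model_observables(res2, tw$network)
  # agreement is limited by the periodic-state tolerance of the fast solver
  # settings (4e-3 relative L2 aggregated over sites; individual
  # observables can deviate somewhat more)
  expect_lt(abs(obs2$MAP_mmHg / tw$observables$MAP_mmHg - 1), 8e-3)
  expect_lt(abs(obs2$uterine$right$RI / tw$observables$uterine$right$RI - 1),
            8e-3)
})

test_that("raising uterine chain resistance does not decrease uterine RI or pi1", {
  ris <- c(); pi1s <- c()
  for (rs in c(0.8, 1.3, 2)) {
    net <- build_default_network(r_ut_scale = rs, topology = "reduced")
    res <- suppressWarnings(solve_network(net, inflow_waveform(4.6, 91.6),
                                          fast_settings()))
    st <- waveform_stats(res$sites$uterine_inlet_right)
    ris <- c(ris, (st$V_max - st$V_min) / st$V_max)
    cc <- net$cascades$right
    pi1s <- c(pi1s, (cc$R_ut + cc$R_arc + cc$R_rad) / 1.73e8)
  }
  expect_true(all(diff(ris) > -0.01))
  expect_true(all(diff(pi1s) > 0))
})

test_that("parameter recovery succeeds on model-generated targets", {
  set.seed(23)
  fast <- fast_settings()
  n_ok <- 0; n <- 5
  for (k in 1:n) {
    R0 <- runif(1, 1.3e8, 2.2e8); C0 <- runif(1, 5e-9, 1.4e-8)
    kb <- runif(1, 0.9, 2.5)
    ru <- runif(2, 0.7, 2); ph <- runif(2, 0.5, 0.8)
    CO <- runif(1, 3.8, 6.5); HR <- runif(1, 72, 105)
    net <- build_default_network(R_total = R0, C_wk = C0, k_beta = kb,
                                 r_ut_scale = c(left = ru[1], right = ru[2]),
                                 cascade_distal_fraction = c(left = ph[1],
                                                             right = ph[2]))
    ref <- suppressWarnings(solve_network(net, inflow_waveform(CO, HR), fast))
    obs <- uteroflow:::model_observables(ref, net)
    rec <- npe_mean_record()
    rec$SBP_mmHg <- obs$SBP_mmHg; rec$DBP_mmHg <- obs$DBP_mmHg
    rec$HR_bpm <- HR; rec$CO_L_per_min <- CO
    rec$PWV_m_per_s <- obs$PWV_m_per_s
    tg <- measurement_targets(rec)
    for (side in c("left", "right")) {
      tg$uterine[[side]]$U_mean_cm_s <- obs$uterine[[side]]$U_mean_cm_s
      tg$uterine[[side]]$RI <- obs$uterine[[side]]$RI
    }
    tw <- suppressWarnings(calibrate(tg, settings = fast, max_iter = 14))
    n_ok <- n_ok + (tw$converged && max(tw$residuals) <= 0.02)
  }
  expect_gte(n_ok, n - 1)
})

test_that("biomarker inputs require convergence and are positive and coherent", {
  rec <- npe_mean_record()
  tw <- suppressWarnings(calibrate(measurement_targets(rec),
                                   settings = fast_settings(), max_iter = 14))
  inp <- extract_biomarker_inputs(tw, rec)
  expect_true(all(unlist(inp) > 0))
  expect_lt(inp$dP_pulse, inp$P_syst)
  expect_equal(inp$SV, lmin_to_m3s(4.6) * 60 / 91.6, tolerance = 1e-12)
  # a non-converged twin is refused unless overridden
  tw2 <- tw; tw2$converged <- FALSE
  expect_error(extract_biomarker_inputs(tw2, rec), "did not converge")
  expect_silent(extract_biomarker_inputs(tw2, rec,
                                         allow_nonconverged = TRUE))
})
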