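test_that("default network has the expected structure and sites", {
  for (topo in c("full", "reduced")) {
    net <- build_default_network(topology = topo)
    s <- net$segments
    expect_equal(sum(s$parent == ""), 1)
    # every non-root segment names exactly one existing parent
    expect_true(all(s$parent[s$parent != ""] %in% s$name))
    expect_true(all(s$A0_prox > 0 & s$A0_dist > 0))
    expect_true(all(s$beta > 0))
    expect_setequal(names(net$cascades), c("left", "right"))
    sites <- uteroflow:::default_sites(net)
    expect_true(all(c("uterine_inlet_left", "uterine_outlet_left",
                      "arcuate_left", "radial_left", "uterine_inlet_right",
                      "uterine_outlet_right", "arcuate_right",
                      "radial_right") %in% names(sites)))
  }
})

test_that("network validation catches malformed trees and parameters", {
  net <- build_default_network()
  bad <- net; bad$segments$parent[2] <- "nonexistent"
  expect_error(validate_network(bad), "unknown parent")
  bad <- net; bad$segments$length_m[1] <- -1
  expect_error(validate_network(bad), "length")
  bad <- net; bad$cascades$left$R_ut <- -1
  expect_error(validate_network(bad), "cascade")
  expect_error(build_default_network(R_total = -1))
})

test_that("network description round-trips through JSON", {
  net <- build_default_network(R_total = 2e8, k_beta = 1.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$segments$beta, net$segments$beta, tolerance = 1e-12)
  expect_equal(back$cascades$left$R_ut, net$cascades$left$R_ut,
               tolerance = 1e-12)
})

test_that("tube-law wave speed obeys its scaling and physiologic range", {
  c1 <- wave_speed(1e6, 5e-4)
  expect_equal(wave_speed(2e6, 5e-4), sqrt(2) * c1)
  # aortic-range stiffness and area (beta 2e6-8e6 Pa/m, A ~ 6 cm^2) give
  # wave speeds in the physiologic 4-12 m/s band
  for (beta in c(2e6, 5e6, 8e6)) {
    c0 <- wave_speed(beta, 6e-4, 1060)
    expect_gt(c0, 4); expect_lt(c0, 12)
  }
  expect_error(wave_speed(-1, 1), "must all be > 0")
})

test_that("measured pulse transit speed matches the tube-law formula", {
  # long, uniform, nearly frictionless vessel; low-amplitude pulse
  net <- single_vessel_network(L = 1.0, r_prox = 0.006, c0 = 6,
                               R1 = 1060 * 6 / (pi * 0.006^2), R2 = 0,
                               C = 1e-10, mu = 1e-6)
  inflow <- inflow_waveform(0.45, 60)      # small stroke volume
  # two cycles by design (first-passage timing, not a periodic state)
  res <- suppressWarnings(
    solve_network(net, inflow,
                  solver_settings(dx_target = 0.01, max_cycles = 2,
                                  tol = 1e-9, p_init_mmHg = 80,
                                  eps_filter = 0),
                  extra_sites = list(a = list(segment = "v", pos = 0.2),
                                     b = list(segment = "v", pos = 0.8))))
  foot <- function(u) {
    thr <- min(u) + 0.05 * (max(u) - min(u))
    res$time[which(u > thr)[1]]
  }
  dt_transit <- foot(res$sites$b$U) - foot(res$sites$a$U)
  # reference speed at the working (pressurised) area
  A_work <- mean(res$sites$a$A)
  c_ref <- wave_speed(net$segments$beta[1], A_work, 1060)
  c_meas <- 0.6 / dt_transit
  expect_lt(abs(c_meas / c_ref - 1), 0.05)
})

test_that("Ohmic limit: mean pressure drop equals Q times R within 1%", {
  R <- 1.5e8; Q <- 8e-6
  net <- single_vessel_network(R1 = R, R2 = 0)
  res <- solve_network(net, constant_inflow(Q, 0.5),
                       solver_settings(tol = 1e-7, max_cycles = 30),
                       extra_sites = list(out = list(segment = "v", pos = 1)))
  P_expect <- Q * R + mmhg_to_pa(5)
  expect_lt(abs(mean(res$sites$out$P) / P_expect - 1), 0.01)
})

test_that("junction conservation: parent mean flow equals sum of child flows", {
  net <- y_network()
  res <- solve_network(net, inflow_waveform(4.8, 75),
                       solver_settings(tol = 1e-5, max_cycles = 20),
                       extra_sites = list(
                         pe = list(segment = "p", pos = 1),
                         c1s = list(segment = "c1", pos = 0),
                         c2s = list(segment = "c2", pos = 0)))
  qp <- mean(res$sites$pe$Q)
  qc <- mean(res$sites$c1s$Q) + mean(res$sites$c2s$Q)
  expect_lt(abs(qc / qp - 1), 0.005)
  # symmetric children split the flow equally
  expect_lt(abs(mean(res$sites$c1s$Q) / mean(res$sites$c2s$Q) - 1), 1e-6)
})

test_that("Windkessel diastolic decay constant equals R2*C within 5%", {
  R2 <- 1.2e9; C <- 1.5e-9
  # stiff short vessel so its own compliance is negligible next to C
  net <- single_vessel_network(L = 0.1, r_prox = 0.004, c0 = 10,
                               R1 = 4e7, R2 = R2, C = C)
  inflow <- inflow_waveform(3.5, 60, systolic_fraction = 0.3)
  res <- solve_network(net, inflow,
                       solver_settings(tol = 1e-6, max_cycles = 40),
                       extra_sites = list(out = list(segment = "v", pos = 1)))
  # log-linear fit over late diastole (inflow is exactly zero there)
  t <- res$time
  idx <- which(t > 0.6 * max(t) & t < 0.97 * max(t))
  p <- res$sites$out$P[idx] - mmhg_to_pa(5)
  fit <- stats::lm(log(p) ~ t[idx])
  tau <- -1 / stats::coef(fit)[2]
  expect_lt(abs(tau / (R2 * C) - 1), 0.05)
})

test_that("periodicity error metric and cycle convergence behave as specified", {
  a <- matrix(rnorm(100, 1e4, 10), 50, 2)
  expect_equal(periodicity_error(a, a), 0)
  b <- a + 5
  expect_gt(periodicity_error(a, b), 0)
  expect_error(periodicity_error(a, a[1:10, ]), "length")
  # cold-start transient: cycle-to-cycle error decreases to convergence
  net <- single_vessel_network()
  res <- solve_network(net, constant_inflow(8e-6, 0.5),
                       solver_settings(tol = 1e-8, max_cycles = 30))
  eh <- res$err_history
  expect_gt(eh[1], eh[length(eh)])
  expect_true(res$converged)
  expect_lt(res$periodicity_error, 1e-8)
})

test_that("halving the time step changes site pressures by less than 1%", {
  net <- build_default_network()
  inflow <- inflow_waveform(4.6, 91.6)
  base <- solve_network(net, inflow, solver_settings(tol = 2e-5,
                                                     max_cycles = 30))
  dt_half <- base$dt / 2
  fine <- solve_network(net, inflow,
                        solver_settings(dt = dt_half, tol = 2e-5,
                                        max_cycles = 30))
  for (site in c("aortic_root", "uterine_inlet_right", "arcuate_right")) {
    p1 <- c(mean(base$sites[[site]]$P), max(base$sites[[site]]$P),
            min(base$sites[[site]]$P))
    p2 <- c(mean(fine$sites[[site]]$P), max(fine$sites[[site]]$P),
            min(fine$sites[[site]]$P))
    expect_lt(max(abs(p2 / p1 - 1)), 0.01, label = site)
  }
})

test_that("a left/right-symmetric network yields identical sides", {
  net <- build_default_network()
  res <- solve_network(net, inflow_waveform(4.6, 91.6),
                       solver_settings(tol = 1e-4))
  for (pair in list(c("uterine_inlet_left", "uterine_inlet_right"),
                    c("arcuate_left", "arcuate_right"),
                    c("radial_left", "radial_right"))) {
    l <- res$sites[[pair[1]]]; r <- res$sites[[pair[2]]]
    expect_lt(max(abs(l$P - r$P)) / max(abs(r$P)), 1e-8)
    expect_lt(max(abs(l$U - r$U)) / max(abs(r$U)), 1e-8)
  }
})

test_that("inflow waveform integrates to the stroke volume", {
  inf <- inflow_waveform(4.6, 91.6)
  t <- seq(0, inf$period, length.out = 20001)
  q <- inflow_eval(inf, t)
  sv_num <- sum((q[-1] + q[-length(q)]) / 2) * diff(t[1:2])
  expect_lt(abs(sv_num / inf$SV_m3 - 1), 1e-3)
  expect_true(all(q >= 0))
})

test_that("cascade compartments follow the resistive-divider limit", {
  cc <- list(R_ut = 2e9, R_arc = 1.5e9, C_arc = 1e-16, A_arc = 2e-5,
             R_rad = 2e9, C_rad = 1e-16, A_rad = 6e-5, L_ut = 0,
             P_ven = mmhg_to_pa(5))
  t <- seq(0, 0.75, length.out = 200)
  P2 <- rep(mmhg_to_pa(90), length(t))       # constant drive
  out <- cascade_waveforms(P2, t, cc)
  Q <- (mmhg_to_pa(90) - cc$P_ven) / (cc$R_ut + cc$R_arc + cc$R_rad)
  expect_equal(mean(out$arcuate$P), cc$P_ven + Q * (cc$R_arc + cc$R_rad),
               tolerance = 1e-3)
  expect_equal(mean(out$radial$P), cc$P_ven + Q * cc$R_rad, tolerance = 1e-3)
  # velocity is flow over nominal area by definition
  expect_equal(out$arcuate$U, out$arcuate$Q / cc$A_arc)
  # raising the most distal resistance raises the arcuate pressure
  cc2 <- cc; cc2$R_rad <- 2 * cc$R_rad
  out2 <- cascade_waveforms(P2, t, cc2)
  expect_gt(mean(out2$arcuate$P), mean(out$arcuate$P))
})
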