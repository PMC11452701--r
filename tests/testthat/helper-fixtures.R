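# shared fixtures: small hand-built networks and records

# single straight vessel with one Windkessel terminal; R2 = 0 makes it a
# pure resistor clamped at P_out
single_vessel_network <- function(L = 0.2, r_prox = 0.005, r_dist = r_prox,
                                  c0 = 6, R1 = 1.5e8, R2 = 0, C = 1e-10,
                                  p_out_mmHg = 5, mu = 3.5e-3, rho = 1060) {
  s <- data.frame(name = "v", parent = "", length_m = L, r_prox_m = r_prox,
                  r_dist_m = r_dist, c0_m_per_s = c0, flow_frac = 1,
                  terminal = "windkessel", side = NA_character_,
                  stringsAsFactors = FALSE)
  s$A0_prox <- pi * r_prox^2
  s$A0_dist <- pi * r_dist^2
  s$beta <- 2 * rho * c0^2 / sqrt(0.5 * (s$A0_prox + s$A0_dist))
  s$R1 <- R1; s$R2 <- R2; s$C <- C; s$P_out <- mmhg_to_pa(p_out_mmHg)
  structure(list(segments = s, cascades = list(),
                 blood = list(rho = rho, mu = mu), k_beta = 1),
            class = "uf_network")
}

# symmetric Y bifurcation, both children ending in equal resistors
y_network <- function(R = 3e8, C = 1e-10, c0 = 6) {
  mk <- function(name, parent, L, r, frac = NA, term = "none") {
    d <- data.frame(name = name, parent = parent, length_m = L, r_prox_m = r,
                    r_dist_m = r, c0_m_per_s = c0, flow_frac = frac,
                    terminal = term, side = NA_character_,
                    stringsAsFactors = FALSE)
    d$A0_prox <- pi * r^2; d$A0_dist <- pi * r^2
    d$beta <- 2 * 1060 * c0^2 / sqrt(pi * r^2)
    d
  }
  s <- rbind(mk("p", "", 0.1, 0.008),
             mk("c1", "p", 0.1, 0.006, 0.5, "windkessel"),
             mk("c2", "p", 0.1, 0.006, 0.5, "windkessel"))
  s$R1 <- ifelse(s$terminal == "windkessel", R, NA)
  s$R2 <- ifelse(s$terminal == "windkessel", 0, NA)
  s$C <- ifelse(s$terminal == "windkessel", C, NA)
  s$P_out <- ifelse(s$terminal == "windkessel", mmhg_to_pa(5), NA)
  structure(list(segments = s, cascades = list(),
                 blood = list(rho = 1060, mu = 3.5e-3), k_beta = 1),
            class = "uf_network")
}

# the group-mean NPE patient used across personalisation tests
npe_mean_record <- function() {
  data.frame(id = "NPE0", group = "NPE", GA_weeks = 23.3, parity = 2,
             BMI = 29.6, SBP_mmHg = 133.9, DBP_mmHg = 89.6, HR_bpm = 91.6,
             CO_L_per_min = 4.6, PWV_m_per_s = 7.3, age_years = 32.2,
             weight_kg = 79, S_left_cm_per_s = 62, D_left_cm_per_s = 31,
             S_right_cm_per_s = 65, D_right_cm_per_s = 32.5, PI = 0.9,
             RI = 0.5, r_ut_mult = 1, stringsAsFactors = FALSE)
}

# settings for cohort-scale batch calibration in tests
fast_settings <- function() {
  solver_settings(dx_target = 0.03, tol = 4e-3, max_cycles = 8, cfl = 0.65)
}
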