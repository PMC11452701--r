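#' Default maternal arterial network
#'
#' Builds the reduced fixed-topology arterial tree used throughout the
#' package: ascending aorta to the iliac bifurcations, the internal-iliac /
#' uterine path on both sides, and the remaining systemic beds truncated to
#' three-element Windkessel terminals. Each uterine artery ends in a
#' utero-ovarian cascade: an ascending-uterine resistance feeding two RC
#' compartments (arcuate, then combined radial+spiral) that drain at venous
#' pressure. Geometry and reference wave speeds are literature-typical for a
#' pregnant adult; they are configuration, not assertions about any specific
#' patient, and the calibration loop rescales the main parameters.
#'
#' Segment stiffness uses the tube law `P = beta (sqrt(A) - sqrt(A0))` with
#' `beta = 2 rho c0^2 / sqrt(A0)`, so `c0` is the wave speed at the reference
#' area. Terminal resistances split a total peripheral resistance `R_total`
#' across beds by nominal flow fractions (uterine beds take
#' `uterine_flow_fraction` per side through their cascades); `R1` of each
#' Windkessel is the characteristic impedance of the feeding vessel.
#'
#' @param R_total total peripheral resistance, Pa s/m^3
#' @param C_wk total Windkessel compliance to distribute, m^3/Pa
#' @param k_beta global stiffness multiplier applied to every beta
#' @param uterine_flow_fraction nominal fraction of CO per uterine side
#' @param r_ut_scale multiplier on each side's cascade resistances (the
#'   "uterine resistance effect" knob)
#' @param cascade_distal_fraction fraction of each side's chain resistance
#'   placed distal to the arcuate compartment (the RI handle: raising it
#'   increases uterine-artery pulsatility at fixed total resistance);
#'   single number or named c(left =, right =)
#' @param cascade_inertance per-side inertance at the cascade entry,
#'   Pa s^2/m^3 (default 0 = purely resistive entry); attenuates pulsatile
#'   entry flow, allowing uterine RI below the resistive floor
#' @param area_scale global multiplier on every reference lumen area
#'   (vessel-size personalisation; the aortic area is a calibrated quantity)
#' @param p_out_mmHg Windkessel outflow pressure
#' @param p_ven_mmHg cascade venous pressure
#' @param rho blood density kg/m^3
#' @param mu blood viscosity Pa s
#' @param topology "full" (24 segments) or "reduced" (15 segments; upper
#'   body and splanchnic/renal beds folded into single terminals, uterine
#'   path untouched) for cohort-scale batch runs
#' @return a `uf_network` object
#' @export
#' @examples
#' net <- build_default_network()
#' nrow(net$segments)
build_default_network <- function(R_total = 1.73e8, C_wk = 8e-9, k_beta = 1,
                                  uterine_flow_fraction = 0.03,
                                  r_ut_scale = 1,
                                  cascade_distal_fraction = 0.65,
                                  cascade_inertance = 0,
                                  area_scale = 1,
                                  p_out_mmHg = 5, p_ven_mmHg = 5,
                                  rho = 1060, mu = 3.5e-3,
                                  topology = c("full", "reduced")) {
  stopifnot(R_total > 0, C_wk > 0, k_beta > 0, uterine_flow_fraction > 0,
            all(r_ut_scale > 0), all(cascade_distal_fraction > 0),
            all(cascade_distal_fraction < 1), area_scale > 0, rho > 0,
            mu > 0)
  topology <- match.arg(topology)
  seg <- function(name, parent, L, rp, rd, c0, frac = NA_real_,
                  terminal = "none", side = NA_character_)
    data.frame(name = name, parent = parent, length_m = L, r_prox_m = rp,
               r_dist_m = rd, c0_m_per_s = c0, flow_frac = frac,
               terminal = terminal, side = side, stringsAsFactors = FALSE)
  s_reduced <- rbind(
    seg("asc_aorta",          "",               0.050, 0.0135, 0.0125, 5.5),
    seg("upper_body",         "asc_aorta",      0.060, 0.0090, 0.0080, 7.0, 0.250, "windkessel"),
    seg("thoracic_aorta",     "asc_aorta",      0.160, 0.0105, 0.0085, 6.0),
    seg("splanchnic",         "thoracic_aorta", 0.050, 0.0055, 0.0050, 8.0, 0.500, "windkessel"),
    seg("abd_aorta",          "thoracic_aorta", 0.140, 0.0075, 0.0060, 6.8),
    seg("common_iliac_left",  "abd_aorta",      0.060, 0.0045, 0.0042, 7.5),
    seg("common_iliac_right", "abd_aorta",      0.060, 0.0045, 0.0042, 7.5),
    seg("external_iliac_left",  "common_iliac_left",  0.100, 0.0035, 0.0032, 8.0, 0.060, "windkessel"),
    seg("external_iliac_right", "common_iliac_right", 0.100, 0.0035, 0.0032, 8.0, 0.060, "windkessel"),
    seg("internal_iliac_left",  "common_iliac_left",  0.050, 0.0030, 0.0028, 8.5),
    seg("internal_iliac_right", "common_iliac_right", 0.050, 0.0030, 0.0028, 8.5),
    seg("pelvic_left",        "internal_iliac_left",  0.050, 0.0025, 0.0022, 9.0, 0.035, "windkessel"),
    seg("pelvic_right",       "internal_iliac_right", 0.050, 0.0025, 0.0022, 9.0, 0.035, "windkessel"),
    seg("uterine_left",       "internal_iliac_left",  0.100, 0.0016, 0.0015, 9.0, NA, "cascade", "left"),
    seg("uterine_right",      "internal_iliac_right", 0.100, 0.0016, 0.0015, 9.0, NA, "cascade", "right")
  )
  s_full <- rbind(
    seg("asc_aorta",          "",                0.050, 0.0135, 0.0130, 5.5),
    seg("brachiocephalic",    "asc_aorta",       0.035, 0.0085, 0.0075, 7.0, 0.125, "windkessel"),
    seg("aortic_arch",        "asc_aorta",       0.025, 0.0122, 0.0115, 5.5),
    seg("l_carotid",          "aortic_arch",     0.150, 0.0040, 0.0037, 8.0, 0.060, "windkessel"),
    seg("arch2",              "aortic_arch",     0.030, 0.0112, 0.0105, 5.7),
    seg("l_subclavian",       "arch2",           0.040, 0.0045, 0.0040, 8.0, 0.065, "windkessel"),
    seg("thoracic_aorta",     "arch2",           0.160, 0.0105, 0.0085, 6.0),
    seg("celiac",             "thoracic_aorta",  0.030, 0.0045, 0.0040, 8.0, 0.150, "windkessel"),
    seg("abd_aorta1",         "thoracic_aorta",  0.060, 0.0080, 0.0075, 6.5),
    seg("sup_mesenteric",     "abd_aorta1",      0.060, 0.0040, 0.0035, 8.0, 0.150, "windkessel"),
    seg("abd_aorta2",         "abd_aorta1",      0.020, 0.0075, 0.0070, 6.5),
    seg("renal_left",         "abd_aorta2",      0.030, 0.0035, 0.0030, 8.0, 0.100, "windkessel"),
    seg("renal_right",        "abd_aorta2",      0.030, 0.0035, 0.0030, 8.0, 0.100, "windkessel"),
    seg("abd_aorta3",         "abd_aorta2",      0.060, 0.0068, 0.0060, 7.0),
    seg("common_iliac_left",  "abd_aorta3",      0.060, 0.0045, 0.0042, 7.5),
    seg("common_iliac_right", "abd_aorta3",      0.060, 0.0045, 0.0042, 7.5),
    seg("external_iliac_left",  "common_iliac_left",  0.100, 0.0035, 0.0032, 8.0, 0.060, "windkessel"),
    seg("external_iliac_right", "common_iliac_right", 0.100, 0.0035, 0.0032, 8.0, 0.060, "windkessel"),
    seg("internal_iliac_left",  "common_iliac_left",  0.040, 0.0030, 0.0028, 8.5),
    seg("internal_iliac_right", "common_iliac_right", 0.040, 0.0030, 0.0028, 8.5),
    seg("pelvic_left",        "internal_iliac_left",  0.050, 0.0025, 0.0022, 9.0, 0.035, "windkessel"),
    seg("pelvic_right",       "internal_iliac_right", 0.050, 0.0025, 0.0022, 9.0, 0.035, "windkessel"),
    seg("uterine_left",       "internal_iliac_left",  0.100, 0.0016, 0.0015, 9.0, NA, "cascade", "left"),
    seg("uterine_right",      "internal_iliac_right", 0.100, 0.0016, 0.0015, 9.0, NA, "cascade", "right")
  )
  s <- if (topology == "full") s_full else s_reduced
  s$r_prox_m <- s$r_prox_m * sqrt(area_scale)
  s$r_dist_m <- s$r_dist_m * sqrt(area_scale)
  s$A0_prox <- pi * s$r_prox_m^2
  s$A0_dist <- pi * s$r_dist_m^2
  A0_mean <- 0.5 * (s$A0_prox + s$A0_dist)
  s$beta <- 2 * rho * s$c0_m_per_s^2 / sqrt(A0_mean) * k_beta

  # Windkessel terminals
  p_out <- mmhg_to_pa(p_out_mmHg)
  wk <- s$terminal == "windkessel"
  Ri <- R_total / s$flow_frac
  Z <- rho * s$c0_m_per_s / s$A0_dist
  s$R1 <- ifelse(wk, pmin(Z, 0.2 * Ri), NA_real_)
  s$R2 <- ifelse(wk, Ri - s$R1, NA_real_)
  s$C <- ifelse(wk, C_wk * s$flow_frac / sum(s$flow_frac[wk]), NA_real_)
  s$P_out <- ifelse(wk, p_out, NA_real_)

  # utero-ovarian cascades: the total chain resistance sets the nominal
  # uterine flow fraction (mean-velocity handle), and the distal fraction
  # phi sets the proximal/distal split (RI handle) at fixed total; the
  # distal part is divided 38.5/61.5 between arcuate and radial+spiral
  # (matching a 35/25/40 chain at the default phi = 0.65).
  # r_ut_scale / cascade_distal_fraction may be single numbers or named
  # c(left =, right =) vectors for per-side calibration.
  side_val <- function(x, side) {
    if (length(x) == 1) as.numeric(x) else as.numeric(x[[side]])
  }
  casc <- function(side) {
    rs <- side_val(r_ut_scale, side)
    phi <- side_val(cascade_distal_fraction, side)
    R_chain <- R_total / uterine_flow_fraction * rs
    # compartment compliance falls as the distal bed gets more resistive:
    # deficient spiral-artery remodelling leaves narrow muscular (stiff)
    # vessels, so R up implies C down; exponent 1.5 on the distal-fraction
    # ratio keeps the normal bed (phi = 0.65) at its reference compliance
    cs <- (0.65 / phi)^1.5
    list(R_ut = (1 - phi) * R_chain,
         R_arc = 0.385 * phi * R_chain, C_arc = 2e-10 * cs, A_arc = 2e-5,
         R_rad = 0.615 * phi * R_chain, C_rad = 2.5e-10 * cs, A_rad = 6e-5,
         L_ut = side_val(cascade_inertance, side),
         P_ven = mmhg_to_pa(p_ven_mmHg))
  }
  net <- structure(list(
    segments = s,
    cascades = list(left = casc("left"), right = casc("right")),
    blood = list(rho = rho, mu = mu),
    k_beta = k_beta
  ), class = "uf_network")
  validate_network(net)
  net
}

#' Validate an arterial network
#'
#' Checks tree structure (single root, every non-root with exactly one
#' existing parent, no cycles), positive geometry and stiffness, terminal
#' completeness of the leaves, and cascade parameter positivity.
#'
#' @param network a `uf_network`
#' @return the network, invisibly
#' @export
validate_network <- function(network) {
  s <- network$segments
  if (anyDuplicated(s$name)) stop("network: duplicate segment names")
  root <- s$name[s$parent == ""]
  if (length(root) != 1) stop("network: need exactly one root segment")
  bad <- setdiff(s$parent[s$parent != ""], s$name)
  if (length(bad)) stop("network: unknown parent segment '", bad[1], "'")
  # reachability from root (guards against cycles/disconnection)
  reached <- root
  repeat {
    nxt <- s$name[s$parent %in% reached & !(s$name %in% reached)]
    if (!length(nxt)) break
    reached <- c(reached, nxt)
  }
  if (length(reached) != nrow(s)) stop("network: segments not reachable from root")
  if (any(s$length_m <= 0)) stop("network: segment lengths must be > 0")
  if (any(s$A0_prox <= 0 | s$A0_dist <= 0)) stop("network: A0 must be > 0")
  if (any(s$beta <= 0)) stop("network: beta must be > 0")
  leaves <- !(s$name %in% s$parent)
  if (any(leaves & s$terminal == "none"))
    stop("network: leaf segment '", s$name[leaves & s$terminal == "none"][1],
         "' lacks a terminal model")
  wk <- s$terminal == "windkessel"
  if (any(wk & (s$R1 < 0 | s$R2 < 0 | s$C <= 0), na.rm = TRUE))
    stop("network: invalid Windkessel parameters")
  for (side in names(network$cascades)) {
    cc <- network$cascades[[side]]
    if (any(unlist(cc[c("R_ut", "R_arc", "R_rad", "C_arc", "C_rad",
                        "A_arc", "A_rad")]) <= 0))
      stop("network: invalid cascade parameters on side '", side, "'")
  }
  invisible(network)
}

#' Tube-law characteristic wave speed
#'
#' `c = sqrt(beta sqrt(A) / (2 rho))` for the tube law
#' `P = beta (sqrt(A) - sqrt(A0))`.
#'
#' @param beta wall stiffness coefficient, Pa/m
#' @param A cross-sectional area, m^2
#' @param rho blood density, kg/m^3
#' @return wave speed in m/s
#' @export
wave_speed <- function(beta, A, rho = 1060) {
  if (any(beta <= 0) || any(A <= 0) || any(rho <= 0))
    stop("wave_speed: beta, A and rho must all be > 0")
  sqrt(beta * sqrt(A) / (2 * rho))
}

#' Read / write a network description file
#'
#' Serialises the segment table, cascades and blood properties to JSON so a
#' network can be versioned alongside an analysis.
#'
#' @param network a `uf_network`
#' @param path file path
#' @return `read_network` returns a `uf_network`
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(list(segments = network$segments,
                            cascades = network$cascades,
                            blood = network$blood,
                            k_beta = network$k_beta),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$segments <- as.data.frame(x$segments, stringsAsFactors = FALSE)
  net <- structure(x, class = "uf_network")
  validate_network(net)
  net
}
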