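#' Aortic-root inflow waveform
#'
#' Periodic volumetric inflow prescribed at the ascending aorta: a half-sine
#' systolic ejection of duration `systolic_fraction * T` whose one-period
#' integral equals the stroke volume `SV = CO/HR` exactly (the half-sine
#' amplitude is `pi SV / (2 Ts)`), with zero flow in diastole.
#'
#' @param CO_L_per_min cardiac output
#' @param HR_bpm heart rate
#' @param systolic_fraction ejection duration as a fraction of the period
#' @return a `uf_inflow` list usable by [solve_network()]
#' @export
inflow_waveform <- function(CO_L_per_min, HR_bpm, systolic_fraction = 0.35) {
  if (CO_L_per_min <= 0 || HR_bpm <= 0) stop("inflow_waveform: CO and HR must be > 0")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("inflow_waveform: systolic_fraction must be in (0,1)")
  period <- 60 / HR_bpm
  SV <- lmin_to_m3s(CO_L_per_min) * period
  Ts <- systolic_fraction * period
  structure(list(type = "pulse", period = period, Ts = Ts,
                 Qmax = pi * SV / (2 * Ts), SV_m3 = SV,
                 HR_bpm = HR_bpm, CO_L_per_min = CO_L_per_min),
            class = "uf_inflow")
}

#' Constant inflow (for steady-state checks)
#'
#' @param Q_m3_per_s constant volumetric inflow
#' @param period nominal "cycle" length used for periodicity bookkeeping, s
#' @return a `uf_inflow` list
#' @export
constant_inflow <- function(Q_m3_per_s, period = 1) {
  if (Q_m3_per_s <= 0) stop("constant_inflow: Q must be > 0")
  structure(list(type = "constant", period = period, Ts = period,
                 Qmax = Q_m3_per_s), class = "uf_inflow")
}

#' Evaluate an inflow waveform on a time grid
#' @param inflow a `uf_inflow`
#' @param t times, s
#' @return Q(t) in m^3/s
#' @export
inflow_eval <- function(inflow, t) {
  if (inflow$type == "constant") return(rep(inflow$Qmax, length(t)))
  tc <- t %% inflow$period
  ifelse(tc < inflow$Ts, inflow$Qmax * sin(pi * tc / inflow$Ts), 0)
}

#' Solver settings
#'
#' @param dx_target target spatial step, m (segments keep at least 4 nodes)
#' @param dt time step, s; `NULL` selects it from the CFL bound with safety
#'   factor `cfl` (the bound is re-checked every step and violation is an
#'   error naming segment and time)
#' @param cfl CFL safety factor for the automatic time step
#' @param max_cycles maximum cardiac cycles to run
#' @param tol relative L2 cycle-to-cycle periodicity tolerance
#' @param p_init_mmHg uniform initial pressure
#' @param p_wk_init_mmHg initial Windkessel / cascade node pressure (default
#'   `p_init_mmHg + 15`); seeding it near the expected MAP avoids very slow
#'   lumped-state transients when compliances are large
#' @param eps_filter second-difference filter coefficient applied to interior
#'   nodes each step; damps the undamped odd-even grid mode of the
#'   Lax-Wendroff scheme while leaving resolved waves essentially untouched
#' @return a `uf_solver_settings` list
#' @export
solver_settings <- function(dx_target = 0.02, dt = NULL, cfl = 0.5,
                            max_cycles = 20L, tol = 1e-3, p_init_mmHg = 80,
                            p_wk_init_mmHg = NULL, eps_filter = 0.02) {
  stopifnot(dx_target > 0, cfl > 0, cfl <= 1, max_cycles >= 1, tol > 0,
            eps_filter >= 0, eps_filter < 0.25)
  if (is.null(p_wk_init_mmHg)) p_wk_init_mmHg <- p_init_mmHg + 15
  structure(list(dx_target = dx_target, dt = if (is.null(dt)) -1 else dt,
                 cfl = cfl, max_cycles = as.integer(max_cycles), tol = tol,
                 p_init_mmHg = p_init_mmHg, p_wk_init_mmHg = p_wk_init_mmHg,
                 eps_filter = eps_filter),
            class = "uf_solver_settings")
}

# discretize the segment table into the flat per-segment lists the C++ core
# expects (0-based indices, nodewise reference areas)
discretize_network <- function(network, settings) {
  s <- network$segments
  idx <- stats::setNames(seq_len(nrow(s)) - 1L, s$name)
  casc_names <- names(network$cascades)
  casc_idx <- stats::setNames(seq_along(casc_names) - 1L, casc_names)
  lapply(seq_len(nrow(s)), function(k) {
    n <- max(4L, as.integer(ceiling(s$length_m[k] / settings$dx_target)) + 1L)
    x <- seq(0, 1, length.out = n)
    A0 <- s$A0_prox[k] + (s$A0_dist[k] - s$A0_prox[k]) * x
    term <- switch(s$terminal[k], none = 0L, windkessel = 1L, cascade = 2L)
    list(name = s$name[k], dx = s$length_m[k] / (n - 1), beta = s$beta[k],
         A0 = A0,
         parent = if (s$parent[k] == "") -1L else unname(idx[s$parent[k]]),
         children = unname(idx[s$name[s$parent == s$name[k]]]),
         term = term,
         R1 = if (term == 1L) s$R1[k] else 0,
         R2 = if (term == 1L) s$R2[k] else 0,
         C = if (term == 1L) s$C[k] else 0,
         Pout = if (term == 1L) s$P_out[k] else 0,
         cascade = if (term == 2L) unname(casc_idx[s$side[k]]) else -1L)
  })
}

default_sites <- function(network) {
  s <- network$segments
  root <- if ("asc_aorta" %in% s$name) "asc_aorta" else s$name[s$parent == ""]
  sites <- list(
    aortic_root = list(segment = root, pos = 0),
    asc_aorta_mid = list(segment = root, pos = 0.5)
  )
  for (side in names(network$cascades)) {
    ut <- paste0("uterine_", side)
    if (ut %in% s$name) {
      sites[[paste0("uterine_inlet_", side)]] <- list(segment = ut, pos = 0)
      sites[[paste0("uterine_outlet_", side)]] <- list(segment = ut, pos = 1)
      sites[[paste0("arcuate_", side)]] <- list(cascade = side, comp = 0L)
      sites[[paste0("radial_", side)]] <- list(cascade = side, comp = 1L)
    }
  }
  sites
}

#' Solve the network to a periodic state
#'
#' Integrates the 1D mass/momentum equations with tube-law closure over
#' repeated cardiac cycles until the cycle-to-cycle relative L2 pressure
#' difference at the monitored sites drops below `settings$tol` (or
#' `max_cycles` is reached, in which case the result is flagged
#' non-converged). Junctions enforce continuity of static pressure and flow;
#' terminals are three-element Windkessels; uterine outlets drive the
#' utero-ovarian RC cascades.
#'
#' @param network a `uf_network`
#' @param inflow a `uf_inflow`
#' @param settings a [solver_settings()]
#' @param extra_sites optional named list of additional monitoring sites,
#'   each `list(segment =, pos =)` with `pos` in `[0, 1]`
#' @return a `uf_simresult`: `time` (s, final cycle), `dt`, named `sites`
#'   (each with vectors `P` Pa, `Q` m^3/s, `U` m/s, `A` m^2), `cycles`,
#'   `periodicity_error`, `err_history`, `converged`, `period`
#' @export
solve_network <- function(network, inflow, settings = solver_settings(),
                          extra_sites = NULL) {
  validate_network(network)
  segs <- discretize_network(network, settings)
  names(segs) <- vapply(segs, `[[`, "", "name")
  site_spec <- c(default_sites(network), extra_sites)
  seg_index <- stats::setNames(seq_along(segs) - 1L, names(segs))
  casc_names <- names(network$cascades)
  sites_flat <- lapply(site_spec, function(st) {
    if (!is.null(st$cascade)) {
      list(seg = -1L, node = 0L,
           cascade = unname(which(casc_names == st$cascade) - 1L),
           comp = as.integer(st$comp))
    } else {
      k <- seg_index[[st$segment]]
      n <- length(segs[[st$segment]]$A0)
      list(seg = unname(k), node = as.integer(round(st$pos * (n - 1))),
           cascade = -1L, comp = 0L)
    }
  })
  set <- list(rho = network$blood$rho, mu = network$blood$mu,
              p_init = mmhg_to_pa(settings$p_init_mmHg), cfl = settings$cfl,
              tol = settings$tol, max_cycles = settings$max_cycles,
              dt = settings$dt, eps_filter = settings$eps_filter,
              p_wk_init = mmhg_to_pa(settings$p_wk_init_mmHg))
  raw <- .solve_network_cpp(unname(segs), unname(network$cascades),
                            unclass(inflow), set, unname(sites_flat))
  site_names <- names(site_spec)
  sites <- lapply(seq_along(site_names), function(k)
    list(P = raw$P[, k], Q = raw$Q[, k], U = raw$U[, k], A = raw$A[, k]))
  names(sites) <- site_names
  if (!raw$converged)
    warning("solve_network: periodicity tolerance not reached after ",
            raw$cycles, " cycles (error ",
            signif(raw$periodicity_error, 3), ")")
  structure(list(time = raw$time, dt = raw$dt, sites = sites,
                 cycles = raw$cycles,
                 periodicity_error = raw$periodicity_error,
                 err_history = raw$err_history, converged = raw$converged,
                 period = inflow$period), class = "uf_simresult")
}

#' Cycle-to-cycle periodicity error
#'
#' Relative L2 difference of monitored pressure waveforms between two
#' consecutive cycles, aggregated over sites: zero for identical cycles.
#'
#' @param cycle_a,cycle_b matrices (time x site) or vectors of pressures
#' @return a scalar
#' @export
periodicity_error <- function(cycle_a, cycle_b) {
  a <- as.numeric(cycle_a); b <- as.numeric(cycle_b)
  if (length(a) != length(b)) stop("periodicity_error: cycles differ in length")
  den <- sqrt(sum(a^2))
  num <- sqrt(sum((b - a)^2))
  if (den > 0) num / den else num
}

#' Integrate the utero-ovarian cascade under a prescribed drive
#'
#' Stand-alone 0D integration of the two-compartment (arcuate, radial+spiral)
#' RC chain driven by a periodic uterine-artery outlet pressure P2(t):
#' implicit Euler over repeated cycles until the compartment pressures are
#' periodic. Velocities are compartment outflow divided by the nominal areas.
#'
#' @param P2 uterine outlet pressure over one period, Pa
#' @param time time grid for `P2` (uniform, one period), s
#' @param cascade a cascade parameter list (see [build_default_network()])
#' @param max_cycles,tol periodic-state controls
#' @return list with `time`, `Q_ut`, and per compartment `P`, `Q`, `U`
#' @export
cascade_waveforms <- function(P2, time, cascade, max_cycles = 200L,
                              tol = 1e-9) {
  n <- length(P2)
  stopifnot(length(time) == n, n >= 2)
  dt <- diff(time[1:2])
  cc <- cascade
  Parc <- mean(P2) * 0.8
  Prad <- 0.5 * (Parc + cc$P_ven)
  outP <- matrix(0, n, 2)
  prev <- NULL
  for (cyc in seq_len(max_cycles)) {
    for (i in seq_len(n)) {
      # implicit Euler on the chain with the entry flow implicit in Parc,
      # which stays stable down to the zero-compliance (resistive) limit
      a11 <- cc$C_arc / dt + 1 / cc$R_arc + 1 / cc$R_ut
      a12 <- -1 / cc$R_arc
      a21 <- -1 / cc$R_arc
      a22 <- cc$C_rad / dt + 1 / cc$R_arc + 1 / cc$R_rad
      b1 <- cc$C_arc / dt * Parc + P2[i] / cc$R_ut
      b2 <- cc$C_rad / dt * Prad + cc$P_ven / cc$R_rad
      det <- a11 * a22 - a12 * a21
      Parc <- (b1 * a22 - a12 * b2) / det
      Prad <- (a11 * b2 - a21 * b1) / det
      outP[i, ] <- c(Parc, Prad)
    }
    if (!is.null(prev) && periodicity_error(prev, outP) < tol) break
    prev <- outP + 0
  }
  Q_arc <- (outP[, 1] - outP[, 2]) / cc$R_arc
  Q_rad <- (outP[, 2] - cc$P_ven) / cc$R_rad
  list(time = time,
       Q_ut = (P2 - outP[, 1]) / cc$R_ut,
       arcuate = list(P = outP[, 1], Q = Q_arc, U = Q_arc / cc$A_arc),
       radial = list(P = outP[, 2], Q = Q_rad, U = Q_rad / cc$A_rad))
}

#' Waveform summary statistics
#'
#' Extrema and time-averages of the pressure and velocity waveforms at one
#' monitored site of a periodic solution (uniform grid, so the mean of the
#' samples is the trapezoidal time-average over the period).
#'
#' @param x either a `uf_simresult` site entry (list with `P` and `U`) or a
#'   numeric vector
#' @return for a site: list with `P_max`, `P_min`, `P_mean`, `V_max`,
#'   `V_min`, `V_mean` (SI units)
#' @export
waveform_stats <- function(x) {
  if (is.list(x)) {
    list(P_max = max(x$P), P_min = min(x$P), P_mean = mean(x$P),
         V_max = max(x$U), V_min = min(x$U), V_mean = mean(x$U))
  } else {
    list(V_max = max(x), V_min = min(x), V_mean = mean(x))
  }
}
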