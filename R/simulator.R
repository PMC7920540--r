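#' Passive membrane parameters
#'
#' @param rm_kohm_cm2 specific membrane resistance (kOhm cm^2).
#' @param ri_ohm_cm cytoplasmic (axial) resistivity (Ohm cm).
#' @param cm_uF_cm2 specific membrane capacitance (uF/cm^2).
#' @param e_pas_mV leak reversal potential (mV).
#' @export
passive_params <- function(rm_kohm_cm2 = 26.0, ri_ohm_cm = 60.0,
                           cm_uF_cm2 = 1.0, e_pas_mV = -75.75) {
  stopifnot(rm_kohm_cm2 > 0, ri_ohm_cm > 0, cm_uF_cm2 > 0)
  structure(list(rm_kohm_cm2 = rm_kohm_cm2, ri_ohm_cm = ri_ohm_cm,
                 cm_uF_cm2 = cm_uF_cm2, e_pas_mV = e_pas_mV),
            class = "passive_params")
}

#' Assemble a compartmental cell model
#'
#' Distributes the channel densities over the discretized morphology
#' (per-compartment maximal conductance = density x compartment area),
#' tabulates the gating curves at the simulation temperature, and returns a
#' ready-to-integrate cell.
#'
#' @param m a [morphology()].
#' @param dist a [distribution_table()].
#' @param pas a [passive_params()].
#' @param catalogue a [kinetics_catalogue()].
#' @param temp_c simulation temperature (deg C).
#' @param max_seg_length discretization limit (um).
#' @param scheme a [region_scheme()].
#' @param ca a [calcium_pools()] template.
#' @param v_init initial voltage (mV); defaults to the leak reversal.
#' @return A `cell_model` object.
#' @export
assemble <- function(m, dist = distribution_table(), pas = passive_params(),
                     catalogue = kinetics_catalogue(), temp_c = 27,
                     max_seg_length = 20, scheme = region_scheme(),
                     ca = calcium_pools(), v_init = NULL) {
  comps <- discretize(m, max_seg_length = max_seg_length,
                      ri = pas$ri_ohm_cm, scheme = scheme)
  if (!all(comps$label %in% names(dist)[-1]))
    stop("unknown region label: ",
         paste(setdiff(comps$label, names(dist)[-1]), collapse = ", "),
         call. = FALSE)
  ncomp <- nrow(comps)
  area_cm2 <- comps$area_um2 * 1e-8
  chan_names <- dist$channel
  nchan <- length(chan_names)
  gbar <- matrix(0, ncomp, nchan, dimnames = list(NULL, chan_names))
  for (c_i in seq_len(nchan)) {
    dens <- unlist(dist[c_i, comps$label])
    gbar[, c_i] <- dens * area_cm2 * 1e6   # uS, or P*area*1e6 for GHK
  }

  # voltage grid and gating tables
  v0 <- -130; v1 <- 60; dvg <- 0.05
  vg <- seq(v0, v1, by = dvg)
  gate_chan <- integer(0); gate_pow <- integer(0); gate_names <- character(0)
  inf_rows <- list(); tau_rows <- list()
  for (c_i in seq_len(nchan)) {
    sp <- catalogue[[chan_names[c_i]]]
    if (is.null(sp)) stop("catalogue lacks channel ", chan_names[c_i], call. = FALSE)
    for (gn in names(sp$gates)) {
      g <- sp$gates[[gn]]
      gate_chan <- c(gate_chan, c_i - 1L)
      gate_pow <- c(gate_pow, g$power)
      gate_names <- c(gate_names, paste0(chan_names[c_i], "_", gn))
      inf_rows[[length(inf_rows) + 1L]] <- gate_inf(g, vg)
      tau_rows[[length(tau_rows) + 1L]] <- pmax(gate_tau(g, vg, temp_c), 1e-3)
    }
  }
  gate_inf_tab <- do.call(rbind, inf_rows)
  gate_tau_tab <- do.call(rbind, tau_rows)

  kinds <- vapply(catalogue[chan_names], function(s) s$conduction$kind, "")
  chan_kind <- ifelse(kinds == "ghk_ca", 1L, 0L)
  erev <- vapply(catalogue[chan_names], function(s)
    if (s$conduction$kind == "ohmic") s$conduction$erev else 0, 0)
  cpool <- vapply(catalogue[chan_names], function(s) {
    if (is.null(s$ca_pool)) -1L else match(s$ca_pool$pool, c("sk", "ano")) - 1L
  }, 0L)
  csrc <- vapply(catalogue[chan_names], function(s) {
    if (is.null(s$ca_source)) -1L else match(s$ca_source, c("cal", "cat")) - 1L
  }, 0L)
  hill_n <- vapply(catalogue[chan_names], function(s)
    if (is.null(s$ca_pool)) 0 else s$ca_pool$hill_n, 0)
  ec50 <- vapply(catalogue[chan_names], function(s)
    if (is.null(s$ca_pool)) 1 else s$ca_pool$ec50_uM, 0)

  ghk_ch <- which(chan_kind == 1L)
  ghk_tab <- if (length(ghk_ch)) {
    cc <- catalogue[[chan_names[ghk_ch[1]]]]$conduction
    ghk_flux(vg, cc$cai_mM, cc$cao_mM, temp_c)
  } else rep(0, length(vg))

  cmat <- list(
    parent = as.integer(comps$parent - 1L),
    g_ax = comps$g_axial_uS,
    c_nF = pas$cm_uF_cm2 * area_cm2 * 1e3,
    g_pas_uS = area_cm2 / (pas$rm_kohm_cm2 * 1e3) * 1e6,
    e_pas = pas$e_pas_mV,
    area_cm2 = area_cm2,
    chan_kind = chan_kind, erev = erev,
    chan_ca_pool = cpool, chan_ca_source = csrc,
    hill_n = hill_n, ec50_uM = ec50,
    gate_chan = gate_chan, gate_pow = gate_pow,
    gate_inf_tab = gate_inf_tab, gate_tau_tab = gate_tau_tab,
    ghk_tab = ghk_tab, v_grid_v0 = v0, v_grid_dv = dvg,
    ca_depth_um = ca$depth_um, ca_rest_uM = ca$ca_rest_uM,
    ca_fraction = ca$pools$fraction, ca_tau_ms = ca$pools$tau_ms,
    v_init = if (is.null(v_init)) pas$e_pas_mV else v_init)

  structure(list(morphology = m, comps = comps, pas = pas, dist = dist,
                 catalogue = catalogue, temp_c = temp_c,
                 gbar = gbar, chan_names = chan_names,
                 gate_names = gate_names, core = cmat,
                 pharmacology = stats::setNames(rep(1, nchan), chan_names),
                 rest = NULL),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  ph <- x$pharmacology[x$pharmacology != 1]
  cat(sprintf("<cell_model: %d compartments, %d channels, %.1f degC%s>\n",
              nrow(x$comps), length(x$chan_names), x$temp_c,
              if (length(ph)) paste0("; pharmacology ",
                                     paste(names(ph), ph, sep = "=", collapse = ", "))
              else ""))
  invisible(x)
}

#' Scale channel conductances (virtual pharmacology)
#'
#' Multiplies the maximal conductance of the named channels everywhere in
#' the cell; factors compose multiplicatively and a factor of 0 removes the
#' channel exactly.
#'
#' @param cell a `cell_model`.
#' @param scales named numeric factors, e.g. `c(KM = 0, IH = 2)`.
#' @return The modified `cell_model` (any cached resting state is dropped).
#' @export
apply_pharmacology <- function(cell, scales) {
  stopifnot(all(names(scales) %in% cell$chan_names), all(scales >= 0))
  cell$pharmacology[names(scales)] <-
    cell$pharmacology[names(scales)] * unname(scales)
  cell$rest <- NULL
  cell
}

#' Current-clamp stimulus description
#'
#' A constant bias current from t = 0 plus a rectangular step.
#'
#' @param bias_pA holding current (pA).
#' @param step_pA step amplitude (pA).
#' @param onset_ms,dur_ms step timing (ms).
#' @param total_ms trace duration (ms).
#' @export
stimulus <- function(bias_pA = 0, step_pA = 0, onset_ms = 0, dur_ms = 0,
                     total_ms = 1000) {
  stopifnot(onset_ms >= 0, onset_ms + dur_ms <= total_ms + 1e-9)
  structure(list(bias_pA = bias_pA, step_pA = step_pA, onset_ms = onset_ms,
                 dur_ms = dur_ms, total_ms = total_ms),
            class = "stimulus")
}

effective_gbar <- function(cell) {
  sweep(cell$gbar, 2, cell$pharmacology, `*`)
}

#' Integrate the cable equations under a current-clamp stimulus
#'
#' Implicit fixed-step integration (backward Euler on the voltage with
#' Hines elimination over the tree; exponential-Euler gates; exact linear
#' calcium pools).  Somatic injection and recording.
#'
#' @param cell a `cell_model` from [assemble()].
#' @param stim a [stimulus()].
#' @param dt time step (ms).
#' @param sample_dt output sampling interval (ms); defaults to `dt`.
#' @param init_state optional state list (from a previous trace's
#'   `attr(, "state")`) to continue from; otherwise gates start at steady
#'   state for `v_init`.
#' @param record_currents record per-channel somatic currents (nA).
#' @param v_clamp if finite, hold all compartments at this voltage and let
#'   gates/calcium evolve (voltage-clamp mode, used for kinetics checks).
#' @param record_gates record somatic gate variables.
#' @param record_comp compartment index to record from (default: soma).
#' @return A `trace` tibble (`time_ms`, `v_mV`) with the stimulus, solver
#'   settings, pharmacology and final state in attributes.
#' @export
integrate_cell <- function(cell, stim, dt = 0.025, sample_dt = NULL,
                           init_state = NULL, record_currents = FALSE,
                           v_clamp = NA_real_, record_gates = FALSE,
                           record_comp = NULL) {
  stopifnot(inherits(cell, "cell_model"), inherits(stim, "stimulus"), dt > 0)
  if (is.null(sample_dt)) sample_dt <- dt
  core <- cell$core
  core$gbar <- effective_gbar(cell)
  soma_comp <- which(cell$comps$region == "soma")[1]
  if (is.null(record_comp)) record_comp <- soma_comp
  st <- list(inj_comp = soma_comp - 1L, bias_pA = stim$bias_pA,
             step_pA = stim$step_pA, onset_ms = stim$onset_ms,
             dur_ms = stim$dur_ms, total_ms = stim$total_ms,
             record_comp = record_comp - 1L)
  res <- cable_integrate_cpp(core, st, dt, sample_dt, init_state,
                             record_currents, v_clamp, record_gates)
  tr <- tibble::tibble(time_ms = as.numeric(res$t), v_mV = as.numeric(res$v))
  attr(tr, "stimulus") <- stim
  attr(tr, "dt") <- dt
  attr(tr, "sample_dt") <- sample_dt
  attr(tr, "pharmacology") <- cell$pharmacology
  attr(tr, "state") <- res$state
  if (record_currents) {
    cur <- res$currents; colnames(cur) <- cell$chan_names
    attr(tr, "currents") <- cur
  }
  if (record_gates) {
    g <- res$gates; colnames(g) <- cell$gate_names
    attr(tr, "gates") <- g
  }
  class(tr) <- c("trace", class(tr))
  tr
}

#' Settle the cell to its (possibly biased) steady state
#'
#' Runs the model without a step for `duration_ms` and caches the final
#' state; used as the discarded pre-roll before every protocol.
#'
#' @param cell a `cell_model`.
#' @param bias_pA holding current during settling.
#' @param duration_ms settling time (ms).
#' @param dt time step (ms).
#' @param from_rest reuse the cell's cached zero-bias resting state as the
#'   starting point (faster convergence for holding-current searches).
#' @return List with `state` (to pass as `init_state`) and `v_end` (mV).
#' @export
settle <- function(cell, bias_pA = 0, duration_ms = 2000, dt = 0.025,
                   from_rest = TRUE) {
  init <- if (from_rest && !is.null(cell$rest)) cell$rest$state else NULL
  tr <- integrate_cell(cell, stimulus(bias_pA = bias_pA,
                                      total_ms = duration_ms),
                       dt = dt, sample_dt = min(duration_ms, 5), init_state = init)
  list(state = attr(tr, "state"), v_end = tr$v_mV[nrow(tr)])
}

#' Cache the cell's resting state
#'
#' @param cell a `cell_model`.
#' @param duration_ms settling time (ms).
#' @param dt time step (ms).
#' @return The cell with `$rest` set (`state`, `vrest_mV`).
#' @export
cache_rest <- function(cell, duration_ms = 2000, dt = 0.025) {
  s <- settle(cell, bias_pA = 0, duration_ms = duration_ms, dt = dt,
              from_rest = FALSE)
  # continue once more from the settled state for a tighter steady state
  s2 <- settle_from(cell, s$state, bias_pA = 0, duration_ms = 500, dt = dt)
  cell$rest <- list(state = s2$state, vrest_mV = s2$v_end)
  cell
}

settle_from <- function(cell, state, bias_pA = 0, duration_ms = 500, dt = 0.025) {
  tr <- integrate_cell(cell, stimulus(bias_pA = bias_pA, total_ms = duration_ms),
                       dt = dt, sample_dt = min(duration_ms, 5),
                       init_state = state)
  list(state = attr(tr, "state"), v_end = tr$v_mV[nrow(tr)])
}

#' Resting membrane potential of the model
#'
#' @param cell a `cell_model`.
#' @param duration_ms settling time (ms).
#' @param dt time step (ms).
#' @return Somatic steady-state voltage (mV) with no injected current.
#' @export
model_vrest <- function(cell, duration_ms = 3000, dt = 0.025) {
  settle(cell, bias_pA = 0, duration_ms = duration_ms, dt = dt,
         from_rest = TRUE)$v_end
}

#' Find the bias current holding the soma at a target voltage
#'
#' Bracketing + bisection on the steady-state somatic voltage.
#'
#' @param cell a `cell_model` (ideally with [cache_rest()] applied).
#' @param v_target target voltage (mV), within (-90, -40).
#' @param tol_mV acceptable steady-state deviation (mV).
#' @param settle_ms settling time per trial (ms).
#' @param dt time step (ms).
#' @param bracket_pA search limits (pA).
#' @return Holding current (pA).
#' @export
find_holding_current <- function(cell, v_target, tol_mV = 0.5,
                                 settle_ms = 1500, dt = 0.025,
                                 bracket_pA = c(-500, 500)) {
  stopifnot(v_target >= -90, v_target <= -40)
  if (is.null(cell$rest)) cell <- cache_rest(cell, dt = dt)
  vrest <- cell$rest$vrest_mV
  f <- function(i_pA) settle(cell, bias_pA = i_pA, duration_ms = settle_ms,
                             dt = dt)$v_end - v_target
  if (abs(vrest - v_target) <= tol_mV) return(0)
  # secant iteration on the (nearly linear) steady-state I-V relation,
  # seeded from a generic input-resistance guess
  rin_guess <- 200  # MOhm
  i_prev <- 0; v_prev <- vrest - v_target
  i_cur <- min(max((v_target - vrest) / rin_guess * 1e3,
                   bracket_pA[1]), bracket_pA[2])
  for (k in 1:12) {
    v_cur <- f(i_cur)
    if (abs(v_cur) <= tol_mV * 0.8) return(i_cur)
    slope <- (v_cur - v_prev) / (i_cur - i_prev)   # mV per pA
    if (!is.finite(slope) || slope <= 1e-5) slope <- 1e3 / rin_guess
    i_next <- i_cur - v_cur / slope
    # damp large extrapolations
    if (abs(i_next - i_cur) > 200) i_next <- i_cur + sign(i_next - i_cur) * 200
    i_next <- min(max(i_next, bracket_pA[1]), bracket_pA[2])
    if (abs(i_next - i_cur) < 0.05) return(i_next)
    i_prev <- i_cur; v_prev <- v_cur; i_cur <- i_next
  }
  if (abs(f(i_cur)) <= tol_mV) return(i_cur)
  stop("holding-current target unreachable within bracket", call. = FALSE)
}

#' Calibrate the surrogate model to the target passive properties
#'
#' Adjusts the surrogate's free knobs — dendritic stem diameter (input
#' resistance), specific membrane resistance (time constant) and leak
#' reversal (resting potential) — by damped fixed-point iteration until the
#' four measured passive properties (input resistance from the -10 pA /
#' 100 ms pulse, slowest double-exponential time constant from the -1 nA /
#' 0.5 ms pulse, capacitance = tau/Rin, and resting potential) are within
#' tolerance of the targets.  All measurements use the same virtual
#' protocols as the analysis pipeline.
#'
#' @param targets list with `rin_Mohm`, `tau_ms`, `c_pF`, `vrest_mV`.
#' @param config starting [surrogate_config()].
#' @param pas starting [passive_params()].
#' @param dist a [distribution_table()].
#' @param catalogue a [kinetics_catalogue()].
#' @param tol relative tolerances: `rin` (default 0.02), `tau` (0.03) and
#'   absolute `vrest` (mV, default 0.3).
#' @param max_iter iteration limit.
#' @param dt integration step (ms).
#' @param adjust_rm also move the specific membrane resistance (default
#'   TRUE); geometry-only calibration otherwise.
#' @return List: `cell` (calibrated, rest state cached), `config`, `pas`,
#'   `measured` (rin/tau/c/vrest), `iterations`, `converged`.
#' @export
calibrate_passive <- function(targets = list(rin_Mohm = 218.2, tau_ms = 19.1,
                                             c_pF = 87.4, vrest_mV = -77.3),
                              config = surrogate_config(),
                              pas = passive_params(),
                              dist = distribution_table(),
                              catalogue = kinetics_catalogue(),
                              tol = list(rin = 0.015, tau = 0.025, vrest = 0.25),
                              max_iter = 12, dt = 0.025,
                              adjust_rm = TRUE) {
  measure <- function(cell) {
    cell <- cache_rest(cell, dt = dt)
    pp <- run_passive(cell, dt = dt)
    rin <- input_resistance(pp$rin_trace)
    tau <- estimate_tau(pp$tau_trace, method = "double_exp")
    list(cell = cell, rin = rin, tau = tau, c_pF = capacitance(tau, rin),
         vrest = cell$rest$vrest_mV)
  }
  cfg <- config; p <- pas
  history <- list()
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cell <- assemble(build_surrogate(cfg), dist = dist, pas = p,
                     catalogue = catalogue)
    mm <- measure(cell)
    history[[it]] <- c(stem = cfg$stem_diameter, rm = p$rm_kohm_cm2,
                       e_pas = p$e_pas_mV, rin = mm$rin, tau = mm$tau,
                       vrest = mm$vrest)
    ok_rin <- abs(mm$rin / targets$rin_Mohm - 1) <= tol$rin
    ok_tau <- abs(mm$tau / targets$tau_ms - 1) <= tol$tau
    ok_v <- abs(mm$vrest - targets$vrest_mV) <= tol$vrest
    if (ok_rin && ok_tau && ok_v) { converged <- TRUE; cell <- mm$cell; break }
    # damped, largely decoupled updates:
    # capacitance mismatch -> dendritic area (stem diameter)
    c_target <- targets$tau_ms / targets$rin_Mohm
    cfg$stem_diameter <- min(max(
      cfg$stem_diameter * (c_target / (mm$tau / mm$rin))^0.9, 1.2), 7)
    # input-conductance mismatch -> leak density (rm)
    if (adjust_rm) {
      area <- total_area(cell$morphology) * 1e-8              # cm^2
      g_leak <- area / (p$rm_kohm_cm2 * 1e3) * 1e9            # nS
      delta <- (1e3 / mm$rin - 1e3 / targets$rin_Mohm)        # nS surplus
      g_new <- max(g_leak - 0.9 * delta, 0.02)
      p$rm_kohm_cm2 <- min(max(area / (g_new * 1e-9) / 1e3, 5), 2000)
    }
    # resting-potential mismatch -> leak reversal, scaled by the ratio of
    # total to leak conductance (the steady-state gain of e_pas on vrest)
    area <- total_area(cell$morphology) * 1e-8
    g_leak <- area / (p$rm_kohm_cm2 * 1e3) * 1e9
    gain <- max(g_leak / (1e3 / mm$rin), 1e-3)
    p$e_pas_mV <- min(max(p$e_pas_mV +
                            (targets$vrest_mV - mm$vrest) / gain * 0.7,
                          -110), -40)
    cell <- mm$cell
  }
  if (!converged) {
    cell <- assemble(build_surrogate(cfg), dist = dist, pas = p,
                     catalogue = catalogue)
    mm <- measure(cell)
    cell <- mm$cell
  }
  structure(list(cell = cell, config = cfg, pas = p,
                 measured = list(rin_Mohm = mm$rin, tau_ms = mm$tau,
                                 c_pF = mm$c_pF, vrest_mV = mm$vrest),
                 targets = targets, iterations = length(history),
                 history = dplyr::bind_rows(lapply(history, as.list)),
                 converged = converged),
            class = "passive_calibration")
}

#' @export
print.passive_calibration <- function(x, ...) {
  cat(sprintf(paste0("<passive_calibration: %s after %d iterations>\n",
                     "  Rin %.1f MOhm (target %.1f)  tau %.2f ms (%.1f)\n",
                     "  C %.1f pF (%.1f)  Vrest %.2f mV (%.1f)\n"),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$measured$rin_Mohm, x$targets$rin_Mohm,
              x$measured$tau_ms, x$targets$tau_ms,
              x$measured$c_pF, x$targets$c_pF,
              x$measured$vrest_mV, x$targets$vrest_mV))
  invisible(x)
}

#' @export
tidy.passive_calibration <- function(x, ...) {
  tibble::tibble(
    property = c("rin_Mohm", "tau_ms", "c_pF", "vrest_mV"),
    estimate = unlist(x$measured, use.names = FALSE),
    target = unlist(x$targets, use.names = FALSE))
}

#' @export
glance.passive_calibration <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 stem_diameter_um = x$config$stem_diameter,
                 rm_kohm_cm2 = x$pas$rm_kohm_cm2,
                 e_pas_mV = x$pas$e_pas_mV)
}
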