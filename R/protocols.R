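#' Run one current-clamp step from a settled state
#'
#' Settles the cell under the bias for `pre_ms` (discarded pre-roll), then
#' records a trace containing the step plus a post-step window.
#'
#' @param cell a `cell_model`.
#' @param bias_pA holding current (pA), on throughout.
#' @param step_pA step amplitude added on top of the bias (pA).
#' @param dur_ms step duration (ms).
#' @param post_ms observation window after the step (ms).
#' @param onset_ms step onset within the recorded trace (ms).
#' @param pre_ms settling pre-roll (ms), discarded.
#' @param dt,sample_dt solver and output steps (ms).
#' @return A `trace`; `attr(. , "hold")` carries the bias and the
#'   end-of-settle voltage.
#' @export
run_step <- function(cell, bias_pA = 0, step_pA = 0, dur_ms = 1000,
                     post_ms = 200, onset_ms = 200, pre_ms = 2000,
                     dt = 0.025, sample_dt = 0.025) {
  s <- settle(cell, bias_pA = bias_pA, duration_ms = pre_ms, dt = dt)
  st <- stimulus(bias_pA = bias_pA, step_pA = step_pA, onset_ms = onset_ms,
                 dur_ms = dur_ms, total_ms = onset_ms + dur_ms + post_ms)
  tr <- integrate_cell(cell, st, dt = dt, sample_dt = sample_dt,
                       init_state = s$state)
  attr(tr, "hold") <- list(bias_pA = bias_pA, v_pre_mV = s$v_end)
  tr
}

#' F-I protocol: depolarizing steps from a holding potential
#'
#' Two-second depolarizing steps on top of a bias current that holds the
#' soma near `hold_target_mV` (-64 mV by default, deep enough to
#' inactivate the T-type calcium current), one trace per amplitude.
#'
#' @param cell a `cell_model`.
#' @param amplitudes_pA depolarizing step amplitudes (pA); default 30-360
#'   in 30 pA increments.
#' @param hold_target_mV holding potential; `NULL` for no bias.
#' @param dur_ms step duration (ms).
#' @param dt,sample_dt solver and output steps (ms).
#' @param pre_ms settling pre-roll (ms).
#' @param hold_pA optional pre-computed bias current (skips the search).
#' @return Tibble: `step_pA`, `hold_pA`, `trace` (list-column of traces).
#' @export
run_fi <- function(cell, amplitudes_pA = seq(30, 360, by = 30),
                   hold_target_mV = -64, dur_ms = 2000, dt = 0.025,
                   sample_dt = 0.025, pre_ms = 2000, hold_pA = NULL) {
  stopifnot(all(amplitudes_pA > 0))
  if (!length(amplitudes_pA))
    return(tibble::tibble(step_pA = numeric(), hold_pA = numeric(),
                          trace = list()))
  if (is.null(hold_pA))
    hold_pA <- if (is.null(hold_target_mV)) 0 else
      find_holding_current(cell, hold_target_mV, dt = dt)
  traces <- purrr::map(amplitudes_pA, function(a)
    tryCatch(run_step(cell, bias_pA = hold_pA, step_pA = a, dur_ms = dur_ms,
                      post_ms = 100, pre_ms = pre_ms, dt = dt,
                      sample_dt = sample_dt),
             error = function(e) structure(list(message = conditionMessage(e)),
                                           class = "trace_error")))
  tibble::tibble(step_pA = amplitudes_pA, hold_pA = hold_pA, trace = traces)
}

#' Rebound protocol: hyperpolarizing steps of graded duration
#'
#' -100 pA steps of 200/500/2000 ms from a bias holding the soma near
#' -71 mV, each trace with a post-step window for rebound-burst analysis.
#'
#' @param cell a `cell_model`.
#' @param amplitude_pA step amplitude (pA, negative).
#' @param durations_ms step durations (ms).
#' @param hold_target_mV holding potential.
#' @param post_ms post-step window (>= 500 ms).
#' @param dt,sample_dt solver and output steps (ms).
#' @param hold_pA optional pre-computed bias current.
#' @param pre_ms settling pre-roll (ms).
#' @return Tibble: `duration_ms`, `hold_pA`, `trace` (list-column).
#' @export
run_rebound <- function(cell, amplitude_pA = -100,
                        durations_ms = c(200, 500, 2000),
                        hold_target_mV = -71, post_ms = 1000, dt = 0.025,
                        sample_dt = 0.025, hold_pA = NULL, pre_ms = 2000) {
  stopifnot(amplitude_pA < 0)
  if (is.null(hold_pA))
    hold_pA <- find_holding_current(cell, hold_target_mV, dt = dt)
  traces <- purrr::map(durations_ms, function(d)
    run_step(cell, bias_pA = hold_pA, step_pA = amplitude_pA, dur_ms = d,
             post_ms = post_ms, dt = dt, sample_dt = sample_dt,
             pre_ms = pre_ms))
  tibble::tibble(duration_ms = durations_ms, hold_pA = hold_pA,
                 trace = traces)
}

#' Sag protocol: hyperpolarizing steps from rest
#'
#' Two-second steps of increasing magnitude with no holding current.
#'
#' @param cell a `cell_model`.
#' @param amplitudes_pA step amplitudes (pA, negative).
#' @param dur_ms step duration (ms).
#' @param dt,sample_dt solver and output steps (ms).
#' @param pre_ms settling pre-roll (ms).
#' @return Tibble: `step_pA`, `trace` (list-column).
#' @export
run_sag <- function(cell, amplitudes_pA = c(-50, -100, -150, -200),
                    dur_ms = 2000, dt = 0.025, sample_dt = 0.025,
                    pre_ms = 2000) {
  stopifnot(all(amplitudes_pA < 0))
  traces <- purrr::map(amplitudes_pA, function(a)
    run_step(cell, bias_pA = 0, step_pA = a, dur_ms = dur_ms, post_ms = 200,
             dt = dt, sample_dt = sample_dt, pre_ms = pre_ms))
  tibble::tibble(step_pA = amplitudes_pA, trace = traces)
}

#' Passive-property protocols
#'
#' The fixed pulses used for the passive estimates: -10 pA for 100 ms
#' (input resistance) and -1 nA for 0.5 ms (membrane time constant, finely
#' sampled).
#'
#' @param cell a `cell_model`.
#' @param dt solver step (ms).
#' @return List with `rin_trace` and `tau_trace`.
#' @export
run_passive <- function(cell, dt = 0.025) {
  rin_trace <- run_step(cell, bias_pA = 0, step_pA = -10, dur_ms = 100,
                        post_ms = 50, onset_ms = 200, pre_ms = 1000,
                        dt = dt, sample_dt = 0.05)
  tau_trace <- run_step(cell, bias_pA = 0, step_pA = -1000, dur_ms = 0.5,
                        post_ms = 250, onset_ms = 50, pre_ms = 1000,
                        dt = dt, sample_dt = 0.025)
  list(rin_trace = rin_trace, tau_trace = tau_trace)
}
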