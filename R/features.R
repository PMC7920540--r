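trace_stim <- function(trace) {
  st <- attr(trace, "stimulus")
  if (is.null(st)) stop("trace carries no stimulus metadata", call. = FALSE)
  st
}

trace_dt <- function(trace) {
  dt <- diff(trace$time_ms)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("trace is not uniformly sampled; resample first", call. = FALSE)
  dt[1]
}

baseline_of <- function(trace, onset_ms, window_ms = 100) {
  i <- trace$time_ms >= max(0, onset_ms - window_ms) & trace$time_ms < onset_ms
  if (!any(i)) trace$v_mV[1] else mean(trace$v_mV[i])
}

#' Detect action potentials by the dV/dt criterion
#'
#' A spike is an upward crossing of the dV/dt threshold followed by a
#' voltage peak above -10 mV within 5 ms; the threshold voltage is the
#' membrane potential at the crossing sample.  Events closer than 2 ms are
#' merged.
#'
#' @param trace a `trace` (uniformly sampled at <= 0.05 ms for
#'   analysis-grade results).
#' @param dvdt_threshold threshold slope, mV/ms.
#' @param peak_min_mV minimal peak voltage to accept a spike.
#' @param peak_window_ms window after the crossing in which the peak must
#'   occur.
#' @param refractory_ms merge window.
#' @return A `spike_train` tibble (`spike_time_ms`, `threshold_mV`).
#' @export
detect_spikes <- function(trace, dvdt_threshold = 10, peak_min_mV = -10,
                          peak_window_ms = 5, refractory_ms = 2) {
  dt <- trace_dt(trace)
  v <- trace$v_mV
  dvdt <- c(NA, diff(v) / dt)
  up <- which(dvdt >= dvdt_threshold & dplyr::lag(dvdt) < dvdt_threshold)
  up <- up[!is.na(up)]
  times <- thr <- numeric(0)
  last <- -Inf
  nwin <- max(1L, round(peak_window_ms / dt))
  for (i in up) {
    t_i <- trace$time_ms[i]
    if (t_i - last < refractory_ms) next
    peak <- max(v[i:min(length(v), i + nwin)])
    if (peak > peak_min_mV) {
      times <- c(times, t_i)
      thr <- c(thr, v[i - 1L])
      last <- t_i
    }
  }
  out <- tibble::tibble(spike_time_ms = times, threshold_mV = thr)
  attr(out, "dvdt_threshold") <- dvdt_threshold
  class(out) <- c("spike_train", class(out))
  out
}

#' Firing rate within a current step
#'
#' Spikes in the first `onset_exclusion` ms of the step are excluded, and
#' the rate is the remaining count divided by the remaining step time.
#'
#' @param spikes a [detect_spikes()] result.
#' @param step_onset,step_duration step timing (ms).
#' @param onset_exclusion initial exclusion window (ms).
#' @return Firing rate in Hz.
#' @export
firing_rate <- function(spikes, step_onset, step_duration,
                        onset_exclusion = 50) {
  stopifnot(step_duration > onset_exclusion)
  n <- sum(spikes$spike_time_ms >= step_onset + onset_exclusion &
             spikes$spike_time_ms <= step_onset + step_duration)
  n / (step_duration - onset_exclusion) * 1000
}

#' Fit a Boltzmann sigmoid to an F-I curve
#'
#' Least-squares fit of `rate(I) = fmax / (1 + exp((i_half - I)/k))` to the
#' (current, rate) points.
#'
#' @param fi tibble with columns `current_pA`, `rate_Hz` (>= 4 points).
#' @return An `fi_fit` object (access with [tidy()]/[glance()]), or an
#'   object with `converged = FALSE` when the data are degenerate
#'   (e.g. all-zero rates).
#' @export
fit_fi_boltzmann <- function(fi) {
  stopifnot(all(c("current_pA", "rate_Hz") %in% names(fi)))
  if (nrow(fi) < 4) stop("need at least 4 F-I points", call. = FALSE)
  out <- list(data = tibble::as_tibble(fi), converged = FALSE,
              fmax = NA_real_, i_half = NA_real_, k = NA_real_,
              sigma = NA_real_)
  class(out) <- "fi_fit"
  if (all(fi$rate_Hz == 0)) return(out)
  fmax0 <- max(fi$rate_Hz) * 1.1
  ih0 <- fi$current_pA[which.min(abs(fi$rate_Hz - fmax0 / 2))]
  k0 <- diff(range(fi$current_pA)) / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(rate_Hz ~ fmax / (1 + exp((i_half - current_pA) / k)),
                      data = fi,
                      start = list(fmax = fmax0, i_half = ih0, k = k0),
                      lower = c(fmax = 1e-3, i_half = -Inf, k = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  out$converged <- TRUE
  out$fmax <- unname(cf["fmax"]); out$i_half <- unname(cf["i_half"])
  out$k <- unname(cf["k"])
  out$sigma <- sqrt(mean(stats::resid(fit)^2))
  out$fit <- fit
  out
}

#' @export
print.fi_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<fi_fit: fmax %.1f Hz, I_half %.1f pA, k %.1f pA, rms %.2f Hz>\n",
                x$fmax, x$i_half, x$k, x$sigma))
  else cat("<fi_fit: not converged>\n")
  invisible(x)
}

#' @export
tidy.fi_fit <- function(x, ...) {
  tibble::tibble(term = c("fmax", "i_half", "k"),
                 estimate = c(x$fmax, x$i_half, x$k))
}

#' @export
glance.fi_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, sigma = x$sigma,
                 n = nrow(x$data))
}

#' Rheobase from an F-I curve
#'
#' Default method inverts the fitted Boltzmann at the target rate,
#' `I = i_half - k log(fmax/target - 1)`.  The `"linear"` method instead
#' interpolates the raw points linearly at the first crossing of the
#' target rate.
#'
#' @param fit an `fi_fit` (for `"boltzmann"`) or a tibble of raw points
#'   (accepted by `"linear"`).
#' @param target_rate_Hz criterion rate (3 Hz by convention; 10 Hz also
#'   used).
#' @param method `"boltzmann"` or `"linear"`.
#' @return Current in pA, or `NA` (with a warning) when the target rate is
#'   not attainable.
#' @export
rheobase <- function(fit, target_rate_Hz = 3,
                     method = c("boltzmann", "linear")) {
  method <- match.arg(method)
  if (method == "boltzmann") {
    stopifnot(inherits(fit, "fi_fit"))
    if (!fit$converged) return(NA_real_)
    if (target_rate_Hz >= fit$fmax) {
      warning("target rate is at or above the fitted maximum; rheobase undefined")
      return(NA_real_)
    }
    fit$i_half - fit$k * log(fit$fmax / target_rate_Hz - 1)
  } else {
    pts <- if (inherits(fit, "fi_fit")) fit$data else tibble::as_tibble(fit)
    pts <- pts[order(pts$current_pA), ]
    above <- which(pts$rate_Hz >= target_rate_Hz)
    if (!length(above)) return(NA_real_)
    i2 <- above[1]
    if (i2 == 1) return(pts$current_pA[1])
    i1 <- i2 - 1
    stats::approx(pts$rate_Hz[c(i1, i2)], pts$current_pA[c(i1, i2)],
                  xout = target_rate_Hz, ties = "ordered")$y
  }
}

#' Sag percentage of a hyperpolarizing step response
#'
#' `sag% = 100 (1 - V_ss / V_peak)` where both are deflections from the
#' pre-step baseline: `V_peak` the peak negative deflection during the
#' step, `V_ss` the deflection at `ss_at_ms` (2000 ms) after onset.
#'
#' @param trace a hyperpolarizing-step `trace` (step of >= 2000 ms).
#' @param baseline_window_ms pre-onset baseline window (ms).
#' @param ss_at_ms time after onset at which the steady state is read (ms).
#' @return A `sag_measure` tibble row: `baseline_mV`, `v_peak_mV`,
#'   `v_ss_mV` (deflections, positive down) and `sag_percent`.
#' @export
sag_percent <- function(trace, baseline_window_ms = 100, ss_at_ms = 2000) {
  st <- trace_stim(trace)
  if (st$step_pA >= 0)
    stop("sag analysis requires a hyperpolarizing step", call. = FALSE)
  if (st$dur_ms < ss_at_ms - 1e-9)
    stop("sag analysis requires a step of at least ", ss_at_ms, " ms",
         call. = FALSE)
  base <- baseline_of(trace, st$onset_ms, baseline_window_ms)
  in_step <- trace$time_ms > st$onset_ms &
    trace$time_ms <= st$onset_ms + st$dur_ms
  v_peak <- base - min(trace$v_mV[in_step])
  i_ss <- which.min(abs(trace$time_ms - (st$onset_ms + ss_at_ms)))
  v_ss <- base - trace$v_mV[i_ss]
  sagp <- if (v_peak == 0) 0 else 100 * (1 - v_ss / v_peak)
  out <- tibble::tibble(baseline_mV = base, v_peak_mV = v_peak,
                        v_ss_mV = v_ss, sag_percent = sagp)
  class(out) <- c("sag_measure", class(out))
  out
}

#' Classify a sag measurement
#'
#' Neurons with sag strictly above the cutoff (default 15%) count as
#' sag-expressing.
#'
#' @param sag a [sag_percent()] result (or a bare percentage).
#' @param cutoff_percent classification threshold.
#' @return `"sag_expressing"` or `"no_sag"`.
#' @export
classify_sag <- function(sag, cutoff_percent = 15) {
  s <- if (is.numeric(sag)) sag else sag$sag_percent
  ifelse(s > cutoff_percent, "sag_expressing", "no_sag")
}

#' Rebound-burst metrics of a hyperpolarizing step response
#'
#' Measures the hyperpolarization reached at the end of the step (relative
#' to the pre-step baseline), counts spikes in the post-step window, and
#' bins the trace by end-of-step hyperpolarization (0-20, 20-40,
#' 40-60 mV).
#'
#' @param trace a hyperpolarizing-step `trace` with a post-step window.
#' @param window_ms post-offset spike-count window (ms).
#' @param dvdt_threshold spike criterion passed to [detect_spikes()].
#' @return Tibble row: `end_hyperpolarization_mV`, `rebound_spike_count`,
#'   `bin`.
#' @export
rebound_metrics <- function(trace, window_ms = 500, dvdt_threshold = 10) {
  st <- trace_stim(trace)
  if (st$step_pA >= 0)
    stop("rebound analysis requires a hyperpolarizing step", call. = FALSE)
  base <- baseline_of(trace, st$onset_ms)
  t_end <- st$onset_ms + st$dur_ms
  i_end <- which.min(abs(trace$time_ms - t_end))
  hyp <- base - trace$v_mV[i_end]
  spikes <- detect_spikes(trace, dvdt_threshold = dvdt_threshold)
  n <- sum(spikes$spike_time_ms > t_end &
             spikes$spike_time_ms <= t_end + window_ms)
  bin <- cut(hyp, breaks = c(0, 20, 40, 60, Inf),
             labels = c("0-20", "20-40", "40-60", ">60"), right = FALSE)
  tibble::tibble(end_hyperpolarization_mV = hyp, rebound_spike_count = n,
                 bin = as.character(bin))
}

#' Membrane time constant from the brief-pulse response
#'
#' Two estimators of the decay after the -1 nA / 0.5 ms charging pulse:
#' `"decay33"` returns the raw elapsed time for the deflection to fall to
#' 33% of its peak (for a single exponential this is `tau * log(1/0.33)`,
#' not tau itself); `"double_exp"` fits `a exp(-t/tau1) + c exp(-t/tau2)`
#' to the decay phase and returns the slowest time constant.
#'
#' @param trace the tau-pulse `trace` (fine sampling, <= 0.025 ms).
#' @param method `"double_exp"` (default) or `"decay33"`.
#' @param fit_window_ms length of decay fitted (ms).
#' @return Time constant estimate (ms) with the method in the
#'   `"method"` attribute.
#' @export
estimate_tau <- function(trace, method = c("double_exp", "decay33"),
                         fit_window_ms = 120) {
  method <- match.arg(method)
  st <- trace_stim(trace)
  base <- baseline_of(trace, st$onset_ms, 20)
  t_end <- st$onset_ms + st$dur_ms
  after <- trace$time_ms >= t_end
  tt <- trace$time_ms[after]; vv <- trace$v_mV[after]
  defl <- base - vv   # positive for hyperpolarizing pulse
  ipk <- which.max(defl)
  if (defl[ipk] <= 1e-6)
    stop("no voltage deflection found; tau estimation failed", call. = FALSE)
  t0 <- tt[ipk]
  d <- defl[ipk:length(defl)]; td <- tt[ipk:length(tt)] - t0
  keep <- td <= fit_window_ms
  d <- d[keep]; td <- td[keep]
  if (method == "decay33") {
    cross <- which(d <= 0.33 * d[1])
    if (!length(cross))
      stop("deflection never decays to 33% within the trace", call. = FALSE)
    out <- td[cross[1]]
  } else {
    # restrict to the monotone decay phase (active currents can produce a
    # small late undershoot below baseline)
    zero <- which(d <= 0)
    if (length(zero) > 1) { keep2 <- seq_len(zero[1] - 1); d <- d[keep2]; td <- td[keep2] }
    # seed the slow component from a log-linear fit to the tail
    tail_i <- td >= max(td) * 0.3 & d > 0
    tau_slow0 <- if (sum(tail_i) > 5) {
      sl <- stats::coef(stats::lm(log(d[tail_i]) ~ td[tail_i]))[2]
      if (is.finite(sl) && sl < 0) -1 / sl else 20
    } else 20
    tau_slow0 <- min(max(tau_slow0, 1), 200)
    fit <- NULL
    for (start in list(list(a = d[1] * 0.7, tau1 = tau_slow0,
                            c0 = d[1] * 0.3, tau2 = tau_slow0 / 8),
                       list(a = d[1] * 0.5, tau1 = 20, c0 = d[1] * 0.5,
                            tau2 = 2))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(d ~ a * exp(-td / tau1) + c0 * exp(-td / tau2),
                          data = data.frame(d = d, td = td),
                          start = start,
                          lower = c(a = 0, tau1 = 0.05, c0 = 0, tau2 = 0.01),
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      # single-exponential fallback, tagged
      fit1 <- tryCatch(
        minpack.lm::nlsLM(d ~ a * exp(-td / tau1),
                          data = data.frame(d = d, td = td),
                          start = list(a = d[1], tau1 = tau_slow0),
                          lower = c(a = 0, tau1 = 0.05)),
        error = function(e) NULL)
      if (is.null(fit1))
        stop("double-exponential fit failed", call. = FALSE)
      out <- unname(stats::coef(fit1)["tau1"])
      attr(out, "method") <- "single_exp_fallback"
      return(out)
    }
    cf <- stats::coef(fit)
    out <- max(cf["tau1"], cf["tau2"])
    names(out) <- NULL
  }
  attr(out, "method") <- method
  out
}

#' Input resistance from the -10 pA / 100 ms pulse
#'
#' `Rin = deflection at 100 ms / injected current`.
#'
#' @param trace the Rin-pulse `trace`.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(trace) {
  st <- trace_stim(trace)
  if (st$step_pA == 0) stop("zero-amplitude pulse; Rin undefined", call. = FALSE)
  base <- baseline_of(trace, st$onset_ms)
  i_meas <- which.min(abs(trace$time_ms - (st$onset_ms + st$dur_ms)))
  defl <- trace$v_mV[i_meas] - base                 # mV
  defl / st$step_pA * 1e3                           # MOhm
}

#' Cell capacitance from tau and Rin
#'
#' @param tau_ms membrane time constant (ms).
#' @param rin_Mohm input resistance (MOhm).
#' @return Capacitance in pF (`tau/Rin`); 0 with a warning for degenerate
#'   `tau = 0`.
#' @export
capacitance <- function(tau_ms, rin_Mohm) {
  stopifnot(rin_Mohm > 0, tau_ms >= 0)
  if (tau_ms == 0) { warning("tau = 0: degenerate capacitance"); return(0) }
  tau_ms / rin_Mohm * 1e3   # ms/MOhm = nF -> pF via 1e3
}

#' Spike threshold of the first action potential
#'
#' Convenience accessor: threshold voltage (dV/dt criterion) of the first
#' spike in a trace.
#'
#' @param trace a `trace`.
#' @param dvdt_threshold criterion slope (mV/ms).
#' @return Threshold (mV) or `NA` if the trace has no spikes.
#' @export
spike_threshold <- function(trace, dvdt_threshold = 10) {
  sp <- detect_spikes(trace, dvdt_threshold = dvdt_threshold)
  if (!nrow(sp)) NA_real_ else sp$threshold_mV[1]
}
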