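# shared fixtures: cheap cells and a memoised calibrated template
.thalamod_test_cache <- new.env(parent = emptyenv())

# soma-only (optionally passive) cell; fast enough for solver unit tests
tiny_cell <- function(passive = TRUE, soma_area = 2000) {
  secs <- tibble::tibble(
    id = 1L, region = "soma", parent_id = NA_integer_,
    length_um = sqrt(soma_area / pi), diam_um = sqrt(soma_area / pi),
    branch_order = 0L, path_dist_um = 0)
  m <- morphology(secs, soma_area_um2 = soma_area)
  dist <- distribution_table()
  if (passive) dist[, -1] <- 0
  assemble(m, dist = dist)
}

# soma + one dendritic section, passive; for the two-compartment oracle
two_comp_cell <- function(dend_len = 100, dend_diam = 2) {
  secs <- tibble::tibble(
    id = c(1L, 2L), region = c("soma", "dend"),
    parent_id = c(NA_integer_, 1L),
    length_um = c(sqrt(293 / pi), dend_len),
    diam_um = c(sqrt(293 / pi), dend_diam),
    branch_order = c(0L, 1L),
    path_dist_um = c(0, dend_len / 2))
  m <- morphology(secs)
  dist <- distribution_table()
  dist[, -1] <- 0
  assemble(m, dist = dist, max_seg_length = dend_len)  # one comp per section
}

# small active surrogate (2 stems, order 2) for protocol plumbing tests
small_active_cell <- function(...) {
  cfg <- surrogate_config(n_stems = 2L, max_branch_order = 2L)
  assemble(build_surrogate(cfg), ...)
}

# the calibrated default model, built once per test session
calibrated_template <- function() {
  if (is.null(.thalamod_test_cache$cal))
    .thalamod_test_cache$cal <- calibrate_passive()
  .thalamod_test_cache$cal
}

# synthetic trace helper: make a `trace` from vectors + stimulus metadata
make_trace <- function(time_ms, v_mV, stim) {
  tr <- tibble::tibble(time_ms = time_ms, v_mV = v_mV)
  attr(tr, "stimulus") <- stim
  class(tr) <- c("trace", class(tr))
  tr
}

# stereotyped spike waveform rising faster than 10 mV/ms, peaking at +20 mV
inject_spikes <- function(time_ms, v_base, spike_times) {
  v <- rep(v_base, length(time_ms))
  for (t0 in spike_times) {
    shape <- 90 * exp(-((time_ms - t0 - 1) / 0.6)^2)  # ~1 ms wide gaussian
    v <- v + shape
  }
  v
}
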