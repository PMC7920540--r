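#' Configuration of a synthetic cohort
#'
#' Describes a population of model cells derived from a calibrated
#' template: per-cell, per-channel log-normal density variability (median
#' 1, given CV), then the condition scalings — `control` leaves the
#' channels untouched, `lesioned` removes the M-current (`km_scale = 0`)
#' and scales up the H-current (`ih_scale = 2` by default; 3 is the
#' stronger published variant).
#'
#' @param n_cells cells per cohort.
#' @param condition `"control"` or `"lesioned"`.
#' @param km_scale,ih_scale condition scalings; defaults depend on
#'   `condition`.
#' @param density_cv coefficient of variation of the per-channel
#'   log-normal density factors.
#' @param seed integer seed; fixed seed gives an identical cohort.
#' @export
cohort_config <- function(n_cells = 8, condition = c("control", "lesioned"),
                          km_scale = NULL, ih_scale = NULL,
                          density_cv = 0.15, seed = 1L) {
  condition <- match.arg(condition)
  if (is.null(km_scale)) km_scale <- if (condition == "control") 1 else 0
  if (is.null(ih_scale)) ih_scale <- if (condition == "control") 1 else 2
  stopifnot(n_cells >= 1, km_scale >= 0, ih_scale >= 0, density_cv >= 0)
  structure(list(n_cells = as.integer(n_cells), condition = condition,
                 km_scale = km_scale, ih_scale = ih_scale,
                 density_cv = density_cv, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a cohort of model cells
#'
#' Each cell is the template with every channel's density multiplied by an
#' independent log-normal factor (median 1, CV `density_cv`), after which
#' the condition scalings are applied.  Deterministic for a fixed seed.
#'
#' @param template a calibrated `cell_model` (e.g.
#'   `calibrate_passive()$cell`).
#' @param config a [cohort_config()].
#' @return Tibble: `cell_id`, `condition`, `cell` (list-column of
#'   `cell_model`s), one factor column per channel.
#' @export
generate_cohort <- function(template, config = cohort_config()) {
  stopifnot(inherits(template, "cell_model"))
  chans <- template$chan_names
  sdl <- sqrt(log(1 + config$density_cv^2))
  rng <- .Random.seed_get()
  on.exit(.Random.seed_set(rng), add = TRUE)
  set.seed(config$seed)
  factors <- matrix(if (sdl > 0) exp(stats::rnorm(config$n_cells * length(chans),
                                                  0, sdl)) else 1,
                    config$n_cells, length(chans),
                    dimnames = list(NULL, chans))
  cells <- purrr::map(seq_len(config$n_cells), function(i) {
    cl <- apply_pharmacology(template, stats::setNames(factors[i, ], chans))
    apply_pharmacology(cl, c(KM = config$km_scale, IH = config$ih_scale))
  })
  out <- tibble::tibble(cell_id = seq_len(config$n_cells),
                        condition = config$condition, cell = cells)
  dplyr::bind_cols(out, tibble::as_tibble(factors))
}

#' Run the feature pipeline over a cohort
#'
#' Measures, per cell: resting potential, rheobase at 3 and 10 Hz (with
#' the spike threshold of the first suprathreshold trace), sag percentage,
#' and the rebound spike count.  Rebound spikes are counted at a *matched
#' end-of-step hyperpolarization* (default 22 mV below the holding
#' baseline, the centre of the experimental 20-40 mV bin): a first
#' -100 pA step measures the cell's hyperpolarization, the amplitude is
#' rescaled to reach the target, and the count is taken from the rescaled
#' step.  Comparing counts at matched hyperpolarization rather than
#' matched current follows the experimental sorting of rebound data and
#' avoids conflating rebound excitability with input-resistance or
#' H-current differences between cells.  `resolution = "reduced"` uses a
#' coarser solver step, shorter settling, a sparser F-I ladder with
#' linear-interpolation rheobase and a single sag amplitude — adequate for
#' direction-of-effect comparisons at a fraction of the cost of the full
#' protocol suite.
#'
#' @param cohort a [generate_cohort()] tibble (rows from several
#'   conditions may be bound together).
#' @param resolution `"reduced"` (default) or `"full"`.
#' @param fi_amplitudes_pA,sag_amplitudes_pA,rebound_duration_ms protocol
#'   settings (defaults depend on `resolution`).
#' @param rebound_target_hyp_mV end-of-step hyperpolarization at which
#'   rebound spikes are counted (mV below the holding baseline).
#' @param progress print one line per cell.
#' @return A `cohort_result`: list with `features` (one row per cell),
#'   `summaries` (per-condition medians/quartiles) and the run settings.
#' @export
run_cohort <- function(cohort, resolution = c("reduced", "full"),
                       fi_amplitudes_pA = NULL, sag_amplitudes_pA = NULL,
                       rebound_duration_ms = 2000,
                       rebound_target_hyp_mV = 22, progress = FALSE) {
  resolution <- match.arg(resolution)
  red <- resolution == "reduced"
  dt <- if (red) 0.1 else 0.025
  pre <- if (red) 800 else 2000
  fi_dur <- if (red) 1000 else 2000
  if (is.null(fi_amplitudes_pA))
    fi_amplitudes_pA <- if (red) c(100, 200, 300, 400, 500) else seq(30, 360, by = 30)
  if (is.null(sag_amplitudes_pA))
    sag_amplitudes_pA <- if (red) -100 else c(-50, -100, -150, -200)

  one_cell <- function(cell, id, cond) {
    res <- tryCatch({
      cell <- cache_rest(cell, duration_ms = if (red) 1200 else 2500, dt = dt)
      vrest <- cell$rest$vrest_mV
      hold_fi <- find_holding_current(cell, -64, dt = dt,
                                      settle_ms = if (red) 700 else 1500)
      fi <- run_fi(cell, amplitudes_pA = fi_amplitudes_pA, hold_pA = hold_fi,
                   dur_ms = fi_dur, dt = dt, sample_dt = dt, pre_ms = pre)
      rates <- purrr::map_dbl(fi$trace, function(tr) {
        st <- attr(tr, "stimulus")
        firing_rate(detect_spikes(tr), st$onset_ms, st$dur_ms)
      })
      fi_tab <- tibble::tibble(current_pA = fi$step_pA, rate_Hz = rates)
      if (red) {
        rheo3 <- rheobase(fi_tab, 3, method = "linear")
        rheo10 <- rheobase(fi_tab, 10, method = "linear")
      } else {
        bfit <- fit_fi_boltzmann(fi_tab)
        rheo3 <- rheobase(bfit, 3)
        rheo10 <- rheobase(bfit, 10)
      }
      i_supra <- which(rates > 0)
      vt <- if (length(i_supra)) spike_threshold(fi$trace[[i_supra[1]]]) else NA_real_
      hold_rb <- find_holding_current(cell, -71, dt = dt,
                                      settle_ms = if (red) 700 else 1500)
      amp <- -100
      probe <- run_step(cell, bias_pA = hold_rb, step_pA = amp,
                        dur_ms = rebound_duration_ms, post_ms = 600,
                        pre_ms = pre, dt = dt, sample_dt = dt)
      rbm <- rebound_metrics(probe)
      # rescale the amplitude (twice) until the end-of-step
      # hyperpolarization matches the target; cells with stronger sag or
      # higher input conductance need systematically larger steps
      for (it in 1:2) {
        if (abs(rbm$end_hyperpolarization_mV - rebound_target_hyp_mV) < 0.5)
          break
        amp <- amp * rebound_target_hyp_mV /
          max(rbm$end_hyperpolarization_mV, 3)
        amp <- max(-500, min(-20, amp))
        matched <- run_step(cell, bias_pA = hold_rb, step_pA = amp,
                            dur_ms = rebound_duration_ms, post_ms = 600,
                            pre_ms = pre, dt = dt, sample_dt = dt)
        rbm <- rebound_metrics(matched)
      }
      sag <- run_sag(cell, amplitudes_pA = sag_amplitudes_pA, dt = dt,
                     sample_dt = 2 * dt, pre_ms = if (red) 1000 else 2000)
      sagp <- mean(purrr::map_dbl(sag$trace,
                                  function(tr) sag_percent(tr)$sag_percent))
      tibble::tibble(cell_id = id, condition = cond, vrest_mV = vrest,
                     rheobase3_pA = rheo3, rheobase10_pA = rheo10,
                     v_threshold_mV = vt,
                     rebound_spikes = rbm$rebound_spike_count,
                     end_hyp_mV = rbm$end_hyperpolarization_mV,
                     sag_percent = sagp, failed = FALSE, error = NA_character_)
    }, error = function(e)
      tibble::tibble(cell_id = id, condition = cond, vrest_mV = NA_real_,
                     rheobase3_pA = NA_real_, rheobase10_pA = NA_real_,
                     v_threshold_mV = NA_real_, rebound_spikes = NA_integer_,
                     end_hyp_mV = NA_real_, sag_percent = NA_real_,
                     failed = TRUE, error = conditionMessage(e)))
    if (progress) message(sprintf("  cell %s/%s done", id, cond))
    res
  }

  feats <- purrr::pmap(list(cohort$cell, cohort$cell_id, cohort$condition),
                       one_cell)
  features <- dplyr::bind_rows(feats)
  if (all(features$failed)) stop("all cells failed", call. = FALSE)
  cohort_result(features, resolution = resolution)
}

#' Assemble a cohort result from per-cell feature rows
#'
#' Recomputes the per-condition summaries (median, quartiles) from the
#' feature table; useful for combining feature rows measured in separate
#' runs.
#'
#' @param features per-cell feature tibble as produced by [run_cohort()].
#' @param resolution label describing the protocol resolution used.
#' @return A `cohort_result`.
#' @export
cohort_result <- function(features, resolution = "reduced") {
  num_cols <- c("vrest_mV", "rheobase3_pA", "rheobase10_pA", "v_threshold_mV",
                "rebound_spikes", "sag_percent")
  summaries <- features |>
    dplyr::filter(!.data$failed) |>
    tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "feature") |>
    dplyr::group_by(.data$condition, .data$feature) |>
    dplyr::summarise(median = stats::median(.data$value, na.rm = TRUE),
                     q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE),
                     q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  structure(list(features = features, summaries = summaries,
                 resolution = resolution),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result: %d cells (%s resolution)>\n",
              nrow(x$features), x$resolution))
  print(x$summaries)
  invisible(x)
}

#' Signed median differences between conditions
#'
#' Per feature, `median(lesioned) - median(control)`, with a flag for
#' agreement with the reported direction of each effect (rheobase lower,
#' resting potential more depolarized, rebound spike count higher, sag
#' larger in the lesioned group).
#'
#' @param result a [run_cohort()] result containing both conditions.
#' @return Tibble: `feature`, `median_control`, `median_lesioned`,
#'   `difference`, `expected_sign`, `sign_agrees`.
#' @export
effect_table <- function(result) {
  s <- result$summaries
  if (!all(c("control", "lesioned") %in% s$condition))
    stop("effect_table needs both conditions", call. = FALSE)
  wide <- s |>
    dplyr::select("condition", "feature", "median") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "median")
  expected <- c(rheobase3_pA = -1, rheobase10_pA = -1, vrest_mV = +1,
                v_threshold_mV = -1, rebound_spikes = +1, sag_percent = +1)
  wide |>
    dplyr::mutate(difference = .data$lesioned - .data$control,
                  expected_sign = unname(expected[.data$feature]),
                  sign_agrees = sign(.data$difference) == .data$expected_sign) |>
    dplyr::rename(median_control = "control", median_lesioned = "lesioned")
}
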