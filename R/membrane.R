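#' Subcellular channel-density table
#'
#' Maximal conductance densities (S/cm^2; permeabilities in cm/s for the
#' GHK calcium channels) per channel and region.  The defaults are the
#' model's published distribution over the AIS, the soma and three
#' dendritic classes (distal; proximal/first-order; second order or
#' above).
#'
#' @param overrides optional named list `channel -> named numeric vector`
#'   of per-region replacements, e.g.
#'   `list(KM = c(soma = 0))`.
#' @return Tibble with columns `channel`, `ais`, `soma`, `dend_class_1`,
#'   `dend_class_2`, `dend_class_3`.
#' @export
distribution_table <- function(overrides = NULL) {
  tb <- tibble::tribble(
    ~channel, ~ais,    ~soma,   ~dend_class_1, ~dend_class_2, ~dend_class_3,
    "NaF",    0.008,   0.152,   0.008,         0.008,         0.004,
    "NaP",    0.0019,  0.0001,  0.0001,        0.0001,        0.0001,
    "KDR",    0.08,    1.52,    0.08,          0.08,          0.08,
    "KA",     0.005,   0.095,   0.005,         0.005,         0.005,
    "KM",     0.0165,  0.00033, 0.00033,       0.00033,       0.00033,
    "CaL",    0.0041,  0.0041,  0.0041,        0.00205,       0.00205,
    "SK",     0.0008,  0.0008,  0.0008,        0.0004,        0.0004,
    "ANO2",   0.00275, 0.00275, 0.00275,       0.001375,      0.001375,
    "CaT",    0,       0,       0.000085,      0.00017,       0.0000425,
    "IH",     0,       0,       0.000035,      0.000035,      0.000035)
  if (!is.null(overrides)) {
    for (ch in names(overrides)) {
      i <- match(ch, tb$channel)
      if (is.na(i)) stop("unknown channel in overrides: ", ch, call. = FALSE)
      for (rg in names(overrides[[ch]])) {
        if (!rg %in% names(tb)[-1])
          stop("unknown region in overrides: ", rg, call. = FALSE)
        tb[[rg]][i] <- overrides[[ch]][[rg]]
      }
    }
  }
  if (any(as.matrix(tb[-1]) < 0))
    stop("densities must be non-negative", call. = FALSE)
  tb
}

#' Write / read a density table as a human-readable config
#'
#' @param tb a [distribution_table()].
#' @param path file path (JSON).
#' @export
distribution_table_json <- function(tb, path = NULL) {
  js <- jsonlite::toJSON(tb, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); invisible(js) } else js
}

#' @rdname distribution_table_json
#' @param json JSON string or file path.
#' @export
distribution_table_from_json <- function(json) {
  tibble::as_tibble(jsonlite::fromJSON(json))
}

#' Calcium microdomain pools
#'
#' Intracellular calcium is tracked in three first-order microdomains:
#' two fed by the L-type flux (25.8% activating SK, decay 14 ms; 74.2%
#' activating ANO2, decay 50 ms) and one fed by the T-type flux (decay
#' 50 ms) that activates no channel and is kept for bookkeeping.  Each pool
#' obeys `d[Ca]/dt = -f * i_Ca * k - ([Ca] - rest)/tau` with
#' `k = 1e4 / (2 F depth)` converting an inward current density to a
#' concentration rate in a thin submembrane shell.
#'
#' @param ca_rest_uM resting calcium (uM).
#' @param depth_um shell depth (um).
#' @param conc_uM optional starting concentrations (named: sk, ano, t).
#' @return A `calcium_pools` object.
#' @export
calcium_pools <- function(ca_rest_uM = 0.05, depth_um = 45,
                          conc_uM = NULL) {
  pools <- tibble::tibble(
    pool = c("sk", "ano", "t"),
    source = c("cal", "cal", "cat"),
    fraction = c(0.258, 0.742, 1.0),
    tau_ms = c(14, 50, 50),
    coupled = c("SK", "ANO2", NA_character_),
    conc_uM = if (is.null(conc_uM)) rep(ca_rest_uM, 3) else
      unname(conc_uM[c("sk", "ano", "t")]))
  structure(list(pools = pools, ca_rest_uM = ca_rest_uM,
                 depth_um = depth_um),
            class = "calcium_pools")
}

#' Advance the calcium pools one time step
#'
#' Exact exponential update of the linear pool dynamics under
#' piecewise-constant calcium influx.
#'
#' @param pools a [calcium_pools()].
#' @param i_cal,i_cat L- and T-type calcium current densities (mA/cm^2,
#'   inward negative).
#' @param dt time step (ms).
#' @return Updated [calcium_pools()].
#' @export
update_calcium <- function(pools, i_cal, i_cat, dt) {
  stopifnot(dt > 0)
  FARADAY <- 96485.332
  k <- 1e4 / (2 * FARADAY * pools$depth_um)        # mM cm^2 / (mA ms)
  p <- pools$pools
  src <- ifelse(p$source == "cal", i_cal, i_cat)
  drive_uM <- pmax(-p$fraction * src * k, 0) * 1e3  # uM/ms, influx only
  target <- pools$ca_rest_uM + drive_uM * p$tau_ms
  p$conc_uM <- target + (p$conc_uM - target) * exp(-dt / p$tau_ms)
  pools$pools <- p
  pools
}

#' Hill activation of a calcium-activated channel
#'
#' @param ca_uM calcium concentration (uM).
#' @param hill_n Hill coefficient.
#' @param ec50_uM half-activation concentration (uM).
#' @export
hill_activation <- function(ca_uM, hill_n, ec50_uM) {
  ca_uM^hill_n / (ca_uM^hill_n + ec50_uM^hill_n)
}
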