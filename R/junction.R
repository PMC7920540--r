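#' Bundled limiting ionic mobility table
#'
#' Limiting equivalent conductances (S cm^2/equiv at 25 deg C) for the ion
#' species appearing in common patch-clamp solutions, from standard
#' electrochemical tables; organic anion values (gluconate, HEPES,
#' nucleotides, phosphocreatine, EGTA) follow the tables distributed with
#' liquid-junction-potential calculators.  Gluconate's mobility is the
#' dominant uncertainty in K-gluconate internals and is listed at 24.3.
#'
#' @return Tibble: `ion`, `z` (signed valence), `lambda` (S cm^2/equiv).
#' @export
ion_mobilities <- function() {
  tibble::tribble(
    ~ion,              ~z, ~lambda,
    "K",                1,   73.5,
    "Na",               1,   50.1,
    "Ca",               2,   59.5,
    "Mg",               2,   53.0,
    "H",                1,  349.8,
    "spermine",         4,   25.0,
    "Cl",              -1,   76.3,
    "HCO3",            -1,   44.5,
    "H2PO4",           -1,   33.0,
    "OH",              -1,  198.0,
    "gluconate",       -1,   24.3,
    "HEPES",           -1,   22.0,
    "GTP",             -2,   25.0,
    "MgATP",           -2,   20.0,
    "phosphocreatine", -2,   28.0,
    "EGTA",            -2,   24.0)
}

#' Ionized composition of the K-gluconate intracellular solution
#'
#' Decomposes the recording-pipette recipe (130 K-gluconate, 10 NaCl,
#' 10 KCl, 10 HEPES, 1 MgCl2, 0.5 Na2-GTP, 1 Mg-ATP, 5 phosphocreatine,
#' 0.1 spermine, 0.2 EGTA, titrated to pH 7.2 with KOH) into ionized
#' species: HEPES is partially deprotonated at pH 7.2 (pKa 7.55), Mg-ATP
#' is carried as a 2- complex, and the potassium added by the KOH/counter-
#' ion titration is set by electroneutrality.
#'
#' @param pH titration endpoint.
#' @param hepes_pKa HEPES acid dissociation constant.
#' @return Tibble: `ion`, `conc_mM`, `z`.
#' @export
solution_internal_kgluconate <- function(pH = 7.2, hepes_pKa = 7.55) {
  hepes_anion <- 10 / (1 + 10^(hepes_pKa - pH))
  ions <- tibble::tribble(
    ~ion,              ~conc_mM,
    "K",               130 + 10,          # K-gluconate + KCl
    "Na",              10 + 1,            # NaCl + Na2-GTP
    "Mg",              1,                 # MgCl2 (ATP-bound Mg complexed)
    "spermine",        0.1,
    "gluconate",       130,
    "Cl",              10 + 10 + 2,       # NaCl + KCl + MgCl2
    "HEPES",           hepes_anion,
    "GTP",             0.5,
    "MgATP",           1,
    "phosphocreatine", 5,
    "EGTA",            0.2)
  ions <- dplyr::left_join(ions, ion_mobilities()[c("ion", "z")], by = "ion")
  # electroneutrality: the deficit is made up by K+ from the KOH titration
  # (and the unstated counter-ions of the phosphate salts)
  imbalance <- -sum(ions$conc_mM * ions$z)
  if (imbalance > 0) ions$conc_mM[ions$ion == "K"] <-
      ions$conc_mM[ions$ion == "K"] + imbalance
  ions[c("ion", "conc_mM", "z")]
}

#' Ionized composition of the recording ACSF
#'
#' 124 NaCl, 2.5 KCl, 1.25 NaH2PO4, 26 NaHCO3, 10 glucose, 2 CaCl2,
#' 1.3 MgCl2 (glucose is neutral and omitted).
#'
#' @return Tibble: `ion`, `conc_mM`, `z`.
#' @export
solution_acsf <- function() {
  ions <- tibble::tribble(
    ~ion,    ~conc_mM,
    "Na",    124 + 1.25 + 26,
    "K",     2.5,
    "Ca",    2,
    "Mg",    1.3,
    "Cl",    124 + 2.5 + 2 * 2 + 2 * 1.3,
    "H2PO4", 1.25,
    "HCO3",  26)
  ions <- dplyr::left_join(ions, ion_mobilities()[c("ion", "z")], by = "ion")
  ions[c("ion", "conc_mM", "z")]
}

#' Liquid junction potential by the stationary Henderson equation
#'
#' Computes the junction potential between the pipette (internal) and bath
#' (external) solutions from their ionized compositions and the bundled
#' mobility table.  The value is reported with the patch-clamp sign
#' convention for the correction magnitude (bath minus pipette), positive
#' for a K-gluconate internal against ACSF.
#'
#' @param internal,external tibbles with columns `ion`, `conc_mM` and
#'   optionally `z` (valence taken from [ion_mobilities()] otherwise).
#' @param temp_c temperature (deg C).
#' @param mobilities mobility table; see [ion_mobilities()].
#' @return Junction potential in mV.
#' @export
junction_potential <- function(internal = solution_internal_kgluconate(),
                               external = solution_acsf(),
                               temp_c = 27, mobilities = ion_mobilities()) {
  prep <- function(sol) {
    sol <- tibble::as_tibble(sol)
    mm <- mobilities
    miss <- setdiff(sol$ion, mm$ion)
    if (length(miss))
      stop("no mobility for species: ", paste(miss, collapse = ", "),
           call. = FALSE)
    sol$lambda <- mm$lambda[match(sol$ion, mm$ion)]
    if (!"z" %in% names(sol)) sol$z <- mm$z[match(sol$ion, mm$ion)]
    sol
  }
  p <- prep(internal); b <- prep(external)
  ions <- union(p$ion, b$ion)
  cp <- stats::setNames(rep(0, length(ions)), ions)
  cb <- cp
  cp[p$ion] <- p$conc_mM; cb[b$ion] <- b$conc_mM
  zz <- mobilities$z[match(ions, mobilities$ion)]
  # mobility u ~ lambda / |z|
  u <- mobilities$lambda[match(ions, mobilities$ion)] / abs(zz)
  RT_F <- 8.3134 * (temp_c + 273.15) / 96485.332 * 1e3   # mV
  num <- sum(zz * u * (cb - cp))
  den <- sum(zz^2 * u * (cb - cp))
  s1 <- sum(zz^2 * u * cp)
  s2 <- sum(zz^2 * u * cb)
  if (abs(den) < 1e-12 || s1 <= 0 || s2 <= 0) return(0)
  RT_F * (num / den) * log(s1 / s2)
}
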