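#' Assay medium for the creatine-kinase clamp
#'
#' Describes the composition of the respirometry/fluorometry assay buffer at
#' one point of a phosphocreatine (PCr) titration. Defaults are the standard
#' clamp composition: ATP 5 mM, creatine 5 mM, PCr 1 mM, 10 mM inorganic
#' phosphate from the K2HPO4 of the buffer, pH 7.2, 37 degrees C.
#'
#' @param atp_mM Total ATP (mM).
#' @param cr_mM Free creatine (mM).
#' @param pcr_mM Phosphocreatine (mM).
#' @param pi_mM Inorganic phosphate (mM), held constant across a titration.
#' @param ph Buffer pH (validated only; speciation is folded into the
#'   apparent constants, see [thermo_constants()]).
#' @param temp_K Assay temperature in kelvin.
#' @param free_mg_mM Free magnesium (mM); carried for completeness.
#'
#' @return An object of class `ck_medium`.
#' @seealso [delta_g_atp()], [demand_series()]
#' @export
ck_medium <- function(atp_mM = 5, cr_mM = 5, pcr_mM = 1, pi_mM = 10,
                      ph = 7.2, temp_K = 310.15, free_mg_mM = 5) {
  conc <- c(atp_mM = atp_mM, cr_mM = cr_mM, pcr_mM = pcr_mM,
            pi_mM = pi_mM, free_mg_mM = free_mg_mM)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all concentrations must be finite and > 0", call. = FALSE)
  if (!is.finite(ph) || ph < 6 || ph > 8.5)
    stop("ph must lie in [6.0, 8.5]", call. = FALSE)
  if (!is.finite(temp_K) || temp_K < 273 || temp_K > 320)
    stop("temp_K must lie in [273, 320]", call. = FALSE)
  structure(list(atp_mM = atp_mM, cr_mM = cr_mM, pcr_mM = pcr_mM,
                 pi_mM = pi_mM, ph = ph, temp_K = temp_K,
                 free_mg_mM = free_mg_mM),
            class = "ck_medium")
}

#' Apparent thermodynamic constants of the clamp
#'
#' The creatine-kinase (CK) reaction at equilibrium clamps the
#' extramitochondrial ATP/ADP ratio at `k_ck_apparent * PCr / Cr`. The free
#' energy of ATP hydrolysis then follows from the standard transformed free
#' energy `dg0_atp_kcal` and the mass-action term. Both constants are
#' *apparent* values on the molar scale at pH ~7.1-7.2, 37 degrees C: proton
#' and magnesium binding are folded into them rather than modelled by an
#' explicit speciation polynomial. The shipped defaults are calibrated so the
#' canonical four-step titration (PCr 1, 6, 15, 30 mM with ATP 5 mM, Cr 5 mM,
#' Pi 10 mM) yields Delta-G_ATP of about -12.94, -14.18, -14.72 and
#' -15.24 kcal/mol.
#'
#' @param k_ck_apparent Apparent CK equilibrium constant (unitless, > 1).
#' @param dg0_atp_kcal Standard transformed free energy of ATP hydrolysis
#'   (kcal/mol, negative).
#' @param gas_const_kcal Gas constant in kcal/mol/K.
#'
#' @return An object of class `thermo_constants`.
#' @export
thermo_constants <- function(k_ck_apparent = 347.6,
                             dg0_atp_kcal = -7.60,
                             gas_const_kcal = 1.9872e-3) {
  if (!is.finite(k_ck_apparent) || k_ck_apparent <= 1)
    stop("k_ck_apparent must be > 1", call. = FALSE)
  if (!is.finite(dg0_atp_kcal) || dg0_atp_kcal >= 0)
    stop("dg0_atp_kcal must be negative", call. = FALSE)
  if (!is.finite(gas_const_kcal) || gas_const_kcal <= 0)
    stop("gas_const_kcal must be positive", call. = FALSE)
  structure(list(k_ck_apparent = k_ck_apparent,
                 dg0_atp_kcal = dg0_atp_kcal,
                 gas_const_kcal = gas_const_kcal),
            class = "thermo_constants")
}

#' Clamped extramitochondrial ATP/ADP ratio
#'
#' With excess CK the ATP/ADP ratio is pinned at the CK equilibrium:
#' `ratio = K'CK * [PCr] / [Cr]`. Strictly increasing (linear) in PCr at
#' fixed creatine.
#'
#' @param medium A [ck_medium()].
#' @param constants A [thermo_constants()].
#' @return Unitless ATP/ADP ratio.
#' @export
atp_adp_ratio <- function(medium, constants = thermo_constants()) {
  stopifnot(inherits(medium, "ck_medium"),
            inherits(constants, "thermo_constants"))
  if (medium$cr_mM <= 0)
    stop("cr_mM must be positive", call. = FALSE)
  constants$k_ck_apparent * medium$pcr_mM / medium$cr_mM
}

#' Free energy of ATP hydrolysis under the CK clamp
#'
#' `Delta-G_ATP = dG0' + R T ln( [Pi] / (ATP/ADP) )` with [Pi] in mol/L
#' against a 1 M reference state and the ATP/ADP ratio from
#' [atp_adp_ratio()]. More negative (lower energy demand) at higher PCr.
#'
#' @inheritParams atp_adp_ratio
#' @return Delta-G_ATP in kcal/mol (negative).
#' @export
delta_g_atp <- function(medium, constants = thermo_constants()) {
  ratio <- atp_adp_ratio(medium, constants)
  rt <- constants$gas_const_kcal * medium$temp_K
  constants$dg0_atp_kcal + rt * log((medium$pi_mM / 1000) / ratio)
}

#' Demand series for a PCr titration
#'
#' Evaluates the clamp at each PCr level of a titration, producing the energy
#' demand axis against which JO2, redox state, membrane potential and H2O2
#' production are plotted. The conventional protocol starts at PCr 1 mM
#' (highest demand, least negative Delta-G) and titrates to 6, 15, 30 mM.
#'
#' @param base_medium A [ck_medium()] giving the fixed Cr, Pi, pH and
#'   temperature; its `pcr_mM` is ignored in favour of the titration levels.
#' @param pcr_titration_mM Strictly increasing vector of PCr levels (mM).
#' @param constants A [thermo_constants()].
#'
#' @return A data frame of class `demand_series` with columns `pcr_mM`,
#'   `atp_adp_ratio` and `dg_atp_kcal`; Delta-G strictly decreasing.
#' @export
#' @examples
#' demand_series(ck_medium(), c(1, 6, 15, 30))
demand_series <- function(base_medium, pcr_titration_mM = c(1, 6, 15, 30),
                          constants = thermo_constants()) {
  stopifnot(inherits(base_medium, "ck_medium"))
  if (length(pcr_titration_mM) < 1 || any(pcr_titration_mM <= 0))
    stop("pcr_titration_mM must be positive", call. = FALSE)
  if (is.unsorted(pcr_titration_mM, strictly = TRUE))
    stop("pcr_titration_mM must be strictly increasing", call. = FALSE)
  states <- lapply(pcr_titration_mM, function(p) {
    m <- base_medium
    m$pcr_mM <- p
    c(ratio = atp_adp_ratio(m, constants), dg = delta_g_atp(m, constants))
  })
  out <- data.frame(pcr_mM = pcr_titration_mM,
                    atp_adp_ratio = vapply(states, `[[`, 0, "ratio"),
                    dg_atp_kcal = vapply(states, `[[`, 0, "dg"))
  class(out) <- c("demand_series", "data.frame")
  out
}
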