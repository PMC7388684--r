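#' @title Cross-membrane transport, circulation, hormone and periphery closures
#' @description Couples the three compartments: facilitative transporter flux
#'   between hepatic blood (SHB) and hepatocytes (SH), whole-body circulation
#'   between systemic blood (SBC) and SHB, insulin/glucagon secretion and
#'   clearance, and lumped peripheral (muscle/adipose) consumption and release
#'   fluxes closing the systemic blood balances.
#' @name exchange
NULL

.blood_species <- c("Fru", "Glu", "Pyr", "FA", "TG", "Ins", "Gcg")
.transport_names <- c("T_Fru", "T_Glu", "T_Pyr", "T_FA", "T_TG")

#' Names of the blood-compartment state variables
#' @return Character vector of the 7 blood species (5 metabolites + insulin
#'   and glucagon in basal-normalised units), fixed order.
#' @export
blood_species <- function() .blood_species

#' Names of the five cross-membrane transport fluxes
#' @return Character vector, fixed order. Positive flux = into the hepatocyte.
#' @export
transport_names <- function() .transport_names

#' Symmetric facilitated-exchange rate
#'
#' The carrier-mediated form `Vmax * (S_out - S_in) / (Km + S_out + S_in)`:
#' zero at equal concentrations, odd in the concentration difference, and
#' bounded by `Vmax` in magnitude.
#'
#' @param S_out Concentration on the blood side (uM), >= 0.
#' @param S_in Concentration on the hepatocyte side (uM), >= 0.
#' @param Vmax Maximal carrier rate (uM/s), > 0.
#' @param Km Carrier affinity constant (uM), > 0.
#' @return Exchange rate (uM/s), positive into the hepatocyte.
#' @export
bidirectional_exchange <- function(S_out, S_in, Vmax, Km) {
  if (any(S_out < 0) || any(S_in < 0))
    stop("negative concentration in bidirectional_exchange")
  if (any(Vmax <= 0) || any(Km <= 0)) stop("Vmax and Km must be > 0")
  Vmax * (S_out - S_in) / (Km + S_out + S_in)
}

#' Evaluate the five SHB -> hepatocyte transport fluxes
#'
#' Fructose uses GLUT2 and GLUT5, each as a unidirectional Michaelis pump in
#' the blood-side concentration plus a symmetric exchange; glucose uses the
#' analogous lumped GLUT pump + exchange; pyruvate/lactate is a pure exchange;
#' fatty acids add an insulin-damped active-uptake term; triglyceride
#' exchange normalises the hepatocyte pool by `TG_ref` and subtracts the
#' hepatic (VLDL-like) export `V_out * TG_SH / (Km_out + TG_SH)`.
#'
#' @param shb Named numeric vector of hepatic-blood species (needs `Fru`,
#'   `Glu`, `Pyr`, `FA`, `TG`, `Ins`), uM (hormones basal-normalised).
#' @param sh Named numeric vector of hepatocyte species, uM.
#' @param params A `parameter_set` or `param_values()` vector.
#' @return Named numeric vector of the 5 transports (uM/s), positive into the
#'   hepatocyte.
#' @export
evaluate_transports <- function(shb, sh, params) {
  p <- if (inherits(params, "parameter_set")) param_values(params) else params
  if (any(shb[c("Fru", "Glu", "Pyr", "FA", "TG")] < 0) ||
      any(sh[.hepatic_species] < 0, na.rm = TRUE))
    stop("negative concentration passed to evaluate_transports")
  ex <- function(S_out, S_in, Vmax, Km) (Vmax * (S_out - S_in)) / (Km + S_out + S_in)

  t_fru <- p[["V_GLUT2_pump"]] * shb[["Fru"]] /
      (p[["Km_GLUT2_pump"]] + shb[["Fru"]]) +
    ex(shb[["Fru"]], sh[["Fru"]], p[["V_GLUT2_ex"]], p[["Km_GLUT2_ex"]]) +
    p[["V_GLUT5_pump"]] * shb[["Fru"]] /
      (p[["Km_GLUT5_pump"]] + shb[["Fru"]]) +
    ex(shb[["Fru"]], sh[["Fru"]], p[["V_GLUT5_ex"]], p[["Km_GLUT5_ex"]])

  t_glu <- p[["V_GLUTG_pump"]] * shb[["Glu"]] /
      (p[["Km_GLUTG_pump"]] + shb[["Glu"]]) +
    ex(shb[["Glu"]], sh[["Glu"]], p[["V_GLUTG_ex"]], p[["Km_GLUTG_ex"]])

  t_pyr <- ex(shb[["Pyr"]], sh[["Pyr"]], p[["V_Pyrex"]], p[["Km_Pyr_ex"]])

  t_fa <- ex(shb[["FA"]], sh[["FA"]], p[["V_FAex"]], p[["Km_FA_ex"]]) +
    p[["V_active"]] * shb[["FA"]] /
      ((p[["Km_active"]] + shb[["FA"]]) *
         (1 + shb[["Ins"]] / p[["Insref_active"]]))

  tg_sh_norm <- sh[["TG"]] / p[["TG_ref"]]
  t_tg <- p[["V_TGex"]] * (shb[["TG"]] - tg_sh_norm) /
      (p[["Km_TG_ex"]] + shb[["TG"]] + tg_sh_norm) -
    p[["V_out"]] * sh[["TG"]] / (p[["Km_out"]] + sh[["TG"]])

  c(T_Fru = t_fru, T_Glu = t_glu, T_Pyr = t_pyr, T_FA = t_fa, T_TG = t_tg)
}

#' Circulation flux between systemic and hepatic blood
#'
#' Blood circulates with rate constant `R_BS`; the hepatic-blood pool receives
#' `R_BS * (C_SBC - C_SHB)` while the systemic pool loses
#' `R_BS * (C_SBC - C_SHB) / R_RL`, where `R_RL = (V_body - V_liver)/V_liver`.
#' With this volume convention circulation conserves total moles exactly:
#' `V_liver * shb_term + (V_body - V_liver) * sbc_term = 0`.
#'
#' @param C_sbc Systemic-blood concentration (uM), >= 0.
#' @param C_shb Hepatic-blood concentration (uM), >= 0.
#' @param params A `parameter_set` or `param_values()` vector.
#' @return List with `shb` and `sbc` rate contributions (uM/s). Vectorised.
#' @export
circulation_flux <- function(C_sbc, C_shb, params) {
  p <- if (inherits(params, "parameter_set")) param_values(params) else params
  shb_term <- p[["R_BS"]] * (C_sbc - C_shb)
  list(shb = shb_term, sbc = -shb_term / p[["R_RL"]])
}

#' Insulin and glucagon dynamics
#'
#' Systemic insulin is secreted as a rising Hill function of systemic blood
#' glucose around the glucose setpoint `Km_Ins_Glu` and cleared first order;
#' glucagon mirrors it with a falling Hill function. Hormone levels are
#' dimensionless multiples of basal (the secretion constants are chosen so
#' the basal fixed point at the setpoint is 1). Hepatic-blood hormones relax
#' toward the systemic values through circulation.
#'
#' @param sbc Named systemic-blood state (needs `Glu`, `Ins`, `Gcg`).
#' @param shb Named hepatic-blood state (needs `Ins`, `Gcg`).
#' @param params A `parameter_set` or `param_values()` vector.
#' @return Named numeric vector `dIns_SHB`, `dGcg_SHB`, `dIns_SBC`,
#'   `dGcg_SBC` (1/s, basal-normalised units).
#' @export
hormone_derivatives <- function(sbc, shb, params) {
  p <- if (inherits(params, "parameter_set")) param_values(params) else params
  glu <- sbc[["Glu"]]
  sec_ins <- p[["V_Ins_sec"]] * glu^p[["n_Ins"]] /
    (p[["Km_Ins_Glu"]]^p[["n_Ins"]] + glu^p[["n_Ins"]])
  sec_gcg <- p[["V_Gcg_sec"]] * p[["Km_Gcg_Glu"]]^p[["n_Gcg"]] /
    (p[["Km_Gcg_Glu"]]^p[["n_Gcg"]] + glu^p[["n_Gcg"]])
  circ_ins <- circulation_flux(sbc[["Ins"]], shb[["Ins"]], p)
  circ_gcg <- circulation_flux(sbc[["Gcg"]], shb[["Gcg"]], p)
  c(dIns_SHB = circ_ins$shb,
    dGcg_SHB = circ_gcg$shb,
    dIns_SBC = sec_ins - p[["k_Ins_clear"]] * sbc[["Ins"]] + circ_ins$sbc,
    dGcg_SBC = sec_gcg - p[["k_Gcg_clear"]] * sbc[["Gcg"]] + circ_gcg$sbc)
}

#' Peripheral consumption and release fluxes
#'
#' Lumped muscle/adipose closure on the systemic blood: `USE` terms are
#' Michaelis consumptions of the systemic species (insulin-stimulated for
#' glucose), `UP` terms are adipose releases of fatty acids and triglyceride
#' suppressed by insulin through an inhibition factor. Because the assembled
#' systemic balances debit blood glucose for the releases
#' (`dGlu -= USE_Glu + UP_FA + UP_TG`; `dFA += UP_FA - USE_FA`;
#' `dTG += UP_TG - USE_TG`), the `UP` terms also carry a glucose saturation
#' factor `Glu/(Km_upGlu + Glu)` so they shut off as their substrate runs
#' out and blood glucose cannot be driven negative.
#'
#' @param sbc Named systemic-blood state (needs `Glu`, `FA`, `TG`, `Ins`).
#' @param params A `parameter_set` or `param_values()` vector.
#' @return Named numeric vector `USE_Glu`, `USE_FA`, `USE_TG`, `UP_FA`,
#'   `UP_TG` (uM/s).
#' @export
periphery_fluxes <- function(sbc, params) {
  p <- if (inherits(params, "parameter_set")) param_values(params) else params
  ins <- sbc[["Ins"]]
  glu_gate <- sbc[["Glu"]] / (p[["Km_upGlu"]] + sbc[["Glu"]])
  c(USE_Glu = p[["V_useGlu"]] * sbc[["Glu"]] /
      (p[["Km_useGlu"]] + sbc[["Glu"]]) * ins,
    USE_FA = p[["V_useFA"]] * sbc[["FA"]] / (p[["Km_useFA"]] + sbc[["FA"]]),
    USE_TG = p[["V_useTG"]] * sbc[["TG"]] / (p[["Km_useTG"]] + sbc[["TG"]]),
    UP_FA = p[["V_upFA"]] * glu_gate *
      inhibition_term(ins, p[["Ki_upIns"]], p[["beta_upFA"]]),
    UP_TG = p[["V_upTG"]] * glu_gate *
      inhibition_term(ins, p[["Ki_upIns"]], p[["beta_upTG"]]))
}
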