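#' @title Hepatocyte reaction kinetics
#' @description The sixteen hepatocyte rate laws: eleven fructolysis /
#'   lipogenesis / lipid-turnover reactions (fructokinase through lipolysis)
#'   plus the four-enzyme glucose branch (glucokinase, glucose-6-phosphatase,
#'   fructose-bisphosphatase, phosphofructokinase). Every law is a product of
#'   a maximal rate, Hill/Michaelis saturation factors in \[0, 1\] for
#'   substrates and clamped cofactors, and allosteric inhibition factors
#'   `1 - beta*X/(Ki + X)` in \[1 - beta, 1\], so all rates are non-negative
#'   for non-negative states.
#' @name kinetics
NULL

.hepatic_species <- c("Fru", "F1P", "DHAP", "GA", "GA3P", "Pyr", "ACoA",
                      "FA", "TG", "Glu", "G6P")
.rate_names <- c("R_KHK", "R_aldB", "R_TPI_DHAP", "R_TPI_GA3P", "R_Tri",
                 "R_PK", "R_PEPCK", "R_PDC", "R_FAS", "R_boxi", "R_TGS",
                 "R_Lply", "R_GK", "R_G6Pase", "R_FBP", "R_PFK")

#' Names of the hepatocyte state variables
#' @return Character vector of the 11 hepatocyte species, in fixed order.
#' @export
hepatic_species <- function() .hepatic_species

#' Names of the 16 hepatocyte reaction rates
#' @return Character vector of rate identifiers, in fixed order.
#' @export
rate_names <- function() .rate_names

#' Hill/Michaelis saturation factor
#'
#' `S^n / (Km^n + S^n)`: 0 at `S = 0`, 1/2 at `S = Km` for any `n`, tending
#' to 1 as `S` grows.
#'
#' @param S Substrate concentration (uM), >= 0.
#' @param Km Half-saturation constant (uM), > 0.
#' @param n Hill exponent, >= 1 (default 1, plain Michaelis-Menten).
#' @return Dimensionless factor in \[0, 1\]. Vectorised over `S`.
#' @export
saturation_term <- function(S, Km, n = 1) {
  if (any(S < 0)) stop("negative substrate concentration in saturation_term")
  if (any(Km <= 0)) stop("Km must be > 0")
  if (any(n < 1)) stop("Hill exponent must be >= 1")
  Sn <- S^n
  Sn / (Km^n + Sn)
}

#' Allosteric inhibition factor
#'
#' `1 - beta * X / (Ki + X)`: 1 with no inhibitor, bounded below by
#' `1 - beta`, so rates stay non-negative whenever `beta` is in \[0, 1\].
#'
#' @param X Inhibitor concentration (uM), >= 0.
#' @param Ki Half-inhibition constant (uM), > 0.
#' @param beta Inhibition strength in \[0, 1\].
#' @return Dimensionless factor in \[1 - beta, 1\]. Vectorised over `X`.
#' @export
inhibition_term <- function(X, Ki, beta) {
  if (any(X < 0)) stop("negative inhibitor concentration in inhibition_term")
  if (any(Ki <= 0)) stop("Ki must be > 0")
  if (any(beta < 0 | beta > 1)) stop("beta must lie in [0, 1]")
  1 - beta * X / (Ki + X)
}

#' Evaluate the 16 hepatocyte reaction rates
#'
#' @param state Named numeric vector with the 11 hepatocyte species
#'   (`hepatic_species()`), all >= 0, in uM.
#' @param params A `parameter_set`, or the named numeric vector from
#'   `param_values()`.
#' @return Named numeric vector of 16 rates (uM/s), see `rate_names()`.
#' @export
evaluate_hepatic_rates <- function(state, params) {
  p <- if (inherits(params, "parameter_set")) param_values(params) else params
  s <- state[.hepatic_species]
  if (any(is.na(s))) stop("state is missing hepatocyte species")
  if (any(s < 0))
    stop("negative hepatocyte concentration(s): ",
         paste(.hepatic_species[s < 0], collapse = ", "))
  sat <- function(S, Km, n = 1) S^n / (Km^n + S^n)
  inh <- function(X, Ki, beta) 1 - beta * X / (Ki + X)

  r <- c(
    R_KHK = p[["V_KHK"]] * sat(s[["Fru"]], p[["Km_KHK"]], p[["n_Fru"]]) *
      sat(p[["ATP"]], p[["Km_ATP"]], p[["n_ATP"]]),
    R_aldB = p[["V_aldB"]] * sat(s[["F1P"]], p[["Km_F1P"]], p[["n_F1P"]]),
    R_TPI_DHAP = p[["V_TPI_DHAP"]] *
      sat(s[["DHAP"]], p[["Km_DHAP"]], p[["n_DHAP"]]),
    R_TPI_GA3P = p[["V_TPI_GA3P"]] *
      sat(s[["GA3P"]], p[["Km_TPIGA3P"]], p[["n_GA3P"]]),
    R_Tri = p[["V_Tri"]] * sat(s[["GA"]], p[["Km_GA"]], p[["n_GA"]]) *
      sat(p[["ATPMg"]], p[["Km_ATPMg"]], p[["n_ATPMg"]]) *
      inh(p[["ATP"]], p[["Ki_ATP"]], p[["beta_ATP"]]) *
      inh(p[["ADP"]], p[["Ki_ADP"]], p[["beta_ADP"]]),
    R_PK = p[["V_PK"]] * sat(s[["GA3P"]], p[["Km_GA3P"]], p[["n_GA3P"]]) *
      sat(p[["ADP"]], p[["Km_ADPpk"]], p[["n_ADPpk"]]) *
      inh(s[["ACoA"]], p[["Ki_ACoA_PK"]], p[["beta_ACoA_PK"]]),
    R_PEPCK = p[["V_PEPCK"]] * sat(s[["Pyr"]], p[["Km_PEPCK"]]) *
      sat(p[["ATP"]], p[["Km_ATPpepck"]]) *
      sat(p[["GTP"]], p[["Km_GTP"]]),
    R_PDC = p[["V_PDC"]] * sat(s[["Pyr"]], p[["Km_Pyr"]]) *
      inh(s[["ACoA"]], p[["ki_CoA_pyr"]], p[["beta_ACoA_PDC"]]),
    R_FAS = p[["V_FAS"]] * sat(s[["ACoA"]], p[["Km_ACoA"]]) *
      sat(p[["ATP"]], p[["Km_ATPfas"]]) *
      inh(s[["FA"]], p[["ki_FA_inhib"]], p[["beta_FA"]]),
    R_boxi = p[["V_boxi"]] * sat(s[["FA"]], p[["Km_boxi"]]) *
      sat(p[["ATP"]], p[["Km_ATPboxi"]]) *
      inh(s[["ACoA"]], p[["ki_CoA_boxi"]], p[["beta_boxi"]]) *
      inh(s[["F1P"]], p[["ki_F1P_inhib"]], p[["beta_PPARa"]]),
    R_TGS = p[["V_TGS"]] * sat(s[["FA"]], p[["Km_FA"]]) *
      sat(s[["GA3P"]], p[["Km_TGSGA3P"]]),
    R_Lply = p[["V_Lply"]] * sat(s[["TG"]], p[["Km_TG"]]),
    R_GK = p[["V_GK"]] * sat(s[["Glu"]], p[["Km_Glu"]], p[["n_Glu"]]) *
      sat(p[["ATP"]], p[["Km_ATPgk"]], p[["n_ATP"]]) *
      inh(s[["G6P"]], p[["ki_G6P"]], 1),
    R_G6Pase = p[["V_G6Pase"]] * sat(s[["G6P"]], p[["Km_G6Pase"]]),
    R_FBP = p[["V_FBP"]] * sat(s[["GA3P"]], p[["Km_FBP"]]),
    R_PFK = p[["V_PFK"]] * sat(s[["G6P"]], p[["Km_PFK"]]) *
      sat(p[["ATP"]], p[["Km_ATPpfk"]]) *
      (1 - sat(p[["ATP"]], p[["ki_ATPfpk"]]) *
             sat(p[["ADP"]], p[["ki_ADPfpk"]])) *
      inh(s[["GA3P"]], p[["ki_GA3Ppfk"]], p[["beta_PFK"]])
  )
  r[.rate_names]
}

#' Assemble hepatocyte state derivatives
#'
#' Combines reaction rates and cross-membrane transports into d/dt of the 11
#' hepatocyte species. Two stoichiometric bookkeeping modes are supported:
#' `"paper-faithful"` (default) uses the original balance tabulation, which omits
#' the triglyceride-synthesis and glucose-branch GA3P terms and the lipolysis
#' glyceraldehyde return; `"carbon-consistent"` restores them
#' (`dGA += R_Lply`, `dGA3P += R_PFK - R_FBP - R_TGS`).
#'
#' @param rates Named rate vector from [evaluate_hepatic_rates()].
#' @param transports Named transport vector from [evaluate_transports()]
#'   (`T_Fru`, `T_Glu`, `T_Pyr`, `T_FA`, `T_TG`; positive = into hepatocyte).
#' @param params A `parameter_set` or named numeric vector (unused by the
#'   balance itself; accepted for interface symmetry).
#' @param mode `"paper-faithful"` or `"carbon-consistent"`.
#' @return Named numeric vector, d/dt of the 11 hepatocyte species (uM/s).
#' @export
hepatic_derivatives <- function(rates, transports, params = NULL,
                                mode = c("paper-faithful",
                                         "carbon-consistent")) {
  mode <- match.arg(mode)
  r <- rates
  tr <- transports
  if (any(!is.finite(r)) || any(!is.finite(tr)))
    stop("non-finite rate or transport")
  d <- c(
    Fru  = tr[["T_Fru"]] - r[["R_KHK"]],
    F1P  = r[["R_KHK"]] - r[["R_aldB"]],
    DHAP = r[["R_aldB"]] - r[["R_TPI_DHAP"]] + r[["R_TPI_GA3P"]],
    GA   = r[["R_aldB"]] - r[["R_Tri"]],
    GA3P = r[["R_TPI_DHAP"]] - r[["R_TPI_GA3P"]] + r[["R_Tri"]] -
      r[["R_PK"]] + r[["R_PEPCK"]],
    Pyr  = tr[["T_Pyr"]] + r[["R_PK"]] - r[["R_PDC"]] - r[["R_PEPCK"]],
    ACoA = r[["R_PDC"]] - 8 * r[["R_FAS"]] + 8 * r[["R_boxi"]],
    FA   = tr[["T_FA"]] + r[["R_FAS"]] - r[["R_boxi"]] -
      3 * r[["R_TGS"]] + 3 * r[["R_Lply"]],
    TG   = tr[["T_TG"]] + r[["R_TGS"]] - r[["R_Lply"]],
    Glu  = tr[["T_Glu"]] - r[["R_GK"]] + r[["R_G6Pase"]],
    G6P  = r[["R_GK"]] - r[["R_G6Pase"]] + r[["R_FBP"]] - r[["R_PFK"]]
  )
  if (mode == "carbon-consistent") {
    d[["GA"]] <- d[["GA"]] + r[["R_Lply"]]
    d[["GA3P"]] <- d[["GA3P"]] + r[["R_PFK"]] - r[["R_FBP"]] - r[["R_TGS"]]
  }
  d
}
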