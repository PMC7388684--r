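# Shared fixtures. The default parameter set is loaded once per test run;
# tests that need modified constants either use load_parameters(overrides=)
# or edit a plain named vector (which bypasses validation on purpose).

test_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_parameters()
    cache
  }
})

test_param_values <- function() param_values(test_params())

# A strictly positive, physiologically shaped random hepatocyte state.
random_hepatic_state <- function() {
  s <- c(Fru = 2000, F1P = 1000, DHAP = 300, GA = 50, GA3P = 1500,
         Pyr = 2000, ACoA = 500, FA = 2000, TG = 20000, Glu = 3000,
         G6P = 400)
  s * stats::runif(length(s), 0.05, 3)
}

random_blood_state <- function() {
  s <- c(Fru = 1000, Glu = 1500, Pyr = 1500, FA = 300, TG = 1500,
         Ins = 1, Gcg = 1)
  s * stats::runif(length(s), 0.05, 3)
}

# Independent straight-line transcription of the sixteen rate laws, written
# directly from the tabulated rate-law formulas (no shared code with the package
# implementation). Serves as the oracle for equivalence tests.
oracle_rates <- function(s, p) {
  hill <- function(S, K, n) S^n / (K^n + S^n)
  mm <- function(S, K) S / (K + S)
  c(
    R_KHK = p[["V_KHK"]] *
      hill(s[["Fru"]], p[["Km_KHK"]], p[["n_Fru"]]) *
      hill(p[["ATP"]], p[["Km_ATP"]], p[["n_ATP"]]),
    R_aldB = p[["V_aldB"]] * hill(s[["F1P"]], p[["Km_F1P"]], p[["n_F1P"]]),
    R_TPI_DHAP = p[["V_TPI_DHAP"]] *
      hill(s[["DHAP"]], p[["Km_DHAP"]], p[["n_DHAP"]]),
    R_TPI_GA3P = p[["V_TPI_GA3P"]] *
      hill(s[["GA3P"]], p[["Km_TPIGA3P"]], p[["n_GA3P"]]),
    R_Tri = p[["V_Tri"]] * hill(s[["GA"]], p[["Km_GA"]], p[["n_GA"]]) *
      hill(p[["ATPMg"]], p[["Km_ATPMg"]], p[["n_ATPMg"]]) *
      (1 - p[["beta_ATP"]] * p[["ATP"]] / (p[["Ki_ATP"]] + p[["ATP"]])) *
      (1 - p[["beta_ADP"]] * p[["ADP"]] / (p[["Ki_ADP"]] + p[["ADP"]])),
    R_PK = p[["V_PK"]] * hill(s[["GA3P"]], p[["Km_GA3P"]], p[["n_GA3P"]]) *
      hill(p[["ADP"]], p[["Km_ADPpk"]], p[["n_ADPpk"]]) *
      (1 - p[["beta_ACoA_PK"]] * s[["ACoA"]] /
         (p[["Ki_ACoA_PK"]] + s[["ACoA"]])),
    R_PEPCK = p[["V_PEPCK"]] * mm(s[["Pyr"]], p[["Km_PEPCK"]]) *
      mm(p[["ATP"]], p[["Km_ATPpepck"]]) * mm(p[["GTP"]], p[["Km_GTP"]]),
    R_PDC = p[["V_PDC"]] * mm(s[["Pyr"]], p[["Km_Pyr"]]) *
      (1 - p[["beta_ACoA_PDC"]] * s[["ACoA"]] /
         (s[["ACoA"]] + p[["ki_CoA_pyr"]])),
    R_FAS = p[["V_FAS"]] * mm(s[["ACoA"]], p[["Km_ACoA"]]) *
      mm(p[["ATP"]], p[["Km_ATPfas"]]) *
      (1 - p[["beta_FA"]] * s[["FA"]] / (s[["FA"]] + p[["ki_FA_inhib"]])),
    R_boxi = p[["V_boxi"]] * mm(s[["FA"]], p[["Km_boxi"]]) *
      mm(p[["ATP"]], p[["Km_ATPboxi"]]) *
      (1 - p[["beta_boxi"]] * s[["ACoA"]] /
         (s[["ACoA"]] + p[["ki_CoA_boxi"]])) *
      (1 - p[["beta_PPARa"]] * s[["F1P"]] /
         (s[["F1P"]] + p[["ki_F1P_inhib"]])),
    R_TGS = p[["V_TGS"]] * mm(s[["FA"]], p[["Km_FA"]]) *
      mm(s[["GA3P"]], p[["Km_TGSGA3P"]]),
    R_Lply = p[["V_Lply"]] * mm(s[["TG"]], p[["Km_TG"]]),
    R_GK = p[["V_GK"]] * hill(s[["Glu"]], p[["Km_Glu"]], p[["n_Glu"]]) *
      hill(p[["ATP"]], p[["Km_ATPgk"]], p[["n_ATP"]]) *
      (1 - s[["G6P"]] / (s[["G6P"]] + p[["ki_G6P"]])),
    R_G6Pase = p[["V_G6Pase"]] * mm(s[["G6P"]], p[["Km_G6Pase"]]),
    R_FBP = p[["V_FBP"]] * mm(s[["GA3P"]], p[["Km_FBP"]]),
    R_PFK = p[["V_PFK"]] * mm(s[["G6P"]], p[["Km_PFK"]]) *
      mm(p[["ATP"]], p[["Km_ATPpfk"]]) *
      (1 - mm(p[["ATP"]], p[["ki_ATPfpk"]]) *
             mm(p[["ADP"]], p[["ki_ADPfpk"]])) *
      (1 - p[["beta_PFK"]] * s[["GA3P"]] /
         (s[["GA3P"]] + p[["ki_GA3Ppfk"]]))
  )
}
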