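#' @useDynLib ecbstdp, .registration = TRUE
#' @importFrom stats approx convolve lm coef var setNames runif
#' @importFrom utils modifyList write.csv
NULL

# Parameter registry -----------------------------------------------------
#
# One row per model constant: default value, unit, short description.
# Time is in seconds, voltage in mV, concentrations in uM (glutamate in mM),
# currents in pA, conductances in nS, capacitance in pF throughout.

.param_registry <- function() {
  p <- function(name, value, unit, desc) {
    data.frame(name = name, value = value, unit = unit, desc = desc,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # -- membrane -------------------------------------------------------
    p("C_m",        50,     "pF",    "membrane capacitance of the isopotential compartment"),
    p("g_L",        5,      "nS",    "leak conductance"),
    p("V_L",        -75,    "mV",    "leak reversal potential (MSN resting potential)"),
    p("g_AMPA",     2.5,    "nS",    "AMPAR maximal conductance"),
    p("E_AMPA",     0,      "mV",    "AMPAR reversal potential"),
    p("alpha_AMPA", 1100,   "1/(mM s)", "AMPAR two-state binding rate"),
    p("beta_AMPA",  190,    "1/s",   "AMPAR two-state unbinding rate"),
    p("g_NMDA",     2.0,    "nS",    "NMDAR maximal conductance"),
    p("E_NMDA",     0,      "mV",    "NMDAR reversal potential"),
    p("alpha_NMDA", 72,     "1/(mM s)", "NMDAR two-state binding rate"),
    p("beta_NMDA",  6.6,    "1/s",   "NMDAR two-state unbinding rate"),
    p("Mg",         1.0,    "mM",    "extracellular magnesium"),
    p("Mg_slope",   0.062,  "1/mV",  "voltage sensitivity of the NMDAR Mg block"),
    p("Mg_scale",   3.57,   "mM",    "concentration scale of the NMDAR Mg block"),
    p("g_VSCC",     1.4,    "nS",    "L-type (Cav1.3) calcium channel maximal conductance"),
    p("vscc_form",  0,      "flag",  "VSCC driving force: 0 = constant-field (GHK), 1 = ohmic"),
    p("E_Ca",       40,     "mV",    "calcium reversal potential for the ohmic VSCC variant"),
    p("V_m_VSCC",   -33,    "mV",    "Cav1.3 activation midpoint"),
    p("k_m_VSCC",   6.7,    "mV",    "Cav1.3 activation slope"),
    p("tau_m_VSCC", 0.001,  "s",     "Cav1.3 activation time constant"),
    p("V_h_VSCC",   -13.4,  "mV",    "Cav1.3 inactivation midpoint"),
    p("k_h_VSCC",   11.9,   "mV",    "Cav1.3 inactivation slope"),
    p("tau_h_VSCC", 0.045,  "s",     "Cav1.3 inactivation time constant"),
    p("Ca_out",     2000,   "uM",    "extracellular calcium (GHK driving force)"),
    p("g_TRPV1",    0.9,    "nS",    "TRPV1 maximal conductance"),
    p("V_half_TRPV1", 60,   "mV",    "TRPV1 voltage activation midpoint without agonist"),
    p("k_V_TRPV1",  18,     "mV",    "TRPV1 voltage activation slope"),
    p("dV_AEA",     130,    "mV",    "leftward shift of the TRPV1 midpoint at saturating AEA"),
    p("K_AEA_TRPV1", 0.7,   "uM",    "AEA concentration of half-maximal TRPV1 midpoint shift"),
    p("n_AEA_TRPV1", 2,     "-",     "Hill exponent of the AEA shift of TRPV1 gating"),
    # -- stimuli --------------------------------------------------------
    p("G_max",      1.0,    "mM",    "peak cleft glutamate per presynaptic spike"),
    p("tau_G",      0.006,  "s",     "glutamate clearance time constant"),
    p("DC_max",     175,    "pA",    "amplitude of the somatic step depolarization current"),
    p("DC_dur",     0.030,  "s",     "duration of the step depolarization"),
    p("AP_max",     1500,   "pA",    "amplitude of the bAP action current transient"),
    p("delta",      0.003,  "s",     "delay from step onset to the bAP transient"),
    p("tau_bAP",    0.002,  "s",     "decay time constant of the bAP transient"),
    # -- calcium --------------------------------------------------------
    p("B_T",        20,     "uM",    "total endogenous fast calcium buffer"),
    p("K_dB",       0.5,    "uM",    "dissociation constant of the endogenous buffer"),
    p("Ca_b",       0.1,    "uM",    "basal cytosolic calcium"),
    p("tau_Cab",    0.025,  "s",     "relaxation time of cytosolic calcium to basal level"),
    p("rho_ER",     0.07,    "-",     "cytosol-to-ER effective volume ratio"),
    p("r_IP3R",     1000,    "1/s",   "maximal IP3R (CICR) release rate"),
    p("r_leak",     0.004,   "1/s",   "ER leak rate"),
    p("v_SERCA",    4,    "uM/s",  "maximal SERCA pump rate"),
    p("K_SERCA",    0.2,    "uM",    "SERCA half-activation calcium"),
    p("d1_IP3R",    0.8,   "uM",    "IP3R IP3 binding constant"),
    p("d2_IP3R",    0.5,  "uM",    "IP3R calcium inactivation constant"),
    p("d3_IP3R",    0.9434, "uM",    "IP3R IP3 constant of the inactivation gate"),
    p("d5_IP3R",    1.0,"uM",    "IP3R calcium activation constant"),
    p("a2_IP3R",    2,    "1/(uM s)", "IP3R inactivation gate rate"),
    p("v_beta",     16,    "uM/s",  "maximal mGluR/PLCbeta IP3 production rate"),
    p("K_R_glu",    0.35,   "mM",    "glutamate half-activation of mGluR/PLCbeta"),
    p("n_glu",      0.7,    "-",     "Hill exponent of glutamate activation of PLCbeta"),
    p("K_pi_Ca",    0.7,    "uM",    "calcium modulation constant of PLCbeta (n = 2)"),
    p("v_delta",    0.02,   "uM/s",  "maximal PLCdelta IP3 production rate"),
    p("kappa_delta", 1.5,   "uM",    "IP3 inhibition constant of PLCdelta"),
    p("K_delta_Ca", 0.3,    "uM",    "calcium half-activation of PLCdelta (n = 2)"),
    p("v_3K",       0.15,    "uM/s",  "maximal IP3 3-kinase rate (CaMKII dependent)"),
    p("K_3K",       1.0,    "uM",    "IP3 half-saturation of IP3 3-kinase"),
    p("r_5P",       0.15,    "1/s",   "IP5 phosphatase (linear) IP3 degradation rate"),
    p("xi_NMDA",    6,     "uM/(s pA)", "current-to-flux conversion for NMDAR calcium"),
    p("xi_VSCC",    3,     "uM/(s pA)", "current-to-flux conversion for VSCC calcium"),
    p("xi_TRPV1",   3,     "uM/(s pA)", "current-to-flux conversion for TRPV1 calcium"),
    # -- endocannabinoids ----------------------------------------------
    p("DAGLtot",    1.0,    "uM",    "total DAG lipase alpha concentration"),
    p("r_DGL",      60,     "1/s",   "maximal DAGLalpha rate (per uM enzyme)"),
    p("K_DAGL",     0.3,    "uM",    "DAGLalpha Michaelis constant for DAG"),
    p("r_DAGK",     2.5,    "1/s",   "DAG kinase (linear) DAG consumption rate"),
    p("r_MAGL",     2,    "1/s",   "MAG lipase 2-AG degradation rate (incl. spillover)"),
    p("r_k",        1.0,    "1/(uM^nc s)", "calcium activation rate of DAGLalpha"),
    p("r_p",        2.0,    "1/s",   "deactivation rate of DAGLalpha"),
    p("n_c",        4,      "-",     "calcium cooperativity of DAGLalpha activation"),
    p("nu_AT",      0.05,    "1/s",   "lumped N-acyltransferase rate of AEA synthesis"),
    p("r_FAAH",     1.0,    "uM/s",  "maximal FAAH AEA degradation rate"),
    p("K_FAAH",     1.0,    "uM",    "FAAH Michaelis constant for AEA"),
    # -- CB1R -----------------------------------------------------------
    p("alpha_CB1R", 15,    "1/(uM s)", "CB1R opening rate per unit agonist"),
    p("beta_CB1R",  2.0,    "1/s",   "CB1R closing rate"),
    p("gamma_CB1R", 0.26,   "1/s",   "CB1R desensitization rate"),
    p("epsilon_CB1R", 0.007, "1/s",   "CB1R recovery rate from desensitization"),
    p("A_endo",     0.10,   "-",     "AEA partial agonism factor at CB1R"),
    # -- presynaptic plasticity ----------------------------------------
    p("k_CB1R",     1.0,    "-",     "gain from open CB1R fraction to plasticity drive"),
    p("D_1",        0.0,    "-",     "tonic offset of the plasticity drive (e.g. dopamine)"),
    p("D_2",        0.0,    "-",     "tonic offset of the plasticity time-constant drive"),
    p("theta_LTD_start", 0.032, "-",  "lower threshold of the LTD band of the drive"),
    p("theta_LTD_stop",  0.075, "-",  "upper threshold of the LTD band"),
    p("theta_LTP_start", 0.082, "-",  "threshold above which LTP is induced"),
    p("A_LTD",      0.27,   "-",     "LTD depth of the threshold rule"),
    p("A_LTP",      1.0,    "-",     "LTP amplitude of the threshold rule"),
    p("P_1",        7.3e-9,   "s",     "time-constant scale of presynaptic plasticity"),
    p("P_2",        0.005,    "-",     "drive scale of the plasticity time constant"),
    p("P_3",        7,      "-",     "drive exponent of the plasticity time constant"),
    p("P_4",        2.0,    "s",     "floor of the plasticity time constant"),
    p("W_pre_max",  3.0,    "-",     "hard ceiling of the presynaptic weight"),
    p("w_post_gain", 3.5,   "-",     "postsynaptic weight gain per fully active CaMKII"),
    p("omega_form", 0,      "flag",  "plasticity rule: 0 = sharp thresholds, 1 = smooth"),
    p("k_S",        2,      "-",     "steepness factor of the smooth threshold rule"),
    # -- CaMKII subsystem ----------------------------------------------
    p("CaM_T",      0.1,    "uM",    "total calmodulin"),
    p("K_CaM",      1.3,    "uM",    "calcium half-activation of calmodulin (n = 4)"),
    p("K5_CaMKII",  0.1,    "uM",    "Ca4CaM dissociation constant from CaMKII subunits"),
    p("k6_CaMKII",  0.0055,      "1/s",   "initial (two-CaM) autophosphorylation rate"),
    p("k7_CaMKII",  1000,      "1/s",   "neighbour-directed autophosphorylation rate"),
    p("CaMKII_T",   3.3333, "uM",    "total CaMKII holoenzyme (6 subunits each)"),
    p("k12_PP1",    2,    "1/s",   "PP1 catalytic dephosphorylation rate"),
    p("K_M_PP1",    0.15,    "uM",    "PP1 Michaelis constant for phospho-CaMKII"),
    p("PP1_T",      0.2,    "uM",    "total protein phosphatase 1"),
    p("I1_T",       1.0,    "uM",    "total inhibitor-1 (DARPP-32 analogue)"),
    p("k3_I1PP1",   30,    "1/(uM s)", "PP1 / phospho-I1 association rate"),
    p("k4_I1PP1",   1,    "1/s",   "PP1 / phospho-I1 dissociation rate"),
    p("k_PKA0",     0.10, "1/s",   "basal PKA phosphorylation rate of I1"),
    p("k_PKA",      1.5,      "1/s",   "calcium-stimulated PKA rate of I1"),
    p("K_PKA",      2.2,    "uM",    "calcium half-activation of PKA"),
    p("n_PKA",      3,      "-",     "Hill exponent of PKA calcium activation"),
    p("k_CaN0",     0.01,   "1/s",   "basal calcineurin dephosphorylation rate of I1P"),
    p("k_CaN",      25,      "1/s",   "calcium-stimulated calcineurin rate"),
    p("K_CaN",      0.5,    "uM",    "calcium half-activation of calcineurin"),
    p("n_CaN",      3,      "-",     "Hill exponent of calcineurin calcium activation"),
    # -- knockout flags (set through apply_variant) --------------------
    p("nmdar_ko",   0,      "flag",  "1 removes calmodulin/CaMKII signalling (W_post = 1)"),
    p("cb1r_ko",    0,      "flag",  "1 clamps CB1R activation to zero"),
    # -- numerics -------------------------------------------------------
    p("atol",       1e-7,   "-",     "absolute integration tolerance"),
    p("rtol",       1e-7,   "-",     "relative integration tolerance"),
    p("blur_sd",    3,      "ms",    "s.d. of the Gaussian spike-timing blur"),
    p("settle_time", 300,   "s",     "post-protocol horizon before weights are read out")
  ))
}

# names that may legitimately be zero or negative
.non_positive_ok <- c("V_L", "E_AMPA", "E_NMDA", "V_m_VSCC", "V_h_VSCC",
                      "D_1", "D_2", "nmdar_ko", "cb1r_ko", "vscc_form",
                      "omega_form")

#' Default model parameters
#'
#' Returns the full parameter set of the corticostriatal STDP signalling
#' model: membrane and channel constants, stimulus shapes, calcium/ER
#' dynamics, the endocannabinoid cascade, CB1R kinetics, the presynaptic
#' threshold plasticity rule, the CaMKII subsystem and numerical settings.
#' All time constants are in seconds, concentrations in micromolar
#' (glutamate in millimolar), voltages in mV, currents in pA.
#'
#' @return A named list of class `ecb_params`.
#' @export
#' @examples
#' ps <- default_parameters()
#' ps$n_PKA      # 3
#' ps$W_pre_max  # 3.0
default_parameters <- function() {
  reg <- .param_registry()
  ps <- as.list(setNames(reg$value, reg$name))
  class(ps) <- "ecb_params"
  validate_parameters(ps)
  ps
}

#' Validate a parameter set
#'
#' Checks that every registry symbol is present (and nothing else), that
#' rates, conductances and concentrations are strictly positive, and that
#' the plasticity thresholds are ordered
#' `theta_LTD_start < theta_LTD_stop < theta_LTP_start`.
#'
#' @param ps named list of parameters.
#' @return `ps`, invisibly, on success; otherwise an error naming the
#'   offending symbol(s).
#' @export
validate_parameters <- function(ps) {
  reg <- .param_registry()
  missing <- setdiff(reg$name, names(ps))
  if (length(missing))
    stop("parameter set is missing symbol(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(ps), reg$name)
  if (length(unknown))
    stop("unknown parameter symbol(s): ", paste(unknown, collapse = ", "))
  vals <- unlist(ps[reg$name])
  if (any(!is.finite(vals)))
    stop("non-finite value for: ",
         paste(reg$name[!is.finite(vals)], collapse = ", "))
  must_pos <- setdiff(reg$name, .non_positive_ok)
  bad <- must_pos[vals[must_pos] <= 0 & !(must_pos %in% c("nmdar_ko", "cb1r_ko"))]
  # knockout flags are 0/1; enzyme rates may be scaled to exactly 0 by a variant
  scalable <- c("r_MAGL", "r_DAGK", "r_DGL", "r_FAAH", "alpha_CB1R", "CaM_T")
  bad <- setdiff(bad, scalable[vals[scalable] == 0])
  if (length(bad))
    stop("non-positive value for strictly positive parameter(s): ",
         paste(bad, collapse = ", "))
  if (!(ps$theta_LTD_start < ps$theta_LTD_stop &&
        ps$theta_LTD_stop < ps$theta_LTP_start))
    stop("thresholds must satisfy theta_LTD_start < theta_LTD_stop < theta_LTP_start")
  if (ps$A_LTD <= 0 || ps$A_LTD > 1) stop("A_LTD must lie in (0, 1]")
  if (ps$A_LTP <= 0) stop("A_LTP must be positive")
  invisible(ps)
}

#' Read a parameter configuration file
#'
#' The file is flat YAML, one `symbol: value` pair per line with units and
#' provenance in end-of-line comments. The document must supply every
#' registry symbol; unknown keys are rejected.
#'
#' @param path path to the YAML document.
#' @return validated parameter set (class `ecb_params`).
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  doc <- yaml::read_yaml(path)
  ps <- lapply(doc, as.numeric)
  class(ps) <- "ecb_params"
  validate_parameters(ps)
  ps
}

#' Write a parameter set to a configuration file
#'
#' Values are written at full double precision so that a written set reloads
#' field-for-field identical; units and descriptions go into comments.
#'
#' @param ps parameter set.
#' @param path output path.
#' @export
write_parameters <- function(ps, path) {
  validate_parameters(ps)
  reg <- .param_registry()
  lines <- c("# ecbstdp model parameters (flat YAML; units in comments)",
             sprintf("%s: %s  # [%s] %s", reg$name,
                     vapply(ps[reg$name], function(v)
                       format(v, digits = 17, scientific = FALSE), ""),
                     reg$unit, reg$desc))
  writeLines(lines, path)
  invisible(path)
}

#' Export a resolved parameter set as JSON (provenance record)
#'
#' @param ps parameter set.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
parameters_json <- function(ps, path = NULL) {
  validate_parameters(ps)
  js <- jsonlite::toJSON(unclass(ps), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  js
}

# Model variants ---------------------------------------------------------

#' Describe a model variant (knockouts and enzyme inhibition)
#'
#' @param nmdar_knockout remove the signalling pathway downstream of NMDAR
#'   (calmodulin and CaMKII), forcing the postsynaptic weight to 1.
#' @param cb1r_knockout clamp CB1R activation to zero whatever the
#'   endocannabinoid level.
#' @param enzyme_scales named numeric vector of fractions in `[0, 1]`
#'   applied to enzyme maximal rates; recognised names are `MAGL`, `DAGK`,
#'   `DAGL` and `FAAH`.
#' @return an object of class `ecb_variant`.
#' @export
#' @examples
#' model_variant(enzyme_scales = c(MAGL = 0, DAGK = 0.05))
model_variant <- function(nmdar_knockout = FALSE, cb1r_knockout = FALSE,
                          enzyme_scales = numeric(0)) {
  known <- c("MAGL", "DAGK", "DAGL", "FAAH")
  if (length(enzyme_scales)) {
    if (is.null(names(enzyme_scales)) || !all(names(enzyme_scales) %in% known))
      stop("enzyme_scales names must be among: ", paste(known, collapse = ", "))
    if (any(enzyme_scales < 0 | enzyme_scales > 1))
      stop("enzyme scale fractions must lie in [0, 1]")
  }
  structure(list(nmdar_knockout = isTRUE(nmdar_knockout),
                 cb1r_knockout = isTRUE(cb1r_knockout),
                 enzyme_scales = enzyme_scales),
            class = "ecb_variant")
}

#' Apply a model variant to a parameter set
#'
#' Returns a new parameter set; the base set is left untouched. Enzyme
#' maximal rates are multiplied by the given fractions, the CB1R knockout
#' zeroes the receptor activation rate so its open fraction stays null, and
#' the NMDAR knockout removes calmodulin so no CaMKII is ever activated and
#' the postsynaptic weight remains 1.
#'
#' @param base parameter set.
#' @param variant an `ecb_variant`.
#' @return modified parameter set.
#' @export
apply_variant <- function(base, variant) {
  validate_parameters(base)
  stopifnot(inherits(variant, "ecb_variant"))
  ps <- base
  map <- c(MAGL = "r_MAGL", DAGK = "r_DAGK", DAGL = "r_DGL", FAAH = "r_FAAH")
  for (enz in names(variant$enzyme_scales))
    ps[[map[[enz]]]] <- ps[[map[[enz]]]] * unname(variant$enzyme_scales[[enz]])
  if (variant$cb1r_knockout) {
    ps$cb1r_ko <- 1
    ps$alpha_CB1R <- 0
  }
  if (variant$nmdar_knockout) {
    ps$nmdar_ko <- 1
    ps$CaM_T <- 0
  }
  validate_parameters(ps)
  ps
}

#' @export
print.ecb_params <- function(x, ...) {
  cat("<ecb_params> ", length(x), " model parameters",
      if (x$nmdar_ko) " [NMDAR-pathway KO]" else "",
      if (x$cb1r_ko) " [CB1R KO]" else "", "\n", sep = "")
  invisible(x)
}
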