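# Reference (pure R) right-hand side of the full model -------------------
#
# The compiled C right-hand side in src/ is the one the integrator uses;
# the functions here are its readable reference, exercised unit-by-unit in
# the tests and compared against the compiled version at random states.

.state_names <- c("V", "r_AMPA", "r_NMDA", "m_VSCC", "h_VSCC",
                  "Ca", "Ca_ER", "h_IP3R", "IP3", "DAG", "AG2", "AEA",
                  "phi_DAGL", "x_CB1R", "d_CB1R", "W_pre", "I1P", "PP1",
                  paste0("B", 1:13))

#' State variable names of the full ODE system
#' @return character vector (length 31) in integration order.
#' @export
state_names <- function() .state_names

# Membrane ----------------------------------------------------------------

#' Two-state receptor gating derivatives
#'
#' Closed/open kinetics `dr/dt = alpha G (1 - r) - beta r` for AMPAR and
#' NMDAR, driven by cleft glutamate.
#'
#' @param r_AMPA,r_NMDA bound receptor fractions.
#' @param G cleft glutamate (mM).
#' @param ps parameter set.
#' @return list with `dr_AMPA` and `dr_NMDA` (1/s).
#' @export
receptor_gating_rhs <- function(r_AMPA, r_NMDA, G, ps) {
  list(dr_AMPA = ps$alpha_AMPA * G * (1 - r_AMPA) - ps$beta_AMPA * r_AMPA,
       dr_NMDA = ps$alpha_NMDA * G * (1 - r_NMDA) - ps$beta_NMDA * r_NMDA)
}

.mg_block <- function(V, ps) 1 / (1 + exp(-ps$Mg_slope * V) * ps$Mg / ps$Mg_scale)

.ghk_drive <- function(V, Ca, ps) {
  u <- V / 13.35                      # zFV/RT, z = 2, RT/F = 26.7 mV
  a <- Ca / ps$Ca_out
  if (abs(u) < 1e-6) return(26.7 * (a - 1))
  26.7 * u * (a - exp(-u)) / (1 - exp(-u))
}

.trpv1_open <- function(V, AEA, ps) {
  n <- ps$n_AEA_TRPV1
  shift <- ps$dV_AEA * AEA^n / (AEA^n + ps$K_AEA_TRPV1^n)
  1 / (1 + exp(-(V - (ps$V_half_TRPV1 - shift)) / ps$k_V_TRPV1))
}

#' Synaptic and channel currents
#'
#' AMPAR/NMDAR ohmic currents scaled by their bound fractions (NMDAR with
#' the voltage-dependent magnesium block at 1 mM Mg), the Cav1.3 VSCC
#' current (constant-field driving force by default, ohmic as a variant)
#' and the TRPV1 current gated by voltage and anandamide.
#'
#' @param V membrane potential (mV).
#' @param r_AMPA,r_NMDA bound receptor fractions.
#' @param m_VSCC,h_VSCC Cav1.3 gates.
#' @param Ca cytosolic calcium (uM).
#' @param AEA anandamide (uM).
#' @param ps parameter set.
#' @return list `I_AMPA`, `I_NMDA`, `I_VSCC`, `I_TRPV1` in pA (negative =
#'   inward).
#' @export
synaptic_currents <- function(V, r_AMPA, r_NMDA, m_VSCC, h_VSCC, Ca, AEA, ps) {
  I_AMPA <- ps$g_AMPA * r_AMPA * (V - ps$E_AMPA)
  I_NMDA <- ps$g_NMDA * r_NMDA * .mg_block(V, ps) * (V - ps$E_NMDA)
  drive <- if (ps$vscc_form > 0.5) (V - ps$E_Ca) else .ghk_drive(V, Ca, ps)
  I_VSCC <- ps$g_VSCC * m_VSCC * h_VSCC * drive
  I_TRPV1 <- ps$g_TRPV1 * V * .trpv1_open(V, AEA, ps)
  list(I_AMPA = I_AMPA, I_NMDA = I_NMDA, I_VSCC = I_VSCC, I_TRPV1 = I_TRPV1)
}

#' Membrane potential derivative
#'
#' `C_m dV/dt = -g_L (V - V_L) - I_AMPA - I_NMDA - I_VSCC - I_TRPV1 -
#' I_act`; the action current is negative when depolarizing.
#'
#' @param V membrane potential (mV).
#' @param currents list as returned by [synaptic_currents()].
#' @param I_act action current (pA).
#' @param ps parameter set.
#' @return dV/dt in mV/s.
#' @export
membrane_rhs <- function(V, currents, I_act, ps) {
  1000 * (-ps$g_L * (V - ps$V_L) - currents$I_AMPA - currents$I_NMDA -
            currents$I_VSCC - currents$I_TRPV1 - I_act) / ps$C_m
}

# Calcium -----------------------------------------------------------------

#' Rapid-buffer time-scaling factor
#'
#' Quasi-steady-state factor of the endogenous calcium buffer,
#' `T(x) = 1 + B_T K_dB / (K_dB + x)^2`, applied to both cytosolic and ER
#' calcium equations.
#'
#' @param x calcium concentration (uM).
#' @param ps parameter set.
#' @return dimensionless factor >= 1.
#' @export
buffer_factor <- function(x, ps) 1 + ps$B_T * ps$K_dB / (ps$K_dB + x)^2

#' CICR fluxes between ER and cytosol
#'
#' IP3-receptor release (Li-Rinzel gating with slow inactivation gate
#' `h_IP3R`), saturable SERCA uptake and passive leak.
#'
#' @param Ca,Ca_ER,IP3,h_IP3R state components.
#' @param ps parameter set.
#' @return list `J_IP3R`, `J_SERCA`, `J_leak` (uM/s).
#' @export
cicr_fluxes <- function(Ca, Ca_ER, IP3, h_IP3R, ps) {
  m_inf <- IP3 / (IP3 + ps$d1_IP3R)
  n_inf <- Ca / (Ca + ps$d5_IP3R)
  J_IP3R <- ps$r_IP3R * (m_inf * n_inf * h_IP3R)^3 * (Ca_ER - Ca)
  J_SERCA <- ps$v_SERCA * Ca^2 / (Ca^2 + ps$K_SERCA^2)
  J_leak <- ps$r_leak * (Ca_ER - Ca)
  list(J_IP3R = J_IP3R, J_SERCA = J_SERCA, J_leak = J_leak)
}

.h_ip3r_rhs <- function(Ca, IP3, h, ps) {
  Q2 <- ps$d2_IP3R * (IP3 + ps$d1_IP3R) / (IP3 + ps$d3_IP3R)
  ps$a2_IP3R * (Q2 * (1 - h) - Ca * h)
}

#' PLC production term shared by IP3 and DAG
#'
#' Glutamate-driven, calcium-modulated PLCbeta plus calcium-dependent
#' PLCdelta (inhibited by its IP3 product).
#'
#' @param Ca,IP3 state components (uM).
#' @param G cleft glutamate (mM).
#' @param ps parameter set.
#' @return production rate (uM/s).
#' @export
plc_production <- function(Ca, IP3, G, ps) {
  J_beta <- ps$v_beta * G^ps$n_glu / (G^ps$n_glu + ps$K_R_glu^ps$n_glu) *
    Ca^2 / (Ca^2 + ps$K_pi_Ca^2)
  J_delta <- ps$v_delta / (1 + IP3 / ps$kappa_delta) *
    Ca^2 / (Ca^2 + ps$K_delta_Ca^2)
  J_beta + J_delta
}

#' IP3 derivative
#'
#' Production by PLCbeta/PLCdelta minus degradation by the linear IP-5P
#' branch and by IP3-3K; the IP3-3K branch is driven by the activated
#' CaMKII fraction taken from the CaMKII subsystem state, not by a Hill
#' proxy of calcium.
#'
#' @param Ca,IP3 state components.
#' @param G glutamate (mM).
#' @param camkii_act phosphorylated CaMKII subunit concentration (uM).
#' @param ps parameter set.
#' @return dIP3/dt (uM/s).
#' @export
ip3_rhs <- function(Ca, IP3, G, camkii_act, ps) {
  act_max <- 6 * ps$CaMKII_T
  frac <- if (act_max > 0) camkii_act / act_max else 0
  plc_production(Ca, IP3, G, ps) -
    ps$v_3K * frac * IP3 / (IP3 + ps$K_3K) -
    ps$r_5P * IP3
}

#' Cytosolic and ER calcium derivatives
#'
#' @param Ca,Ca_ER,IP3,h_IP3R state components.
#' @param currents list from [synaptic_currents()].
#' @param ps parameter set.
#' @return list `dCa`, `dCa_ER` (uM/s).
#' @export
calcium_rhs <- function(Ca, Ca_ER, IP3, h_IP3R, currents, ps) {
  fl <- cicr_fluxes(Ca, Ca_ER, IP3, h_IP3R, ps)
  net <- fl$J_IP3R - fl$J_SERCA + fl$J_leak
  influx <- -ps$xi_NMDA * currents$I_NMDA - ps$xi_VSCC * currents$I_VSCC -
    ps$xi_TRPV1 * currents$I_TRPV1
  dCa <- (net - (Ca - ps$Ca_b) / ps$tau_Cab + influx) / buffer_factor(Ca, ps)
  dCa_ER <- -ps$rho_ER * net / buffer_factor(Ca_ER, ps)
  list(dCa = dCa, dCa_ER = dCa_ER)
}

# Endocannabinoids --------------------------------------------------------

#' DAGLalpha calcium-activation derivative
#'
#' `dphi/dt = r_k C^n_c (1 - phi) - r_p phi`.
#'
#' @param phi activated DAGLalpha fraction.
#' @param Ca cytosolic calcium (uM).
#' @param ps parameter set.
#' @return dphi/dt (1/s).
#' @export
dagl_activation_rhs <- function(phi, Ca, ps)
  ps$r_k * Ca^ps$n_c * (1 - phi) - ps$r_p * phi

#' DAG and 2-AG derivatives
#'
#' DAG is co-produced with IP3 by PLC, consumed by activated DAGLalpha
#' (producing 2-AG) and by DAG kinase; 2-AG is degraded by MAG lipase.
#'
#' @param DAG,AG2,phi state components.
#' @param R_P PLC production rate (uM/s).
#' @param ps parameter set.
#' @return list `dDAG`, `dAG2` (uM/s).
#' @export
dag_2ag_rhs <- function(DAG, AG2, phi, R_P, ps) {
  v_DGL <- ps$r_DGL * ps$DAGLtot * phi * DAG / (DAG + ps$K_DAGL)
  list(dDAG = R_P - v_DGL - ps$r_DAGK * DAG,
       dAG2 = v_DGL - ps$r_MAGL * AG2)
}

#' Anandamide derivative
#'
#' Calcium-driven synthesis through the (quasi-steady-state) NAPE pathway
#' minus saturable FAAH degradation:
#' `dAEA/dt = nu_AT C - r_FAAH AEA / (K_FAAH + AEA)`.
#'
#' @param AEA anandamide (uM).
#' @param Ca cytosolic calcium (uM).
#' @param ps parameter set.
#' @return dAEA/dt (uM/s).
#' @export
aea_rhs <- function(AEA, Ca, ps)
  ps$nu_AT * Ca - ps$r_FAAH * AEA / (ps$K_FAAH + AEA)

#' CB1R three-state kinetics
#'
#' Open (`x`), desensitized (`d`) and inactivated (`1 - x - d`) receptor
#' fractions driven by the agonist mix `eCB = 2-AG + 0.10 AEA`.
#'
#' @param x,d open and desensitized fractions.
#' @param AG2,AEA agonist concentrations (uM).
#' @param ps parameter set.
#' @return list `dx`, `dd` (1/s) and the agonist level `eCB`.
#' @export
cb1r_rhs <- function(x, d, AG2, AEA, ps) {
  eCB <- AG2 + ps$A_endo * AEA
  list(dx = ps$alpha_CB1R * eCB * (1 - x - d) -
         (ps$beta_CB1R + ps$gamma_CB1R) * x,
       dd = -ps$epsilon_CB1R * d + ps$gamma_CB1R * x,
       eCB = eCB)
}

# Presynaptic plasticity ---------------------------------------------------

#' Sharp three-threshold plasticity rule
#'
#' Target level of the presynaptic weight as a function of the CB1R
#' plasticity drive: 1 below `theta_LTD_start` and in the dead zone
#' between `theta_LTD_stop` and `theta_LTP_start`; `1 - A_LTD` inside the
#' LTD band; `1 + A_LTP` above `theta_LTP_start`.
#'
#' @param y plasticity drive (dimensionless, vectorised).
#' @param ps parameter set.
#' @return target weight level.
#' @export
omega <- function(y, ps) {
  out <- rep(1, length(y))
  out[y >= ps$theta_LTD_start & y <= ps$theta_LTD_stop] <- 1 - ps$A_LTD
  out[y > ps$theta_LTP_start] <- 1 + ps$A_LTP
  out
}

#' Smooth variant of the threshold rule
#'
#' Continuous sigmoidal composition that approaches [omega()] pointwise
#' (away from the thresholds) as the steepness factor `k_S` grows; the
#' transition width of each threshold is `theta / (10 k_S)`.
#'
#' @param y plasticity drive (vectorised).
#' @param ps parameter set.
#' @param k_S steepness factor (default from `ps`).
#' @return smooth target weight level.
#' @export
omega_smooth <- function(y, ps, k_S = ps$k_S) {
  if (k_S <= 0) stop("k_S must be positive")
  sig <- function(u) 1 / (1 + exp(-u))
  w1 <- ps$theta_LTD_start / (10 * k_S)
  w2 <- ps$theta_LTD_stop / (10 * k_S)
  w3 <- ps$theta_LTP_start / (10 * k_S)
  ltd <- sig((y - ps$theta_LTD_start) / w1) * sig((ps$theta_LTD_stop - y) / w2)
  ltp <- sig((y - ps$theta_LTP_start) / w3)
  1 - ps$A_LTD * ltd + ps$A_LTP * ltp
}

#' Presynaptic plasticity time constant
#'
#' `tau(x) = P_1 / (P_2^P_3 + x^P_3) + P_4`: fast weight changes at high
#' CB1R drive, nearly frozen weights (memory) at rest.
#'
#' @param x time-constant drive (dimensionless, vectorised).
#' @param ps parameter set.
#' @return time constant in s.
#' @export
tau_wpre <- function(x, ps) ps$P_1 / (ps$P_2^ps$P_3 + x^ps$P_3) + ps$P_4

#' Presynaptic weight derivative
#'
#' Relaxation of `W_pre` toward the threshold-rule target with the
#' state-dependent time constant; the ceiling at `W_pre_max` is enforced
#' as derivative truncation so trajectories stay continuous.
#'
#' @param W_pre presynaptic weight.
#' @param x_CB1R open CB1R fraction.
#' @param ps parameter set.
#' @return dW_pre/dt (1/s).
#' @export
wpre_rhs <- function(W_pre, x_CB1R, ps) {
  y <- ps$k_CB1R * x_CB1R + ps$D_1
  target <- if (ps$omega_form > 0.5) omega_smooth(y, ps) else omega(y, ps)
  tau <- tau_wpre(ps$k_CB1R * x_CB1R + ps$D_2, ps)
  dW <- (target - W_pre) / tau
  if (W_pre >= ps$W_pre_max && dW > 0) dW <- 0
  dW
}

#' Total synaptic weight
#'
#' @param W_pre,W_post component weights.
#' @return their product; 1 means no plasticity.
#' @export
total_weight <- function(W_pre, W_post) W_pre * W_post

# Full system --------------------------------------------------------------

#' Full model right-hand side (reference implementation)
#'
#' Assembles all module derivatives for a named state vector; used as the
#' readable reference for the compiled right-hand side and by the unit
#' tests. Not intended for production integration (use [run_protocol()]).
#'
#' @param t time (s).
#' @param y named state vector (see [state_names()]).
#' @param ps parameter set.
#' @param protocol an `stdp_protocol` (or `NULL` for no stimulation).
#' @return derivative vector in state order.
#' @export
model_rhs <- function(t, y, ps, protocol = NULL) {
  y <- setNames(as.numeric(y), .state_names)
  G <- if (is.null(protocol)) 0 else glutamate_concentration(t, protocol, ps)
  I_act <- if (is.null(protocol)) 0 else action_current(t, protocol, ps)
  cur <- synaptic_currents(y["V"], y["r_AMPA"], y["r_NMDA"], y["m_VSCC"],
                           y["h_VSCC"], y["Ca"], y["AEA"], ps)
  gates <- receptor_gating_rhs(y["r_AMPA"], y["r_NMDA"], G, ps)
  m_inf <- 1 / (1 + exp(-(y["V"] - ps$V_m_VSCC) / ps$k_m_VSCC))
  h_inf <- 1 / (1 + exp((y["V"] - ps$V_h_VSCC) / ps$k_h_VSCC))
  ca <- calcium_rhs(y["Ca"], y["Ca_ER"], y["IP3"], y["h_IP3R"], cur, ps)
  ck <- camkii_subsystem_rhs(list(B = y[paste0("B", 1:13)],
                                  I1P = y["I1P"], PP1 = y["PP1"]),
                             y["Ca"], ps)
  R_P <- plc_production(y["Ca"], y["IP3"], G, ps)
  ecb <- dag_2ag_rhs(y["DAG"], y["AG2"], y["phi_DAGL"], R_P, ps)
  cb <- cb1r_rhs(y["x_CB1R"], y["d_CB1R"], y["AG2"], y["AEA"], ps)
  unname(c(
    membrane_rhs(y["V"], cur, I_act, ps),
    gates$dr_AMPA, gates$dr_NMDA,
    (m_inf - y["m_VSCC"]) / ps$tau_m_VSCC,
    (h_inf - y["h_VSCC"]) / ps$tau_h_VSCC,
    ca$dCa, ca$dCa_ER,
    .h_ip3r_rhs(y["Ca"], y["IP3"], y["h_IP3R"], ps),
    ip3_rhs(y["Ca"], y["IP3"], G, ck$CaMKII_act, ps),
    ecb$dDAG, ecb$dAG2,
    aea_rhs(y["AEA"], y["Ca"], ps),
    dagl_activation_rhs(y["phi_DAGL"], y["Ca"], ps),
    cb$dx, cb$dd,
    wpre_rhs(y["W_pre"], y["x_CB1R"], ps),
    ck$dI1P, ck$dPP1,
    ck$dB))
}
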