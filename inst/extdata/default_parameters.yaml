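# ecbstdp model parameters (flat YAML; units in comments)
C_m: 50  # [pF] membrane capacitance of the isopotential compartment
g_L: 5  # [nS] leak conductance
V_L: -75  # [mV] leak reversal potential (MSN resting potential)
g_AMPA: 2.5  # [nS] AMPAR maximal conductance
E_AMPA: 0  # [mV] AMPAR reversal potential
alpha_AMPA: 1100  # [1/(mM s)] AMPAR two-state binding rate
beta_AMPA: 190  # [1/s] AMPAR two-state unbinding rate
g_NMDA: 2  # [nS] NMDAR maximal conductance
E_NMDA: 0  # [mV] NMDAR reversal potential
alpha_NMDA: 72  # [1/(mM s)] NMDAR two-state binding rate
beta_NMDA: 6.5999999999999996  # [1/s] NMDAR two-state unbinding rate
Mg: 1  # [mM] extracellular magnesium
Mg_slope: 0.062  # [1/mV] voltage sensitivity of the NMDAR Mg block
Mg_scale: 3.5699999999999998  # [mM] concentration scale of the NMDAR Mg block
g_VSCC: 1.3999999999999999  # [nS] L-type (Cav1.3) calcium channel maximal conductance
vscc_form: 0  # [flag] VSCC driving force: 0 = constant-field (GHK), 1 = ohmic
E_Ca: 40  # [mV] calcium reversal potential for the ohmic VSCC variant
V_m_VSCC: -33  # [mV] Cav1.3 activation midpoint
k_m_VSCC: 6.7000000000000002  # [mV] Cav1.3 activation slope
tau_m_VSCC: 0.001  # [s] Cav1.3 activation time constant
V_h_VSCC: -13.4  # [mV] Cav1.3 inactivation midpoint
k_h_VSCC: 11.9  # [mV] Cav1.3 inactivation slope
tau_h_VSCC: 0.044999999999999998  # [s] Cav1.3 inactivation time constant
Ca_out: 2000  # [uM] extracellular calcium (GHK driving force)
g_TRPV1: 0.90000000000000002  # [nS] TRPV1 maximal conductance
V_half_TRPV1: 60  # [mV] TRPV1 voltage activation midpoint without agonist
k_V_TRPV1: 18  # [mV] TRPV1 voltage activation slope
dV_AEA: 130  # [mV] leftward shift of the TRPV1 midpoint at saturating AEA
K_AEA_TRPV1: 0.69999999999999996  # [uM] AEA concentration of half-maximal TRPV1 midpoint shift
n_AEA_TRPV1: 2  # [-] Hill exponent of the AEA shift of TRPV1 gating
G_max: 1  # [mM] peak cleft glutamate per presynaptic spike
tau_G: 0.0060000000000000001  # [s] glutamate clearance time constant
DC_max: 175  # [pA] amplitude of the somatic step depolarization current
DC_dur: 0.029999999999999999  # [s] duration of the step depolarization
AP_max: 1500  # [pA] amplitude of the bAP action current transient
delta: 0.0030000000000000001  # [s] delay from step onset to the bAP transient
tau_bAP: 0.002  # [s] decay time constant of the bAP transient
B_T: 20  # [uM] total endogenous fast calcium buffer
K_dB: 0.5  # [uM] dissociation constant of the endogenous buffer
Ca_b: 0.10000000000000001  # [uM] basal cytosolic calcium
tau_Cab: 0.025000000000000001  # [s] relaxation time of cytosolic calcium to basal level
rho_ER: 0.070000000000000007  # [-] cytosol-to-ER effective volume ratio
r_IP3R: 1000  # [1/s] maximal IP3R (CICR) release rate
r_leak: 0.0040000000000000001  # [1/s] ER leak rate
v_SERCA: 4  # [uM/s] maximal SERCA pump rate
K_SERCA: 0.20000000000000001  # [uM] SERCA half-activation calcium
d1_IP3R: 0.80000000000000004  # [uM] IP3R IP3 binding constant
d2_IP3R: 0.5  # [uM] IP3R calcium inactivation constant
d3_IP3R: 0.94340000000000002  # [uM] IP3R IP3 constant of the inactivation gate
d5_IP3R: 1  # [uM] IP3R calcium activation constant
a2_IP3R: 2  # [1/(uM s)] IP3R inactivation gate rate
v_beta: 16  # [uM/s] maximal mGluR/PLCbeta IP3 production rate
K_R_glu: 0.34999999999999998  # [mM] glutamate half-activation of mGluR/PLCbeta
n_glu: 0.69999999999999996  # [-] Hill exponent of glutamate activation of PLCbeta
K_pi_Ca: 0.69999999999999996  # [uM] calcium modulation constant of PLCbeta (n = 2)
v_delta: 0.02  # [uM/s] maximal PLCdelta IP3 production rate
kappa_delta: 1.5  # [uM] IP3 inhibition constant of PLCdelta
K_delta_Ca: 0.29999999999999999  # [uM] calcium half-activation of PLCdelta (n = 2)
v_3K: 0.14999999999999999  # [uM/s] maximal IP3 3-kinase rate (CaMKII dependent)
K_3K: 1  # [uM] IP3 half-saturation of IP3 3-kinase
r_5P: 0.14999999999999999  # [1/s] IP5 phosphatase (linear) IP3 degradation rate
xi_NMDA: 6  # [uM/(s pA)] current-to-flux conversion for NMDAR calcium
xi_VSCC: 3  # [uM/(s pA)] current-to-flux conversion for VSCC calcium
xi_TRPV1: 3  # [uM/(s pA)] current-to-flux conversion for TRPV1 calcium
DAGLtot: 1  # [uM] total DAG lipase alpha concentration
r_DGL: 60  # [1/s] maximal DAGLalpha rate (per uM enzyme)
K_DAGL: 0.29999999999999999  # [uM] DAGLalpha Michaelis constant for DAG
r_DAGK: 2.5  # [1/s] DAG kinase (linear) DAG consumption rate
r_MAGL: 2  # [1/s] MAG lipase 2-AG degradation rate (incl. spillover)
r_k: 1  # [1/(uM^nc s)] calcium activation rate of DAGLalpha
r_p: 2  # [1/s] deactivation rate of DAGLalpha
n_c: 4  # [-] calcium cooperativity of DAGLalpha activation
nu_AT: 0.050000000000000003  # [1/s] lumped N-acyltransferase rate of AEA synthesis
r_FAAH: 1  # [uM/s] maximal FAAH AEA degradation rate
K_FAAH: 1  # [uM] FAAH Michaelis constant for AEA
alpha_CB1R: 15  # [1/(uM s)] CB1R opening rate per unit agonist
beta_CB1R: 2  # [1/s] CB1R closing rate
gamma_CB1R: 0.26000000000000001  # [1/s] CB1R desensitization rate
epsilon_CB1R: 0.0070000000000000001  # [1/s] CB1R recovery rate from desensitization
A_endo: 0.10000000000000001  # [-] AEA partial agonism factor at CB1R
k_CB1R: 1  # [-] gain from open CB1R fraction to plasticity drive
D_1: 0  # [-] tonic offset of the plasticity drive (e.g. dopamine)
D_2: 0  # [-] tonic offset of the plasticity time-constant drive
theta_LTD_start: 0.032000000000000001  # [-] lower threshold of the LTD band of the drive
theta_LTD_stop: 0.074999999999999997  # [-] upper threshold of the LTD band
theta_LTP_start: 0.082000000000000003  # [-] threshold above which LTP is induced
A_LTD: 0.27000000000000002  # [-] LTD depth of the threshold rule
A_LTP: 1  # [-] LTP amplitude of the threshold rule
P_1: 0.0000000073  # [s] time-constant scale of presynaptic plasticity
P_2: 0.0050000000000000001  # [-] drive scale of the plasticity time constant
P_3: 7  # [-] drive exponent of the plasticity time constant
P_4: 2  # [s] floor of the plasticity time constant
W_pre_max: 3  # [-] hard ceiling of the presynaptic weight
w_post_gain: 3.5  # [-] postsynaptic weight gain per fully active CaMKII
omega_form: 0  # [flag] plasticity rule: 0 = sharp thresholds, 1 = smooth
k_S: 2  # [-] steepness factor of the smooth threshold rule
CaM_T: 0.10000000000000001  # [uM] total calmodulin
K_CaM: 1.3  # [uM] calcium half-activation of calmodulin (n = 4)
K5_CaMKII: 0.10000000000000001  # [uM] Ca4CaM dissociation constant from CaMKII subunits
k6_CaMKII: 0.0054999999999999997  # [1/s] initial (two-CaM) autophosphorylation rate
k7_CaMKII: 1000  # [1/s] neighbour-directed autophosphorylation rate
CaMKII_T: 3.3332999999999999  # [uM] total CaMKII holoenzyme (6 subunits each)
k12_PP1: 2  # [1/s] PP1 catalytic dephosphorylation rate
K_M_PP1: 0.14999999999999999  # [uM] PP1 Michaelis constant for phospho-CaMKII
PP1_T: 0.20000000000000001  # [uM] total protein phosphatase 1
I1_T: 1  # [uM] total inhibitor-1 (DARPP-32 analogue)
k3_I1PP1: 30  # [1/(uM s)] PP1 / phospho-I1 association rate
k4_I1PP1: 1  # [1/s] PP1 / phospho-I1 dissociation rate
k_PKA0: 0.10000000000000001  # [1/s] basal PKA phosphorylation rate of I1
k_PKA: 1.5  # [1/s] calcium-stimulated PKA rate of I1
K_PKA: 2.2000000000000002  # [uM] calcium half-activation of PKA
n_PKA: 3  # [-] Hill exponent of PKA calcium activation
k_CaN0: 0.01  # [1/s] basal calcineurin dephosphorylation rate of I1P
k_CaN: 25  # [1/s] calcium-stimulated calcineurin rate
K_CaN: 0.5  # [uM] calcium half-activation of calcineurin
n_CaN: 3  # [-] Hill exponent of calcineurin calcium activation
nmdar_ko: 0  # [flag] 1 removes calmodulin/CaMKII signalling (W_post = 1)
cb1r_ko: 0  # [flag] 1 clamps CB1R activation to zero
atol: 0.000000099999999999999995  # [-] absolute integration tolerance
rtol: 0.000000099999999999999995  # [-] relative integration tolerance
blur_sd: 3  # [ms] s.d. of the Gaussian spike-timing blur
settle_time: 300  # [s] post-protocol horizon before weights are read out
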