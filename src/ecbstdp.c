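/* Compiled right-hand side of the corticostriatal STDP signalling model.
 *
 * Mirrors the reference implementation in R/model_rhs.R (which documents
 * the equations); kept in C because a full (dt, N, frequency) plasticity
 * map requires thousands of seconds of stiff model time.
 *
 * Parameter vector layout (packed by .pack_parms() on the R side):
 *   [0]                 NP, number of named parameters (122)
 *   [1 .. NP]           named parameters in registry order
 *   [NP+1 .. +196]      A6  (14 x 14, column major)  CaMKII ring, k6 g^2
 *   [.. +196]           A7                          CaMKII ring, k7 g
 *   [.. +196]           A12                         CaMKII ring, PP1
 *   [.. +14]            phospho-subunit count per ring class
 *   [next]              n_pre, pre event times, n_post, post event times
 */

#include <R.h>
#include <math.h>

#define MAXPAR 8192
static double pbuf[MAXPAR];
static int plen = 0;

void ecbstdp_init(void (*odeparms)(int *, double *))
{
    int n = MAXPAR;
    odeparms(&n, pbuf);   /* deSolve copies the full parms vector */
    plen = (int) pbuf[0]; /* only used as a sanity anchor */
}

#define par(i) pbuf[1 + (i)]

#define P_C_m par(0)
#define P_g_L par(1)
#define P_V_L par(2)
#define P_g_AMPA par(3)
#define P_E_AMPA par(4)
#define P_alpha_AMPA par(5)
#define P_beta_AMPA par(6)
#define P_g_NMDA par(7)
#define P_E_NMDA par(8)
#define P_alpha_NMDA par(9)
#define P_beta_NMDA par(10)
#define P_Mg par(11)
#define P_Mg_slope par(12)
#define P_Mg_scale par(13)
#define P_g_VSCC par(14)
#define P_vscc_form par(15)
#define P_E_Ca par(16)
#define P_V_m_VSCC par(17)
#define P_k_m_VSCC par(18)
#define P_tau_m_VSCC par(19)
#define P_V_h_VSCC par(20)
#define P_k_h_VSCC par(21)
#define P_tau_h_VSCC par(22)
#define P_Ca_out par(23)
#define P_g_TRPV1 par(24)
#define P_V_half_TRPV1 par(25)
#define P_k_V_TRPV1 par(26)
#define P_dV_AEA par(27)
#define P_K_AEA_TRPV1 par(28)
#define P_n_AEA_TRPV1 par(29)
#define P_G_max par(30)
#define P_tau_G par(31)
#define P_DC_max par(32)
#define P_DC_dur par(33)
#define P_AP_max par(34)
#define P_delta par(35)
#define P_tau_bAP par(36)
#define P_B_T par(37)
#define P_K_dB par(38)
#define P_Ca_b par(39)
#define P_tau_Cab par(40)
#define P_rho_ER par(41)
#define P_r_IP3R par(42)
#define P_r_leak par(43)
#define P_v_SERCA par(44)
#define P_K_SERCA par(45)
#define P_d1_IP3R par(46)
#define P_d2_IP3R par(47)
#define P_d3_IP3R par(48)
#define P_d5_IP3R par(49)
#define P_a2_IP3R par(50)
#define P_v_beta par(51)
#define P_K_R_glu par(52)
#define P_n_glu par(53)
#define P_K_pi_Ca par(54)
#define P_v_delta par(55)
#define P_kappa_delta par(56)
#define P_K_delta_Ca par(57)
#define P_v_3K par(58)
#define P_K_3K par(59)
#define P_r_5P par(60)
#define P_xi_NMDA par(61)
#define P_xi_VSCC par(62)
#define P_xi_TRPV1 par(63)
#define P_DAGLtot par(64)
#define P_r_DGL par(65)
#define P_K_DAGL par(66)
#define P_r_DAGK par(67)
#define P_r_MAGL par(68)
#define P_r_k par(69)
#define P_r_p par(70)
#define P_n_c par(71)
#define P_nu_AT par(72)
#define P_r_FAAH par(73)
#define P_K_FAAH par(74)
#define P_alpha_CB1R par(75)
#define P_beta_CB1R par(76)
#define P_gamma_CB1R par(77)
#define P_epsilon_CB1R par(78)
#define P_A_endo par(79)
#define P_k_CB1R par(80)
#define P_D_1 par(81)
#define P_D_2 par(82)
#define P_theta_LTD_start par(83)
#define P_theta_LTD_stop par(84)
#define P_theta_LTP_start par(85)
#define P_A_LTD par(86)
#define P_A_LTP par(87)
#define P_P_1 par(88)
#define P_P_2 par(89)
#define P_P_3 par(90)
#define P_P_4 par(91)
#define P_W_pre_max par(92)
#define P_w_post_gain par(93)
#define P_omega_form par(94)
#define P_k_S par(95)
#define P_CaM_T par(96)
#define P_K_CaM par(97)
#define P_K5_CaMKII par(98)
#define P_k6_CaMKII par(99)
#define P_k7_CaMKII par(100)
#define P_CaMKII_T par(101)
#define P_k12_PP1 par(102)
#define P_K_M_PP1 par(103)
#define P_PP1_T par(104)
#define P_I1_T par(105)
#define P_k3_I1PP1 par(106)
#define P_k4_I1PP1 par(107)
#define P_k_PKA0 par(108)
#define P_k_PKA par(109)
#define P_K_PKA par(110)
#define P_n_PKA par(111)
#define P_k_CaN0 par(112)
#define P_k_CaN par(113)
#define P_K_CaN par(114)
#define P_n_CaN par(115)
#define P_nmdar_ko par(116)
#define P_cb1r_ko par(117)

#define NP 122
#define OFF_MAT (1 + NP)
#define A6(i, j)  pbuf[OFF_MAT + (j) * 14 + (i)]
#define A7(i, j)  pbuf[OFF_MAT + 196 + (j) * 14 + (i)]
#define A12(i, j) pbuf[OFF_MAT + 392 + (j) * 14 + (i)]
#define NPHOS(i)  pbuf[OFF_MAT + 588 + (i)]
#define OFF_EV    (OFF_MAT + 602)

static double sigm(double u) { return 1.0 / (1.0 + exp(-u)); }

static double hillp(double x, double K, double n)
{
    double xn, Kn;
    if (x <= 0.0) return 0.0;
    xn = pow(x, n); Kn = pow(K, n);
    return xn / (xn + Kn);
}

void ecbstdp_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double V = y[0], rA = y[1], rN = y[2], m = y[3], h = y[4];
    const double Ca = y[5] > 0.0 ? y[5] : 0.0;
    const double CaER = y[6] > 0.0 ? y[6] : 0.0;
    const double hip = y[7], IP3 = y[8] > 0.0 ? y[8] : 0.0;
    const double DAG = y[9] > 0.0 ? y[9] : 0.0;
    const double AG2 = y[10] > 0.0 ? y[10] : 0.0;
    const double AEA = y[11] > 0.0 ? y[11] : 0.0;
    const double phi = y[12], x = y[13], d = y[14], W = y[15];
    const double I1P = y[16], PP1 = y[17];
    const double *B = y + 18;           /* B1..B13 */
    int i, j, npre, npost;
    double G = 0.0, Iact = 0.0;

    /* forcing terms: sums over past events (events sorted ascending) */
    npre = (int) pbuf[OFF_EV];
    for (i = npre - 1; i >= 0; i--) {
        double dt = *t - pbuf[OFF_EV + 1 + i];
        if (dt < 0.0) continue;
        if (dt > 40.0 * P_tau_G) break;
        G += exp(-dt / P_tau_G);
    }
    G *= P_G_max;
    npost = (int) pbuf[OFF_EV + 1 + npre];
    for (i = npost - 1; i >= 0; i--) {
        double dt = *t - pbuf[OFF_EV + 2 + npre + i];
        if (dt < 0.0) continue;
        if (dt >= 0.0 && dt < P_DC_dur) Iact -= P_DC_max;
        if (dt - P_delta >= 0.0 && dt - P_delta < 40.0 * P_tau_bAP)
            Iact -= P_AP_max * exp(-(dt - P_delta) / P_tau_bAP);
        if (dt > P_DC_dur && dt - P_delta > 40.0 * P_tau_bAP) break;
    }

    /* currents (pA, negative inward) */
    {
        double IA = P_g_AMPA * rA * (V - P_E_AMPA);
        double Bmg = 1.0 / (1.0 + exp(-P_Mg_slope * V) * P_Mg / P_Mg_scale);
        double IN = P_g_NMDA * rN * Bmg * (V - P_E_NMDA);
        double drive, IV, Pop, IT, shift;
        if (P_vscc_form > 0.5) {
            drive = V - P_E_Ca;
        } else {
            double u = V / 13.35, a = Ca / P_Ca_out;
            if (fabs(u) < 1e-6) drive = 26.7 * (a - 1.0);
            else drive = 26.7 * u * (a - exp(-u)) / (1.0 - exp(-u));
        }
        IV = P_g_VSCC * m * h * drive;
        shift = P_dV_AEA * hillp(AEA, P_K_AEA_TRPV1, P_n_AEA_TRPV1);
        Pop = sigm((V - (P_V_half_TRPV1 - shift)) / P_k_V_TRPV1);
        IT = P_g_TRPV1 * V * Pop;

        ydot[0] = 1000.0 * (-P_g_L * (V - P_V_L) - IA - IN - IV - IT - Iact)
                  / P_C_m;
        ydot[1] = P_alpha_AMPA * G * (1.0 - rA) - P_beta_AMPA * rA;
        ydot[2] = P_alpha_NMDA * G * (1.0 - rN) - P_beta_NMDA * rN;
        ydot[3] = (sigm((V - P_V_m_VSCC) / P_k_m_VSCC) - m) / P_tau_m_VSCC;
        ydot[4] = (sigm(-(V - P_V_h_VSCC) / P_k_h_VSCC) - h) / P_tau_h_VSCC;

        /* calcium and ER */
        {
            double minf = IP3 / (IP3 + P_d1_IP3R);
            double ninf = Ca / (Ca + P_d5_IP3R);
            double gate = minf * ninf * hip;
            double Jip3r = P_r_IP3R * gate * gate * gate * (CaER - Ca);
            double Jser = P_v_SERCA * Ca * Ca / (Ca * Ca + P_K_SERCA * P_K_SERCA);
            double Jleak = P_r_leak * (CaER - Ca);
            double net = Jip3r - Jser + Jleak;
            double influx = -P_xi_NMDA * IN - P_xi_VSCC * IV - P_xi_TRPV1 * IT;
            double TC = 1.0 + P_B_T * P_K_dB / ((P_K_dB + Ca) * (P_K_dB + Ca));
            double TE = 1.0 + P_B_T * P_K_dB / ((P_K_dB + CaER) * (P_K_dB + CaER));
            double Q2 = P_d2_IP3R * (IP3 + P_d1_IP3R) / (IP3 + P_d3_IP3R);
            ydot[5] = (net - (Ca - P_Ca_b) / P_tau_Cab + influx) / TC;
            ydot[6] = -P_rho_ER * net / TE;
            ydot[7] = P_a2_IP3R * (Q2 * (1.0 - hip) - Ca * hip);
        }
    }

    /* CaMKII ring + PP1 / I1 */
    {
        double Bfull[14], dB[14], Sp = 0.0, B0 = P_CaMKII_T;
        double ca4, g, mu, k66, k77, vPKA, vCaN, cplx, I1free, dPP1;
        for (i = 0; i < 13; i++) B0 -= B[i];
        Bfull[0] = B0;
        for (i = 0; i < 13; i++) Bfull[i + 1] = B[i];
        for (i = 0; i < 14; i++) Sp += NPHOS(i) * Bfull[i];
        if (Sp < 0.0) Sp = 0.0;
        ca4 = (P_CaM_T > 0.0)
            ? P_CaM_T * hillp(Ca, P_K_CaM, 4.0) : 0.0;
        g = (ca4 > 0.0) ? ca4 / (P_K5_CaMKII + ca4) : 0.0;
        mu = P_k12_PP1 * PP1 / (P_K_M_PP1 + Sp);
        k66 = P_k6_CaMKII * g * g;
        k77 = P_k7_CaMKII * g;
        for (i = 0; i < 14; i++) {
            double s = 0.0;
            for (j = 0; j < 14; j++)
                s += (k66 * A6(i, j) + k77 * A7(i, j) + mu * A12(i, j))
                     * Bfull[j];
            dB[i] = s;
        }
        for (i = 0; i < 13; i++) ydot[18 + i] = dB[i + 1];
        cplx = P_PP1_T - PP1;
        I1free = P_I1_T - I1P - cplx;
        if (I1free < 0.0) I1free = 0.0;
        vPKA = P_k_PKA0 + P_k_PKA * hillp(Ca, P_K_PKA, P_n_PKA);
        vCaN = P_k_CaN0 + P_k_CaN * hillp(Ca, P_K_CaN, P_n_CaN);
        dPP1 = -P_k3_I1PP1 * I1P * PP1 + P_k4_I1PP1 * cplx;
        ydot[17] = dPP1;
        ydot[16] = dPP1 + vPKA * I1free - vCaN * I1P;

        /* IP3 / DAG / 2-AG / AEA / DAGL activation */
        {
            double Jb = P_v_beta * hillp(G, P_K_R_glu, P_n_glu)
                        * Ca * Ca / (Ca * Ca + P_K_pi_Ca * P_K_pi_Ca);
            double Jd = P_v_delta / (1.0 + IP3 / P_kappa_delta)
                        * Ca * Ca / (Ca * Ca + P_K_delta_Ca * P_K_delta_Ca);
            double RP = Jb + Jd;
            double actmax = 6.0 * P_CaMKII_T;
            double frac = actmax > 0.0 ? Sp / actmax : 0.0;
            double vDGL = P_r_DGL * P_DAGLtot * phi * DAG / (DAG + P_K_DAGL);
            double eCB, yd, target, tau, xd, dW;
            ydot[8] = RP - P_v_3K * frac * IP3 / (IP3 + P_K_3K) - P_r_5P * IP3;
            ydot[9] = RP - vDGL - P_r_DAGK * DAG;
            ydot[10] = vDGL - P_r_MAGL * AG2;
            ydot[11] = P_nu_AT * Ca - P_r_FAAH * AEA / (P_K_FAAH + AEA);
            ydot[12] = P_r_k * pow(Ca, P_n_c) * (1.0 - phi) - P_r_p * phi;

            eCB = AG2 + P_A_endo * AEA;
            ydot[13] = P_alpha_CB1R * eCB * (1.0 - x - d)
                       - (P_beta_CB1R + P_gamma_CB1R) * x;
            ydot[14] = -P_epsilon_CB1R * d + P_gamma_CB1R * x;

            yd = P_k_CB1R * x + P_D_1;
            if (P_omega_form > 0.5) {
                double w1 = P_theta_LTD_start / (10.0 * P_k_S);
                double w2 = P_theta_LTD_stop / (10.0 * P_k_S);
                double w3 = P_theta_LTP_start / (10.0 * P_k_S);
                target = 1.0
                    - P_A_LTD * sigm((yd - P_theta_LTD_start) / w1)
                              * sigm((P_theta_LTD_stop - yd) / w2)
                    + P_A_LTP * sigm((yd - P_theta_LTP_start) / w3);
            } else {
                target = 1.0;
                if (yd >= P_theta_LTD_start && yd <= P_theta_LTD_stop)
                    target = 1.0 - P_A_LTD;
                else if (yd > P_theta_LTP_start)
                    target = 1.0 + P_A_LTP;
            }
            xd = P_k_CB1R * x + P_D_2;
            tau = P_P_1 / (pow(P_P_2, P_P_3) + pow(xd, P_P_3)) + P_P_4;
            dW = (target - W) / tau;
            if (W >= P_W_pre_max && dW > 0.0) dW = 0.0;
            ydot[15] = dW;
        }
    }
    if (*ip > 0) yout[0] = 0.0;
}
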