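/* Electromechanical hiPSC-cardiomyocyte cell model: ionic membrane currents
 * (Hodgkin-Huxley formulations), intracellular Ca2+ handling with SR
 * uptake/release, and a troponin/cross-bridge contractile element.
 *
 * Compiled right-hand side for deSolve (initfunc/derivs convention).
 * The R-level mirror of these equations lives in R/model-rates.R; the two
 * are kept in lock-step and cross-checked by the test suite.
 *
 * Units: t ms, V mV, concentrations mM, currents pA/pF, force mN/mm^2.
 */

#include <math.h>
#include <R.h>

#define N_PARMS 40

static double parms[N_PARMS];

#define g_Na      parms[0]
#define g_CaL     parms[1]
#define g_Kr      parms[2]
#define g_Ks      parms[3]
#define g_K1      parms[4]
#define g_f       parms[5]
#define g_to      parms[6]
#define k_NaCa    parms[7]
#define P_NaK     parms[8]
#define g_bNa     parms[9]
#define g_bCa     parms[10]
#define g_pCa     parms[11]
#define V_up      parms[12]
#define K_up      parms[13]
#define V_leak    parms[14]
#define a_rel     parms[15]
#define b_rel     parms[16]
#define c_rel     parms[17]
#define Na_o      parms[18]
#define K_o       parms[19]
#define Ca_o      parms[20]
#define temp      parms[21]
#define C_m       parms[22]
#define V_c       parms[23]
#define V_sr      parms[24]
#define stim_amp  parms[25]
#define stim_dur  parms[26]
#define k_on      parms[27]
#define k_off     parms[28]
#define trpn_tot  parms[29]
#define n_xb      parms[30]
#define k_half    parms[31]
#define f_xb      parms[32]
#define g_xb      parms[33]
#define F_max     parms[34]
#define cross_sec parms[35]
#define E_f       parms[36]
#define stim_on   parms[37]
#define clamp_mode parms[38]
#define buffer_ca parms[39]

/* fixed constants (documented in the model vignette) */
static const double Frd = 96.4867;   /* C/mmol */
static const double Rgas = 8.3143;   /* J/(mol K) */
static const double Buf_c = 0.15, K_bufc = 0.001;
static const double Buf_sr = 10.0, K_bufsr = 0.3;
static const double gama = 0.35, Km_Nai = 87.5, Km_Ca = 1.38,
                    k_sat = 0.1, alpha_ncx = 2.5;
static const double Km_K = 1.0, Km_Na = 20.0;
static const double K_pCa = 0.0005;
static const double F_conv = 96485.34; /* C/mol, for current-to-flux conversion */

void cm_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* states: 0 V, 1 m, 2 h, 3 j, 4 d, 5 f, 6 fca, 7 xr, 8 xs, 9 y,
 *         10 g, 11 Nai, 12 Ki, 13 Cai, 14 CaSR, 15 TRPN, 16 XB,
 *         17 rto, 18 sto */
void cm_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double V = y[0], m = y[1], h = y[2], j = y[3], d = y[4],
                 f = y[5], fca = y[6], xr = y[7], xs = y[8], yf = y[9],
                 gg = y[10], Nai = y[11], Ki = y[12], Cai = y[13],
                 CaSR = y[14], TRPN = y[15], XB = y[16],
                 rto = y[17], sto = y[18];

    const double RTF = Rgas * temp / Frd;
    const double E_Na = RTF * log(Na_o / Nai);
    const double E_K  = RTF * log(K_o / Ki);
    const double E_Ks = RTF * log((K_o + 0.03 * Na_o) / (Ki + 0.03 * Nai));
    const double E_Ca = 0.5 * RTF * log(Ca_o / Cai);

    /* --- fast Na+ current --- */
    const double I_Na = g_Na * m * m * m * h * j * (V - E_Na);
    double tmp = 1.0 + exp((-56.86 - V) / 9.03);
    const double m_inf = 1.0 / (tmp * tmp);
    const double a_m = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
    const double b_m = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
                       0.1 / (1.0 + exp((V - 50.0) / 200.0));
    const double tau_m = a_m * b_m;
    tmp = 1.0 + exp((V + 71.55) / 7.43);
    const double h_inf = 1.0 / (tmp * tmp);
    double a_h, b_h, a_j, b_j;
    if (V < -40.0) {
        a_h = 0.057 * exp(-(V + 80.0) / 6.8);
        b_h = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
        a_j = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
              (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
        b_j = 0.02424 * exp(-0.01052 * V) /
              (1.0 + exp(-0.1378 * (V + 40.14)));
    } else {
        a_h = 0.0;
        b_h = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
        a_j = 0.0;
        b_j = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
    }
    const double tau_h = 1.0 / (a_h + b_h);
    const double tau_j = 1.0 / (a_j + b_j);
    const double j_inf = h_inf;

    /* --- L-type Ca2+ current (GHK driving force) --- */
    double vfrt2 = 2.0 * V / RTF;
    double ghk;
    if (fabs(vfrt2) < 1e-6)
        ghk = 2.0 * Frd * (Cai - 0.341 * Ca_o); /* limit V -> 0 */
    else
        ghk = 2.0 * Frd * vfrt2 * (Cai * exp(vfrt2) - 0.341 * Ca_o) /
              (exp(vfrt2) - 1.0);
    const double I_CaL = g_CaL * d * f * fca * ghk;
    const double d_inf = 1.0 / (1.0 + exp((-5.0 - V) / 7.5));
    const double a_d = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    const double b_d = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    const double c_d = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    const double tau_d = a_d * b_d + c_d;
    const double f_inf = 0.08 + 0.92 / (1.0 + exp((V + 20.0) / 7.0));
    const double tau_f = 40.0 + 500.0 / (1.0 + exp(-(V + 15.0) / 8.0));
    const double rca = Cai / 0.0015;
    const double fca_inf = 0.92 + 0.08 / (1.0 + rca * rca);
    const double tau_fca = 15.0;

    /* --- rapid delayed rectifier --- */
    const double xr_inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
    const double a_xr = 100.0 / (1.0 + exp((-45.0 - V) / 10.0));
    const double b_xr = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
    const double tau_xr = a_xr * b_xr;
    const double r_inf = 1.0 / (1.0 + exp((V - 10.0) / 34.0)) /
                         (1.0 + exp(-(V + 58.0) / 5.0));
    const double I_Kr = g_Kr * sqrt(K_o / 5.4) * xr * r_inf * (V - E_K);

    /* --- slow delayed rectifier --- */
    const double xs_inf = 1.0 / (1.0 + exp((-35.0 - V) / 6.0));
    const double a_xs = 400.0 / sqrt(1.0 + exp((-10.0 - V) / 6.0));
    const double b_xs = 1.0 / (1.0 + exp((V - 60.0) / 20.0));
    const double tau_xs = a_xs * b_xs;
    const double I_Ks = g_Ks * xs * xs * (V - E_Ks);

    /* --- transient outward current --- */
    const double rto_inf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
    const double tau_rto = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) +
                           0.8;
    const double sto_inf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    const double tau_sto = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
                           5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
    const double I_to = g_to * rto * sto * (V - E_K);

    /* --- inward rectifier --- */
    const double a_k1 = 0.1 / (1.0 + exp(0.06 * (V - E_K - 200.0)));
    const double b_k1 = (3.0 * exp(0.0002 * (V - E_K + 100.0)) +
                         exp(0.1 * (V - E_K - 10.0))) /
                        (1.0 + exp(-0.5 * (V - E_K)));
    const double xk1_inf = a_k1 / (a_k1 + b_k1);
    const double I_K1 = g_K1 * sqrt(K_o / 5.4) * xk1_inf * (V - E_K);

    /* --- funny current (mixed Na/K, lumped reversal E_f) --- */
    const double I_f = g_f * yf * (V - E_f);
    const double y_inf = 1.0 / (1.0 + exp((V + 80.6) / 6.8));
    const double tau_y = 1000.0;

    /* --- Na/Ca exchanger --- */
    const double vfrt = V / RTF;
    const double I_NaCa = k_NaCa *
        (exp(gama * vfrt) * Nai * Nai * Nai * Ca_o -
         exp((gama - 1.0) * vfrt) * Na_o * Na_o * Na_o * Cai * alpha_ncx) /
        ((Km_Nai * Km_Nai * Km_Nai + Na_o * Na_o * Na_o) *
         (Km_Ca + Ca_o) * (1.0 + k_sat * exp((gama - 1.0) * vfrt)));

    /* --- Na/K pump --- */
    const double nai3 = Nai * Nai * Nai;
    const double I_NaK = P_NaK * K_o * nai3 /
        ((K_o + Km_K) * (nai3 + Km_Na * Km_Na * Km_Na) *
         (1.0 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt)));

    /* --- background and pump currents --- */
    const double I_bNa = g_bNa * (V - E_Na);
    const double I_bCa = g_bCa * (V - E_Ca);
    const double I_pCa = g_pCa * Cai / (Cai + K_pCa);

    const double I_ion = I_Na + I_CaL + I_Kr + I_Ks + I_K1 + I_f +
                         I_to + I_NaCa + I_NaK + I_bNa + I_bCa + I_pCa;
    const double I_stim = (stim_on > 0.5) ? -stim_amp : 0.0;

    /* --- SR Ca2+ fluxes (mM/ms) --- */
    const double J_up = V_up / (1.0 + (K_up / Cai) * (K_up / Cai));
    const double J_leak = V_leak * (CaSR - Cai);
    const double J_rel = (a_rel * CaSR * CaSR / (b_rel * b_rel + CaSR * CaSR)
                          + c_rel) * d * gg * (CaSR - Cai);
    const double rg = Cai / 0.00035;
    const double g_inf = 1.0 / (1.0 + pow(rg, 6.0));
    const double tau_g = 2.0;

    /* --- contractile element --- */
    const double dTRPN = k_on * Cai * (1.0 - TRPN) - k_off * TRPN;
    const double perm = 1.0 /
        (1.0 + pow(k_half / (TRPN > 1e-12 ? TRPN : 1e-12), n_xb));
    const double dXB = f_xb * perm * (1.0 - XB) - g_xb * XB;
    const double F_stress = F_max * XB;

    /* --- buffering (rapid-buffer approximation) --- */
    const double bi = 1.0 /
        (1.0 + Buf_c * K_bufc / ((Cai + K_bufc) * (Cai + K_bufc)));
    const double bsr = 1.0 /
        (1.0 + Buf_sr * K_bufsr / ((CaSR + K_bufsr) * (CaSR + K_bufsr)));

    const double conv = C_m / (V_c * F_conv); /* pA/pF -> mM/ms */

    ydot[0] = (clamp_mode > 0.5) ? 0.0 : -(I_ion + I_stim);
    ydot[1] = (m_inf - m) / tau_m;
    ydot[2] = (h_inf - h) / tau_h;
    ydot[3] = (j_inf - j) / tau_j;
    ydot[4] = (d_inf - d) / tau_d;
    ydot[5] = (f_inf - f) / tau_f;
    ydot[6] = (fca_inf - fca) / tau_fca;
    ydot[7] = (xr_inf - xr) / tau_xr;
    ydot[8] = (xs_inf - xs) / tau_xs;
    ydot[9] = (y_inf - yf) / tau_y;
    ydot[10] = (g_inf - gg) / tau_g;
    ydot[11] = -(I_Na + I_bNa + 3.0 * I_NaK + 3.0 * I_NaCa + 0.5 * I_f) *
               conv;
    /* bulk intracellular K+ held fixed: removes the minutes-scale resting-
     * potential drift so paced steady states are well defined */
    ydot[12] = 0.0;
    const double J_trpn = trpn_tot * dTRPN;
    ydot[13] = bi * (-(I_CaL + I_bCa + I_pCa - 2.0 * I_NaCa) * conv * 0.5 +
                     J_leak - J_up + J_rel - J_trpn);
    ydot[14] = bsr * (V_c / V_sr) * (J_up - J_rel - J_leak);
    ydot[15] = dTRPN;
    ydot[16] = dXB;
    ydot[17] = (rto_inf - rto) / tau_rto;
    ydot[18] = (sto_inf - sto) / tau_sto;

    /* pipette Ca2+ buffering (EGTA emulation) freezes Ca compartments */
    if (buffer_ca > 0.5) {
        ydot[13] = 0.0;
        ydot[14] = 0.0;
    }

    if (*ip >= 17) {
        yout[0] = I_Na;   yout[1] = I_CaL; yout[2] = I_Kr;
        yout[3] = I_Ks;   yout[4] = I_K1;  yout[5] = I_f;
        yout[6] = I_to;   yout[7] = I_NaCa; yout[8] = I_NaK;
        yout[9] = I_bNa;  yout[10] = I_bCa; yout[11] = I_pCa;
        yout[12] = I_stim; yout[13] = I_ion; yout[14] = F_stress;
        yout[15] = J_rel; yout[16] = J_up;
    }
}
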