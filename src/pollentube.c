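/* Compiled right-hand side of the pollen tube growth model.
 *
 * State (13): v, P, L, eta, h, Ca_i, H_i, K_i, Cl_i, V, p_Ca, p_K, n_K
 * Forcings (10): Ca_o, H_o, K_o, Cl_o, Osm_o, eta_eq, Osm_i,
 *                fusion_scale, r, drdt
 * Must agree with the R reference implementation cellRhs() to float
 * precision; the test suite cross-checks both at random states.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 60
#define NFORC  10

static double parms[NPARMS];
static double forc[NFORC];

/* parameter aliases (order fixed by .packParams in R/params.R) */
#define c_R        parms[0]
#define c_T        parms[1]
#define c_F        parms[2]
#define c_Vref     parms[3]
#define p_Lp       parms[4]
#define p_Aosm     parms[5]
#define p_eps      parms[6]
#define p_Pc       parms[7]
#define p_vext     parms[8]
#define p_etaeq    parms[9]
#define p_k1       parms[10]
#define p_k2a      parms[11]
#define p_fus      parms[12]
#define p_r0       parms[13]
#define p_h0       parms[14]
#define p_L0       parms[15]
#define p_Osmi     parms[16]
#define p_Cao      parms[17]
#define p_Ho       parms[18]
#define p_Ko       parms[19]
#define p_Clo      parms[20]
#define p_Osmo     parms[21]
#define p_Cm       parms[22]
#define p_ovs      parms[23]
#define p_g1       parms[24]
#define p_Vh1      parms[25]
#define p_s1       parms[26]
#define p_g2       parms[27]
#define p_Vh2      parms[28]
#define p_s2       parms[29]
#define p_g3       parms[30]
#define p_Vh3      parms[31]
#define p_s3       parms[32]
#define p_Ipmax    parms[33]
#define p_Vhp      parms[34]
#define p_sp       parms[35]
#define p_Kmp      parms[36]
#define p_g5       parms[37]
#define p_Vh5      parms[38]
#define p_s5       parms[39]
#define p_g6       parms[40]
#define p_Vh6      parms[41]
#define p_s6       parms[42]
#define p_gCasa    parms[43]
#define p_gKsa     parms[44]
#define p_gClsa    parms[45]
#define p_kOC0     parms[46]
#define p_kCO0     parms[47]
#define p_ka       parms[48]
#define p_kCa      parms[49]
#define p_kH       parms[50]
#define p_kK       parms[51]
#define p_kCl      parms[52]
#define p_Cas      parms[53]
#define p_Hs       parms[54]
#define p_Cls      parms[56]
#define p_Ks       parms[55]
#define p_bCa      parms[57]
#define p_bH       parms[58]
#define p_taun     parms[59]

/* forcing aliases */
#define f_Cao   forc[0]
#define f_Ho    forc[1]
#define f_Ko    forc[2]
#define f_Clo   forc[3]
#define f_Osmo  forc[4]
#define f_etaeq forc[5]
#define f_Osmi  forc[6]
#define f_fus   forc[7]
#define f_r     forc[8]
#define f_drdt  forc[9]

void ptube_init(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void ptube_forc(void (*odeforcs)(int *, double *))
{
    int n = NFORC;
    odeforcs(&n, forc);
}

static double ghk(double g, double V, double z, double ci, double ce,
                  double Vref)
{
    double x = z * V / Vref;
    if (fabs(x) < 1e-6)
        return g * Vref * (ci - ce) / z;
    double em = exp(-x);
    return g * V * (ci - ce * em) / (1.0 - em);
}

static double boltz(double V, double Vh, double s)
{
    return 1.0 / (1.0 + exp((Vh - V) / s));
}

static double dmax(double a, double b) { return a > b ? a : b; }
static double dmin(double a, double b) { return a < b ? a : b; }

void ptube_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    if (ip[0] < 23) error("nout should be at least 23");

    double v   = y[0];
    double P   = y[1];
    double L   = y[2];
    double eta = dmax(y[3], 1e3);
    double h   = dmax(y[4], 1e-9);
    double Ca  = dmax(y[5], 0.0);
    double H   = dmax(y[6], 0.0);
    double K   = dmax(y[7], 0.0);
    double Cl  = dmax(y[8], 0.0);
    double V   = y[9];
    double pCa = dmin(dmax(y[10], 0.0), 1.0);
    double pK  = dmin(dmax(y[11], 0.0), 1.0);
    double nK  = dmin(dmax(y[12], 0.0), 1.0);

    double r = f_r;
    double OV = p_ovs * 2.0 / r;
    double RTm = c_R * c_T * 1000.0;   /* Pa per M */

    double pi_i = RTm * (Ca + H + K + Cl + f_Osmi);
    double pi_o = RTm * (f_Cao + f_Ho + f_Ko + f_Clo + f_Osmo);

    double inflow  = p_Lp * p_Aosm * (pi_i - pi_o);
    double outflow = p_Lp * p_Aosm * P;
    double dv = inflow - outflow;
    double phi = 1.0 / eta;
    double plastic_rel = p_vext / v * phi * dmax(P - p_Pc, 0.0);
    double dP = p_eps * (dv / v - plastic_rel);
    double dL = (dv - 2.0 * M_PI * r * L * f_drdt) / (M_PI * r * r);

    double k2 = f_fus * p_k2a / (r * r);
    double Rs = k2 * Ca;
    double deta = -eta * Rs / h + p_k1 * (f_etaeq - eta);
    double r_i = dmax(r - h, 0.1 * r);
    double dh = -3.0 * (r * r - r_i * r_i) / (2.0 * r * r) * dL + Rs;

    /* cap the closed->open rate: keeps the gate ODE integrable when
       transient turgor excursions push exp(ka*P) to astronomical values;
       the open fraction is saturated there anyway */
    double kCO = p_kCO0 * exp(dmin(p_ka * P, 700.0));
    kCO = dmin(kCO, 1e4);
    double dpCa = kCO * (1.0 - pCa) - p_kOC0 * pCa;
    double dpK  = kCO * (1.0 - pK)  - p_kOC0 * pK;

    double E_H  = c_Vref * log(dmax(f_Ho, 1e-30) / dmax(H, 1e-30));
    double E_Cl = -c_Vref * log(dmax(f_Clo, 1e-12) / dmax(Cl, 1e-12));

    double I1 = boltz(V, p_Vh1, -p_s1) * ghk(p_g1, V, 1.0, K, f_Ko, c_Vref);
    double I2 = nK * ghk(p_g2, V, 1.0, K, f_Ko, c_Vref);
    double I3 = boltz(V, p_Vh3, p_s3) * ghk(p_g3, V, 2.0, Ca, f_Cao, c_Vref);
    double I4 = p_Ipmax * boltz(V, p_Vhp, p_sp) * H / (H + p_Kmp);
    double I5 = p_g5 * boltz(V, p_Vh5, -p_s5) * (V - (2.0 * E_H - E_Cl));
    double I6 = boltz(V, p_Vh6, p_s6) * ghk(p_g6, V, -1.0, Cl, f_Clo, c_Vref);
    double Isa1 = pCa * ghk(p_gCasa, V, 2.0, Ca, f_Cao, c_Vref);
    double Isa2 = pK * ghk(p_gKsa, V, 1.0, K, f_Ko, c_Vref);
    double Isa3 = (p_gClsa > 0.0)
        ? pCa * ghk(p_gClsa, V, -1.0, Cl, f_Clo, c_Vref) : 0.0;

    double dV = -(I1 + I2 + I3 + I4 + I5 + I6 + Isa1 + Isa2 + Isa3) / p_Cm;

    double rel = dv / v;
    double toM = 1e-3;
    double dCa = -OV * (I3 + Isa1) / (2.0 * c_F) * toM
        - p_kCa * (Ca - p_Cas) - rel * Ca - p_bCa * (Ca - p_Cas);
    double dH = -OV * (I4 + 2.0 * I5) / c_F * toM
        - p_kH * (H - p_Hs) - rel * H - p_bH * (H - p_Hs);
    double dK = -OV * (I1 + I2 + Isa2) / c_F * toM
        - p_kK * (K - p_Ks) - rel * K;
    double dCl = -OV * (-I6 - Isa3 + I5) / c_F * toM
        - p_kCl * (Cl - p_Cls) - rel * Cl;

    ydot[0] = dv;   ydot[1] = dP;   ydot[2] = dL;  ydot[3] = deta;
    ydot[4] = dh;   ydot[5] = dCa;  ydot[6] = dH;  ydot[7] = dK;
    double n_inf = boltz(V, p_Vh2, p_s2);
    ydot[8] = dCl;  ydot[9] = dV;   ydot[10] = dpCa; ydot[11] = dpK;
    ydot[12] = (n_inf - nK) / p_taun;

    yout[0] = pi_i;     yout[1] = pi_o;     yout[2] = phi;
    yout[3] = inflow;   yout[4] = outflow;  yout[5] = dv;
    yout[6] = p_vext * phi * dmax(P - p_Pc, 0.0) + v / p_eps * dP;
    yout[7] = dP;       yout[8] = dL;       yout[9] = Rs;
    yout[10] = k2;
    yout[11] = I1; yout[12] = I2; yout[13] = I3;
    yout[14] = I4; yout[15] = I5; yout[16] = I6;
    yout[17] = Isa1; yout[18] = Isa2;
    yout[19] = r; yout[20] = f_drdt; yout[21] = f_etaeq; yout[22] = OV;
}

static const R_CMethodDef cMethods[] = {
    {NULL, NULL, 0}
};

void R_init_pollentube(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
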