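/* Compiled right-hand side of the Rac1-RhoA-PAK network for deSolve.
 *
 * State vector (nM), fixed order shared with R/species.R:
 *   1 Rac1_GDP  2 Rac1_GTP  3 RhoA_GDP  4 RhoA_GTP  5 iPAK  6 cPAK  7 pPAK
 *   8 iPAK_I    9 GEFH1    10 pGEFH1   11 pGEFH1_1433  12 F1433
 *  13 GAPi     14 GAPa
 *
 * Parameter vector (31):
 *   1..27 kinetic constants (see R/kinetics.R for order and units),
 *   28 u_target: applied free inhibitor (nM) the intracellular level relaxes to,
 *   29 u0:       intracellular free inhibitor at segment start (nM),
 *   30 k_wash:   relaxation rate ln(2)/t_half (1/min); 0 = clamped at u0,
 *   31 t0:       model time at segment start (min).
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 31

static double parms[N_PARMS];

void rhoswitch_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

void rhoswitch_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const double Vb_racgef = parms[0],  Km_r1 = parms[1];
    const double kcat_gap  = parms[2],  Vb_racgap = parms[3], Km_r2 = parms[4];
    const double kcat_gef  = parms[5],  Vb_rhogef = parms[6], Km_r3 = parms[7];
    const double Vb_rhogap = parms[8],  Km_r4 = parms[9];
    const double kon_pak   = parms[10], koff_pak = parms[11], k_auto = parms[12];
    const double V_ppase   = parms[13], Km_p = parms[14];
    const double kcat_pakgef = parms[15], Km_g = parms[16];
    const double V_gppase  = parms[17], Km_gp = parms[18];
    const double kon_14    = parms[19], koff_14 = parms[20];
    const double kcat_rho  = parms[21], Km_ga = parms[22];
    const double V_gapoff  = parms[23], Km_gd = parms[24];
    const double kon_i     = parms[25], koff_i = parms[26];
    const double u_target  = parms[27], u0 = parms[28];
    const double k_wash    = parms[29], t0 = parms[30];

    const double Rac1_GDP = y[0], Rac1_GTP = y[1];
    const double RhoA_GDP = y[2], RhoA_GTP = y[3];
    const double iPAK = y[4], cPAK = y[5], pPAK = y[6], iPAK_I = y[7];
    const double GEFH1 = y[8], pGEFH1 = y[9], pGEFH1_1433 = y[10];
    const double F1433 = y[11], GAPi = y[12], GAPa = y[13];

    double u = (k_wash > 0.0)
        ? u_target + (u0 - u_target) * exp(-k_wash * (*t - t0))
        : u0;
    if (u < 0.0) u = 0.0;

    const double v_rac_act   = Vb_racgef * Rac1_GDP / (Km_r1 + Rac1_GDP);
    const double v_rac_deact = (kcat_gap * GAPa + Vb_racgap) * Rac1_GTP /
                               (Km_r2 + Rac1_GTP);
    const double v_rho_act   = (kcat_gef * GEFH1 + Vb_rhogef) * RhoA_GDP /
                               (Km_r3 + RhoA_GDP);
    const double v_rho_deact = Vb_rhogap * RhoA_GTP / (Km_r4 + RhoA_GTP);
    const double v_pak_bind  = kon_pak * Rac1_GTP * iPAK - koff_pak * cPAK;
    const double v_pak_auto  = k_auto * cPAK;
    const double v_pak_deph  = V_ppase * pPAK / (Km_p + pPAK);
    const double v_gef_phos  = kcat_pakgef * pPAK * GEFH1 / (Km_g + GEFH1);
    const double v_gef_deph  = V_gppase * pGEFH1 / (Km_gp + pGEFH1);
    const double v_seq_bind  = kon_14 * pGEFH1 * F1433 - koff_14 * pGEFH1_1433;
    const double v_gap_act   = kcat_rho * RhoA_GTP * GAPi / (Km_ga + GAPi);
    const double v_gap_deact = V_gapoff * GAPa / (Km_gd + GAPa);
    const double v_inh_bind  = kon_i * u * iPAK;
    const double v_inh_unb   = koff_i * iPAK_I;

    ydot[0]  = -v_rac_act + v_rac_deact;                       /* Rac1_GDP */
    ydot[1]  =  v_rac_act - v_rac_deact - v_pak_bind + v_pak_auto; /* Rac1_GTP */
    ydot[2]  = -v_rho_act + v_rho_deact;                       /* RhoA_GDP */
    ydot[3]  =  v_rho_act - v_rho_deact;                       /* RhoA_GTP */
    ydot[4]  = -v_pak_bind + v_pak_deph - v_inh_bind + v_inh_unb; /* iPAK */
    ydot[5]  =  v_pak_bind - v_pak_auto;                       /* cPAK */
    ydot[6]  =  v_pak_auto - v_pak_deph;                       /* pPAK */
    ydot[7]  =  v_inh_bind - v_inh_unb;                        /* iPAK_I */
    ydot[8]  = -v_gef_phos + v_gef_deph;                       /* GEFH1 */
    ydot[9]  =  v_gef_phos - v_gef_deph - v_seq_bind;          /* pGEFH1 */
    ydot[10] =  v_seq_bind;                                    /* pGEFH1_1433 */
    ydot[11] = -v_seq_bind;                                    /* F1433 */
    ydot[12] = -v_gap_act + v_gap_deact;                       /* GAPi */
    ydot[13] =  v_gap_act - v_gap_deact;                       /* GAPa */

    if (*ip > 0) yout[0] = u;
}

static const R_CMethodDef cMethods[] = {
    {"rhoswitch_initmod", (DL_FUNC) &rhoswitch_initmod, 1},
    {"rhoswitch_derivs",  (DL_FUNC) &rhoswitch_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_rhoswitch(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
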