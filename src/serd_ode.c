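/* Compiled right-hand side of the ER turnover (stimulation-of-loss)
 * indirect-response model, with the one-compartment repeat-dose oral
 * exposure evaluated analytically by superposition.
 *
 * parms layout (see simulate_er()):
 *   0 kout   basal degradation rate (1/h)
 *   1 smax   maximal fold-stimulation of degradation
 *   2 sc50   free conc at half-maximal stimulation (nM)
 *   3 e0     baseline ER level
 *   4 ka     absorption rate (1/h)
 *   5 ke     elimination rate (1/h)
 *   6 cscale dose/Vd * fu * 1e6 / MW (nM); for constant exposure the
 *            constant free concentration itself
 *   7 interval dosing interval (h)
 *   8 ndoses number of doses; < 0 flags constant exposure = cscale
 */
#include <R.h>
#include <Rmath.h>
#include <R_ext/Rdynload.h>

static double parms[9];
#define P_KOUT   parms[0]
#define P_SMAX   parms[1]
#define P_SC50   parms[2]
#define P_E0     parms[3]
#define P_KA     parms[4]
#define P_KE     parms[5]
#define P_CSCALE parms[6]
#define P_INTER  parms[7]
#define P_NDOSES parms[8]

void serd_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

static double free_conc(double t)
{
    if (P_NDOSES < 0)
        return P_CSCALE;
    double cu = 0.0, ka = P_KA, ke = P_KE;
    double kmax = ka > ke ? ka : ke;
    int nd = (int) P_NDOSES;
    for (int k = 0; k < nd; k++) {
        double tau = t - k * P_INTER;
        if (tau < 0)
            break;
        if (fabs(ka - ke) < 1e-10 * kmax)
            cu += ka * tau * exp(-ka * tau);
        else
            cu += ka / (ka - ke) * (exp(-ke * tau) - exp(-ka * tau));
    }
    return cu * P_CSCALE;
}

void serd_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double cu = free_conc(*t);
    double stim = 1.0 + P_SMAX * cu / (P_SC50 + cu);
    ydot[0] = P_KOUT * P_E0 - P_KOUT * stim * y[0];
}

static const R_CMethodDef CEntries[] = {
    {"serd_initmod", (DL_FUNC) &serd_initmod, 1},
    {"serd_derivs",  (DL_FUNC) &serd_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_serdpd(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
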