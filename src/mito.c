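/* Mass-action ODE right-hand side of the two-switch mitotic control model,
 * in the form deSolve expects for compiled models, plus .Call entry points
 * used by the fixed-point solver and the fixed-step RK4 integrator.
 *
 * Parameter vector layout (length 35, order fixed; see R/parameters.R):
 *  0 kaPP1      1 kaPP1a    2 kiPP1      3 kCdk1PP1   4 kPP1Gwl
 *  5 kass       6 kdis      7 kcatB55    8 kGwlENSA   9 kPPXGwl
 * 10 kCdk1Sub  11 kCdk1Gwl 12 kB55Gwl   13 kB55Sub   14 kCdk2Gwl
 * 15 kCdc25S   16 kCdc25F  17 kWee1S    18 kWee1F    19 kCdk1Wee1
 * 20 kCdk1Cdc25 21 kPPXY15 22 kCdk2Wee1 23 kCdk2Cdc25 24 kB55Wee1
 * 25 kB55Cdc25 26 CycBTot  27 Cdk2Tot   28 PP1Tot    29 ENSATot
 * 30 B55Tot    31 GwlTot   32 SubTot    33 Kd        34 inhibitor (uM)
 *
 * State vector order (length 10): Subp, CycBCdk1, PP1, pENSATot, Gwlp,
 * PP2AB55, Wee1, Wee1pp, Cdc25, Cdc25pp.  The Wee1 variable is the
 * unphosphorylated, catalytically fast form; Wee1Tot = Cdc25Tot = 1.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define N_PAR 35
#define N_VAR 10

static double parms[N_PAR];

static void rhs_core(const double *p, const double *y, double *dy)
{
    const double Subp = y[0], CycBCdk1 = y[1], PP1 = y[2], pENSAt = y[3],
                 Gwlp = y[4], PP2AB55 = y[5], Wee1 = y[6], Wee1pp = y[7],
                 Cdc25 = y[8], Cdc25pp = y[9];

    const double f = 1.0 / (1.0 + p[34] / p[33]);   /* rapid-equilibrium 1NM-PP1 binding */
    const double VCdk1 = CycBCdk1 * f;

    const double Complex = p[30] - PP2AB55;          /* pENSA:B55 = B55Tot - PP2AB55 */
    const double Wee1p   = 1.0 - Wee1 - Wee1pp;
    const double Cdc25p  = 1.0 - Cdc25 - Cdc25pp;

    const double Vwee = p[17] * (1.0 - Wee1) + p[18] * Wee1;
    const double V25  = p[15] * (1.0 - Cdc25pp) + p[16] * Cdc25pp;
    const double VGwl = p[8] * Gwlp;

    const double cdk1_w1 = p[19] * VCdk1 + p[22] * p[27];  /* Wee1 site kinases  */
    const double cdk1_25 = p[20] * VCdk1 + p[23] * p[27];  /* Cdc25 site kinases */
    const double b55_w1  = p[21] + p[24] * PP2AB55;        /* Wee1 site phosphatases  */
    const double b55_25  = p[21] + p[25] * PP2AB55;        /* Cdc25 site phosphatases */

    dy[0] = p[10] * VCdk1 * (p[32] - Subp) - p[13] * PP2AB55 * Subp;
    dy[1] = V25 * (p[26] - CycBCdk1) - Vwee * CycBCdk1;
    dy[2] = (p[0] + p[1] * PP1) * (p[28] - PP1) - (p[2] + p[3] * VCdk1) * PP1;
    dy[3] = VGwl * (p[29] - pENSAt) - p[7] * Complex;
    dy[4] = (p[11] * VCdk1 + p[14] * p[27]) * (p[31] - Gwlp)
            - (p[12] * PP2AB55 + p[9] + p[4] * PP1) * Gwlp;
    dy[5] = (p[6] + p[7]) * Complex - p[5] * PP2AB55 * (pENSAt - Complex);
    dy[6] = b55_w1 * Wee1p - cdk1_w1 * Wee1;
    dy[7] = cdk1_w1 * Wee1p - b55_w1 * Wee1pp;
    dy[8] = b55_25 * Cdc25p - cdk1_25 * Cdc25;
    dy[9] = cdk1_25 * Cdc25p - b55_25 * Cdc25pp;
}

/* ---- deSolve compiled-model interface ---- */

void mito_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PAR;
    odeparms(&n, parms);
}

void mito_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    rhs_core(parms, y, ydot);
}

/* ---- .Call interface ---- */

SEXP C_mito_rhs(SEXP y, SEXP p)
{
    if (LENGTH(y) != N_VAR) error("state vector must have length %d", N_VAR);
    if (LENGTH(p) != N_PAR) error("parameter vector must have length %d", N_PAR);
    SEXP out = PROTECT(allocVector(REALSXP, N_VAR));
    rhs_core(REAL(p), REAL(y), REAL(out));
    UNPROTECT(1);
    return out;
}

/* Fixed-step classical RK4; saves every `save_every` steps (row 0 = y0). */
SEXP C_mito_rk4(SEXP y0, SEXP p, SEXP dt_, SEXP n_steps_, SEXP save_every_)
{
    if (LENGTH(y0) != N_VAR) error("state vector must have length %d", N_VAR);
    if (LENGTH(p) != N_PAR) error("parameter vector must have length %d", N_PAR);
    const double dt = asReal(dt_);
    const R_xlen_t n_steps = (R_xlen_t) asReal(n_steps_);
    const R_xlen_t save_every = (R_xlen_t) asReal(save_every_);
    if (dt <= 0 || n_steps < 0 || save_every < 1)
        error("invalid RK4 stepping arguments");

    const R_xlen_t n_save = n_steps / save_every + 1;
    SEXP out = PROTECT(allocMatrix(REALSXP, (int) n_save, N_VAR));
    double *o = REAL(out);
    const double *pp = REAL(p);

    double y[N_VAR], k1[N_VAR], k2[N_VAR], k3[N_VAR], k4[N_VAR], tmp[N_VAR];
    for (int j = 0; j < N_VAR; j++) {
        y[j] = REAL(y0)[j];
        o[j * n_save] = y[j];
    }

    R_xlen_t row = 1;
    for (R_xlen_t s = 1; s <= n_steps; s++) {
        rhs_core(pp, y, k1);
        for (int j = 0; j < N_VAR; j++) tmp[j] = y[j] + 0.5 * dt * k1[j];
        rhs_core(pp, tmp, k2);
        for (int j = 0; j < N_VAR; j++) tmp[j] = y[j] + 0.5 * dt * k2[j];
        rhs_core(pp, tmp, k3);
        for (int j = 0; j < N_VAR; j++) tmp[j] = y[j] + dt * k3[j];
        rhs_core(pp, tmp, k4);
        for (int j = 0; j < N_VAR; j++)
            y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
        if (s % save_every == 0) {
            for (int j = 0; j < N_VAR; j++) o[j * n_save + row] = y[j];
            row++;
        }
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_mito_rhs", (DL_FUNC) &C_mito_rhs, 2},
    {"C_mito_rk4", (DL_FUNC) &C_mito_rk4, 5},
    {NULL, NULL, 0}
};

void R_init_mitoswitch(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);   /* deSolve looks up mito_derivs by name */
}
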