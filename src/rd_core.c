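#include <stdlib.h>
#include <string.h>
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Five diffusible species (BMP, Chordin, Noggin, BMP-Chordin, BMP-Noggin) on a
   1D axis with zero-flux (mirror) ends. State is interleaved per node,
   y[5*i + 0..4] = B, C, N, BC, BN, so the Jacobian is banded (half-bandwidth 5)
   and lsoda's banded mode stays cheap for stiff parameter draws.

   Parameters are staged from R by rd_set_parms() before each ode() call:
   [0] n nodes, [1] dx, [2..6] D (B,C,N,BC,BN), [7..11] dec (same order),
   [12] kon_BC, [13] koff_BC, [14] kon_BN, [15] koff_BN, [16] lambda_C,
   [17] lambda_BC, then etaB[n], etaC[n], etaN[n], tld[n]. */

static double *rd_parms = NULL;
static R_xlen_t rd_np = 0;

SEXP rd_set_parms(SEXP p)
{
    R_xlen_t n = XLENGTH(p);
    double *buf = (double *) realloc(rd_parms, (size_t) n * sizeof(double));
    if (buf == NULL)
        error("rd_set_parms: allocation failed");
    rd_parms = buf;
    memcpy(rd_parms, REAL(p), (size_t) n * sizeof(double));
    rd_np = n;
    return R_NilValue;
}

void rd_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    if (rd_parms == NULL)
        error("rd_derivs: parameters not staged");
    int n = (int) rd_parms[0];
    double dx2 = rd_parms[1] * rd_parms[1];
    const double *D   = rd_parms + 2;
    const double *dec = rd_parms + 7;
    double konBC  = rd_parms[12], koffBC = rd_parms[13];
    double konBN  = rd_parms[14], koffBN = rd_parms[15];
    double lamC   = rd_parms[16], lamBC  = rd_parms[17];
    const double *etaB = rd_parms + 18;
    const double *etaC = rd_parms + 18 + n;
    const double *etaN = rd_parms + 18 + 2 * n;
    const double *tld  = rd_parms + 18 + 3 * n;

    for (int i = 0; i < n; i++) {
        int il = (i == 0) ? 1 : i - 1;        /* mirror ends: ghost = inner */
        int ir = (i == n - 1) ? n - 2 : i + 1;
        const double *yc = y + 5 * i;
        const double *yl = y + 5 * il;
        const double *yr = y + 5 * ir;
        double B = yc[0], C = yc[1], N = yc[2], BC = yc[3], BN = yc[4];
        double bindBC = konBC * B * C - koffBC * BC;
        double bindBN = konBN * B * N - koffBN * BN;
        double relBC  = lamBC * tld[i] * BC;
        double *d = ydot + 5 * i;
        d[0] = D[0] * (yl[0] + yr[0] - 2.0 * B)  / dx2 + etaB[i]
               - dec[0] * B - bindBC - bindBN + relBC;
        d[1] = D[1] * (yl[1] + yr[1] - 2.0 * C)  / dx2 + etaC[i]
               - dec[1] * C - bindBC - lamC * tld[i] * C;
        d[2] = D[2] * (yl[2] + yr[2] - 2.0 * N)  / dx2 + etaN[i]
               - dec[2] * N - bindBN;
        d[3] = D[3] * (yl[3] + yr[3] - 2.0 * BC) / dx2
               + bindBC - dec[3] * BC - relBC;
        d[4] = D[4] * (yl[4] + yr[4] - 2.0 * BN) / dx2
               + bindBN - dec[4] * BN;
    }
}

static const R_CallMethodDef callMethods[] = {
    {"rd_set_parms", (DL_FUNC) &rd_set_parms, 1},
    {NULL, NULL, 0}
};

void R_init_bmpgrad(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks rd_derivs up by name */
}
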