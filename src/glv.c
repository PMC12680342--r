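/* Compiled right-hand side for dense generalized Lotka-Volterra systems,
 * used through deSolve's compiled-model interface.
 *
 * Parameter vector layout handed over by the R side:
 *   parms[0]            N (number of species)
 *   parms[1]            guard threshold for the blow-up root function
 *   parms[2 .. 2+N-1]   growth rates mu_i
 *   parms[2+N .. ]      interaction matrix beta, row-major (beta_11,
 *                       beta_12, ..., beta_NN)
 *
 * dx_i/dt = x_i * (mu_i + sum_j beta_ij x_j)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* 15 species is the support-enumeration cap used by the stability module;
 * the buffer leaves headroom beyond it. */
#define GLV_MAX_PARMS (2 + 20 + 20 * 20)

static double glv_parms[GLV_MAX_PARMS];

void glv_initmod(void (*odeparms)(int *, double *))
{
    int n = GLV_MAX_PARMS;
    odeparms(&n, glv_parms);
}

void glv_derivs(int *neq, double *t, double *x, double *dx,
                double *yout, int *ip)
{
    const int N = (int) glv_parms[0];
    const double *mu = glv_parms + 2;
    const double *beta = glv_parms + 2 + N;

    for (int i = 0; i < N; i++) {
        double s = mu[i];
        const double *bi = beta + (size_t) i * N;
        for (int j = 0; j < N; j++)
            s += bi[j] * x[j];
        dx[i] = x[i] * s;
    }
}

/* Root crosses zero when max_i |x_i| reaches the guard threshold or a
 * non-finite state appears; lsodar stops the integration there. */
void glv_root(int *neq, double *t, double *x, int *ng, double *gout,
              double *out, int *ip)
{
    const double guard = glv_parms[1];
    double m = 0.0;
    int bad = 0;

    for (int i = 0; i < *neq; i++) {
        double a = fabs(x[i]);
        if (!R_FINITE(a)) { bad = 1; break; }
        if (a > m) m = a;
    }
    gout[0] = bad ? 0.0 : guard - m;
}

/* Analytic state Jacobian: J_ij = delta_ij (mu_i + sum_k beta_ik x_k)
 *                                 + x_i beta_ij */
void glv_jac(int *neq, double *t, double *x, int *ml, int *mu_band,
             double *pd, int *nrowpd, double *yout, int *ip)
{
    const int N = (int) glv_parms[0];
    const double *mu = glv_parms + 2;
    const double *beta = glv_parms + 2 + N;

    for (int i = 0; i < N; i++) {
        double g = mu[i];
        const double *bi = beta + (size_t) i * N;
        for (int k = 0; k < N; k++)
            g += bi[k] * x[k];
        for (int j = 0; j < N; j++) {
            double v = x[i] * bi[j];
            if (i == j) v += g;
            /* pd is column-major with nrowpd rows */
            pd[(size_t) j * (*nrowpd) + i] = v;
        }
    }
}

static const R_CMethodDef CEntries[] = {
    {"glv_initmod", (DL_FUNC) &glv_initmod, 1},
    {"glv_derivs",  (DL_FUNC) &glv_derivs,  6},
    {"glv_root",    (DL_FUNC) &glv_root,    7},
    {"glv_jac",     (DL_FUNC) &glv_jac,     9},
    {NULL, NULL, 0}
};

void R_init_mcident(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
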