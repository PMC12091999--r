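/* Compiled RHS / Jacobian / root functions for mass-action kinetic models,
 * in deSolve's compiled-model calling convention.
 *
 * The model is packed into a single double vector (see pack_model() on the R
 * side).  Layout, all doubles:
 *
 *   p[0]  total length of the vector (used by kr_init to size its copy)
 *   p[1]  mode: 0 = linear exchange D*(X - x); 1 = RCRN uptake + growth dilution
 *   p[2]  n    (number of state variables)
 *   p[3]  R    (number of reactions)
 *   p[4]  root mode bitmask: 1 = log-distance stop, 2 = derivative-residual stop
 *   then 6 per-reaction arrays of length R:
 *        sub1, sub2, prd1, prd2   (1-based species index, 0 = absent slot)
 *        a (= v * k+), b (= v * k-)
 *   then 5 per-species arrays of length n:
 *        D, X, T (transporter index, RCRN mode), clamp (1 = frozen), xst
 *   then 3 scalars: disttol, epsabs, epsrel
 *
 * Reactions have at most two substrates and two products (multisets); the
 * stoichiometric update is accumulated as -J on each substrate slot and +J on
 * each product slot, which reproduces S %*% J exactly, including catalysts
 * (same species on both sides) and duplicated species (coefficient 2).
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>
#include <stdlib.h>

#define KR_MIN_LEN 8

static double *pm = NULL;

/* The packed model can be long and its length varies per call, so instead of
 * the fixed-length odeparms copier we take a pointer into the parms vector
 * itself (kept alive by deSolve for the duration of the solver call). */
void kr_init(void (*odeparms)(int *, double *))
{
    static SEXP (*get_gparms)(void) = NULL;
    if (get_gparms == NULL)
        get_gparms = (SEXP (*)(void))
            R_GetCCallable("deSolve", "get_deSolve_gparms");
    SEXP gparms = get_gparms();
    if (TYPEOF(gparms) != REALSXP || LENGTH(gparms) < KR_MIN_LEN)
        error("kinresponse: malformed packed model");
    pm = REAL(gparms);
}

#define KR_HEAD 5

static void kr_core(double *y, double *ydot, double *maxflux)
{
    int n = (int) pm[2];
    int R = (int) pm[3];
    int mode = (int) pm[1];
    const double *sub1 = pm + KR_HEAD;
    const double *sub2 = sub1 + R;
    const double *prd1 = sub2 + R;
    const double *prd2 = prd1 + R;
    const double *a = prd2 + R;
    const double *b = a + R;
    const double *D = b + R;
    const double *X = D + n;
    const double *T = X + n;
    const double *clamp = T + n;
    double mf = 0.0;

    for (int i = 0; i < n; i++)
        ydot[i] = 0.0;

    for (int r = 0; r < R; r++) {
        int s1 = (int) sub1[r] - 1;
        int s2 = (int) sub2[r] - 1;
        int p1 = (int) prd1[r] - 1;
        int p2 = (int) prd2[r] - 1;
        double xs = y[s1] * (s2 >= 0 ? y[s2] : 1.0);
        double xp = y[p1] * (p2 >= 0 ? y[p2] : 1.0);
        double J = a[r] * xs - b[r] * xp;
        double aJ = fabs(J);
        if (aJ > mf)
            mf = aJ;
        ydot[s1] -= J;
        if (s2 >= 0)
            ydot[s2] -= J;
        ydot[p1] += J;
        if (p2 >= 0)
            ydot[p2] += J;
    }

    if (mode == 0) {
        for (int i = 0; i < n; i++)
            if (D[i] != 0.0)
                ydot[i] += D[i] * (X[i] - y[i]);
    } else {
        /* RCRN: uptake D_i * x_T(i) * X_i and dilution -mu * x_i with
         * mu = sum_i D_i x_T(i) X_i (growth rate = total uptake). */
        double mu = 0.0;
        for (int i = 0; i < n; i++)
            if (D[i] != 0.0)
                mu += D[i] * y[(int) T[i] - 1] * X[i];
        for (int i = 0; i < n; i++) {
            if (D[i] != 0.0)
                ydot[i] += D[i] * y[(int) T[i] - 1] * X[i];
            ydot[i] -= mu * y[i];
        }
    }

    for (int i = 0; i < n; i++)
        if (clamp[i] != 0.0)
            ydot[i] = 0.0;

    if (maxflux != NULL)
        *maxflux = mf;
}

void kr_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    kr_core(y, ydot, NULL);
}

void kr_jac(int *neq, double *t, double *y, int *ml, int *mu_,
            double *pd, int *nrowpd, double *yout, int *ip)
{
    int n = (int) pm[2];
    int R = (int) pm[3];
    int mode = (int) pm[1];
    int nr = *nrowpd;
    const double *sub1 = pm + KR_HEAD;
    const double *sub2 = sub1 + R;
    const double *prd1 = sub2 + R;
    const double *prd2 = prd1 + R;
    const double *a = prd2 + R;
    const double *b = a + R;
    const double *D = b + R;
    const double *X = D + n;
    const double *T = X + n;
    const double *clamp = T + n;

    for (int j = 0; j < n; j++)
        for (int i = 0; i < n; i++)
            pd[i + j * nr] = 0.0;

    for (int r = 0; r < R; r++) {
        int s1 = (int) sub1[r] - 1;
        int s2 = (int) sub2[r] - 1;
        int p1 = (int) prd1[r] - 1;
        int p2 = (int) prd2[r] - 1;
        /* dJ/dx contributions (product rule; duplicate species accumulate) */
        int var[4];
        double coef[4];
        int m = 0;
        var[m] = s1;
        coef[m++] = a[r] * (s2 >= 0 ? y[s2] : 1.0);
        if (s2 >= 0) {
            var[m] = s2;
            coef[m++] = a[r] * y[s1];
        }
        var[m] = p1;
        coef[m++] = -b[r] * (p2 >= 0 ? y[p2] : 1.0);
        if (p2 >= 0) {
            var[m] = p2;
            coef[m++] = -b[r] * y[p1];
        }
        for (int q = 0; q < m; q++) {
            int j = var[q];
            double c = coef[q];
            pd[s1 + j * nr] -= c;
            if (s2 >= 0)
                pd[s2 + j * nr] -= c;
            pd[p1 + j * nr] += c;
            if (p2 >= 0)
                pd[p2 + j * nr] += c;
        }
    }

    if (mode == 0) {
        for (int i = 0; i < n; i++)
            if (D[i] != 0.0)
                pd[i + i * nr] -= D[i];
    } else {
        double mu = 0.0;
        for (int i = 0; i < n; i++)
            if (D[i] != 0.0)
                mu += D[i] * y[(int) T[i] - 1] * X[i];
        for (int i = 0; i < n; i++) {
            if (D[i] != 0.0)
                pd[i + ((int) T[i] - 1) * nr] += D[i] * X[i];
            pd[i + i * nr] -= mu;
        }
        /* -x_i * dmu/dx_j */
        for (int i = 0; i < n; i++) {
            if (D[i] == 0.0)
                continue;
            int j = (int) T[i] - 1;
            double g = D[i] * X[i];
            for (int k = 0; k < n; k++)
                pd[k + j * nr] -= y[k] * g;
        }
    }

    for (int i = 0; i < n; i++)
        if (clamp[i] != 0.0)
            for (int j = 0; j < n; j++)
                pd[i + j * nr] = 0.0;
}

void kr_root(int *neq, double *t, double *y, int *ng, double *gout,
             double *out, int *ip)
{
    int n = (int) pm[2];
    int R = (int) pm[3];
    int rootmode = (int) pm[4];
    const double *xst = pm + KR_HEAD + 6 * R + 4 * n;
    const double *tail = pm + KR_HEAD + 6 * R + 5 * n;
    double disttol = tail[0];
    double epsabs = tail[1];
    double epsrel = tail[2];
    double g = 1e300;

    if (rootmode & 1) {
        double d2 = 0.0;
        for (int i = 0; i < n; i++) {
            double yi = y[i] > 1e-300 ? y[i] : 1e-300;
            double xi = xst[i] > 1e-300 ? xst[i] : 1e-300;
            double d = log(yi) - log(xi);
            d2 += d * d;
        }
        double gd = sqrt(d2) - disttol;
        if (gd < g)
            g = gd;
    }
    if (rootmode & 2) {
        double ydot[1024];
        double mf = 0.0, md = 0.0;
        if (n > 1024)
            error("kinresponse: state dimension exceeds compiled root buffer");
        kr_core(y, ydot, &mf);
        for (int i = 0; i < n; i++) {
            double ad = fabs(ydot[i]);
            if (ad > md)
                md = ad;
        }
        double gr = md - (epsabs + epsrel * mf);
        if (gr < g)
            g = gr;
    }
    gout[0] = g;
}
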