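/* Four-population thalamocortical neural mass model.
 *
 * State y = (PY, IN, TC, RE).  Cortical populations (PY, IN) have sigmoid
 * activation wrapping their whole input; thalamic populations (TC, RE) are
 * linear in their inputs.  Noise (amplitude alpha) enters the TC equation
 * only, scaled by 1/tau3 and sqrt(dt) (Euler-Maruyama).
 */
#include <R.h>
#include <Rinternals.h>
#include <Rmath.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* parameter vector layout (length 19):
 * 0..3   tau1..tau4
 * 4..12  c1..c9
 * 13..16 h_py, h_in, h_tc, h_re
 * 17     a
 * 18     theta
 */
static double parms[19];

void tcm_initmod(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, parms);
}

static R_INLINE double sigm(double x, double a, double theta)
{
    return 1.0 / (1.0 + exp(-a * (x - theta)));
}

static R_INLINE void tcm_rhs(const double *p, const double *y, double *dy)
{
    const double py = y[0], in = y[1], tc = y[2], re = y[3];
    const double a = p[17], th = p[18];
    dy[0] = (-py + sigm(p[4] * py - p[6] * in + p[12] * tc + p[13], a, th)) / p[0];
    dy[1] = (-in + sigm(p[5] * py + p[14], a, th)) / p[1];
    dy[2] = (-tc + p[10] * py - p[9] * re + p[15]) / p[2];
    dy[3] = (-re + p[11] * py - p[7] * re + p[8] * tc + p[16]) / p[3];
}

/* deSolve interface */
void tcm_derivs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    tcm_rhs(parms, y, ydot);
}

/* Fixed-step Euler-Maruyama (Euler when alpha == 0).
 * Records every `thin`-th step starting at t = 0; returns (nrec x 5) matrix
 * with columns t, PY, IN, TC, RE.  Errors out if any state exceeds `bound`.
 */
SEXP C_simulate_em(SEXP s_parms, SEXP s_alpha, SEXP s_init, SEXP s_nstep,
                   SEXP s_dt, SEXP s_thin, SEXP s_bound)
{
    const double *p = REAL(s_parms);
    const double alpha = asReal(s_alpha);
    const double dt = asReal(s_dt);
    const double bound = asReal(s_bound);
    const int nstep = asInteger(s_nstep);
    const int thin = asInteger(s_thin);
    const double sq = sqrt(dt) * alpha / p[2]; /* noise on TC, 1/tau3 scaled */

    double y[4], dy[4];
    for (int k = 0; k < 4; k++) y[k] = REAL(s_init)[k];

    const int nrec = nstep / thin + 1;
    SEXP out = PROTECT(allocMatrix(REALSXP, nrec, 5));
    double *o = REAL(out);
    int irec = 0;
    o[irec] = 0.0;
    for (int k = 0; k < 4; k++) o[irec + nrec * (k + 1)] = y[k];
    irec++;

    GetRNGstate();
    for (int i = 1; i <= nstep; i++) {
        tcm_rhs(p, y, dy);
        for (int k = 0; k < 4; k++) y[k] += dt * dy[k];
        if (alpha > 0.0) y[2] += sq * norm_rand();
        for (int k = 0; k < 4; k++) {
            if (!R_FINITE(y[k]) || fabs(y[k]) > bound) {
                PutRNGstate();
                UNPROTECT(1);
                error("state diverged (|state| > %g) at t = %g", bound, i * dt);
            }
        }
        if (i % thin == 0) {
            o[irec] = i * dt;
            for (int k = 0; k < 4; k++) o[irec + nrec * (k + 1)] = y[k];
            irec++;
        }
    }
    PutRNGstate();
    UNPROTECT(1);
    return out;
}

/* Adaptive Dormand-Prince 5(4) integrator recording on a fixed output grid.
 * Used for the deterministic solution path; dense output by cubic Hermite
 * interpolation within accepted steps.
 */
static const double DPc[7] = {0., 1. / 5, 3. / 10, 4. / 5, 8. / 9, 1., 1.};
static const double DPb5[7] = {35. / 384, 0., 500. / 1113, 125. / 192,
                               -2187. / 6784, 11. / 84, 0.};
static const double DPb4[7] = {5179. / 57600, 0., 7571. / 16695, 393. / 640,
                               -92097. / 339200, 187. / 2100, 1. / 40};
static const double DPa[7][6] = {
    {0, 0, 0, 0, 0, 0},
    {1. / 5, 0, 0, 0, 0, 0},
    {3. / 40, 9. / 40, 0, 0, 0, 0},
    {44. / 45, -56. / 15, 32. / 9, 0, 0, 0},
    {19372. / 6561, -25360. / 2187, 64448. / 6561, -212. / 729, 0, 0},
    {9017. / 3168, -355. / 33, 46732. / 5247, 49. / 176, -5103. / 18656, 0},
    {35. / 384, 0., 500. / 1113, 125. / 192, -2187. / 6784, 11. / 84}};

SEXP C_simulate_dp45(SEXP s_parms, SEXP s_init, SEXP s_times, SEXP s_rtol,
                     SEXP s_atol, SEXP s_bound)
{
    const double *p = REAL(s_parms);
    const double rtol = asReal(s_rtol), atol = asReal(s_atol);
    const double bound = asReal(s_bound);
    const double *tout = REAL(s_times);
    const int nout = LENGTH(s_times);

    double y[4], ynew[4], k[7][4], yerr, sc;
    for (int j = 0; j < 4; j++) y[j] = REAL(s_init)[j];

    SEXP out = PROTECT(allocMatrix(REALSXP, nout, 5));
    double *o = REAL(out);

    double t = tout[0];
    o[0] = t;
    for (int j = 0; j < 4; j++) o[nout * (j + 1)] = y[j];

    double h = 1e-4;
    const double tend = tout[nout - 1];
    int iout = 1;
    tcm_rhs(p, y, k[0]); /* FSAL */
    long nsteps = 0;

    while (t < tend && iout < nout) {
        if (++nsteps > 50000000L) {
            UNPROTECT(1);
            error("integrator exceeded step budget");
        }
        if (t + h > tend) h = tend - t;
        for (int s = 1; s < 7; s++) {
            double ytmp[4];
            for (int j = 0; j < 4; j++) {
                double acc = 0.0;
                for (int q = 0; q < s; q++) acc += DPa[s][q] * k[q][j];
                ytmp[j] = y[j] + h * acc;
            }
            tcm_rhs(p, ytmp, k[s]);
            if (s == 6) for (int j = 0; j < 4; j++) ynew[j] = ytmp[j];
        }
        /* error estimate */
        double errnorm = 0.0;
        for (int j = 0; j < 4; j++) {
            double e5 = 0.0, e4 = 0.0;
            for (int s = 0; s < 7; s++) {
                e5 += DPb5[s] * k[s][j];
                e4 += DPb4[s] * k[s][j];
            }
            yerr = h * (e5 - e4);
            sc = atol + rtol * fmax(fabs(y[j]), fabs(ynew[j]));
            errnorm += (yerr / sc) * (yerr / sc);
        }
        errnorm = sqrt(errnorm / 4.0);
        if (errnorm <= 1.0) { /* accept */
            double tnew = t + h;
            /* dense output: cubic Hermite on [t, tnew] */
            while (iout < nout && tout[iout] <= tnew + 1e-12) {
                double s01 = (tout[iout] - t) / h;
                double h00 = (1 + 2 * s01) * (1 - s01) * (1 - s01);
                double h10 = s01 * (1 - s01) * (1 - s01);
                double h01 = s01 * s01 * (3 - 2 * s01);
                double h11 = s01 * s01 * (s01 - 1);
                for (int j = 0; j < 4; j++)
                    o[iout + nout * (j + 1)] =
                        h00 * y[j] + h * h10 * k[0][j] + h01 * ynew[j] +
                        h * h11 * k[6][j];
                o[iout] = tout[iout];
                iout++;
            }
            t = tnew;
            for (int j = 0; j < 4; j++) {
                y[j] = ynew[j];
                k[0][j] = k[6][j]; /* FSAL */
                if (!R_FINITE(y[j]) || fabs(y[j]) > bound) {
                    UNPROTECT(1);
                    error("state diverged (|state| > %g) at t = %g", bound, t);
                }
            }
        }
        double fac = 0.9 * pow(fmax(errnorm, 1e-10), -0.2);
        fac = fmin(5.0, fmax(0.2, fac));
        h *= fac;
        if (h < 1e-12) {
            UNPROTECT(1);
            error("step size underflow at t = %g", t);
        }
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef callMethods[] = {
    {"C_simulate_em", (DL_FUNC)&C_simulate_em, 7},
    {"C_simulate_dp45", (DL_FUNC)&C_simulate_dp45, 6},
    {NULL, NULL, 0}};

void R_init_ictogen(DllInfo *info)
{
    R_registerRoutines(info, NULL, callMethods, NULL, NULL);
    R_forceSymbols(info, FALSE);
}
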