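/* Compiled right-hand sides for the four circadian feedback architectures.
 *
 * Species carry an extra trailing state `light` (0 dark / 1 light) with zero
 * derivative; it is toggled from R by integrator events so that square-wave
 * light-dark forcing is integrated with event-aligned restarts rather than
 * stepped over.  The light factor multiplies the Michaelis degradation vmax
 * of cytoplasmic clock protein X (D2) -- and of the cytoplasmic X:Y complex
 * (D5) in the semi-dual and dual models -- as (1 + delta * light).
 *
 * Parameter layouts must match the R-side templates in R/models.R exactly.
 */

#include <math.h>
#include <R.h>
#include <R_ext/Rdynload.h>

/* ---- parameter blocks (filled by deSolve via odeparms) ---- */

static double p_single[18];    /* S1 S2 K1 T1 T2 U1 U2 D1..D6 L1..L3 h delta */
static double p_duo[32];       /* S1..S4 K1 K2 A B T1 T2 U1 U2 D1..D12 L1..L6 h delta */
static double p_red[34];       /* S1..S4 K1 K2 T1..T4 U1..U4 D1..D12 L1..L6 h delta */

void initmod_single(void (*odeparms)(int *, double *))
{
    int n = 18;
    odeparms(&n, p_single);
}

void initmod_duo(void (*odeparms)(int *, double *))
{
    int n = 32;
    odeparms(&n, p_duo);
}

void initmod_red(void (*odeparms)(int *, double *))
{
    int n = 34;
    odeparms(&n, p_red);
}

/* Hill-repressed transcription: vmax * K^h / (K^h + r^h), r >= 0 */
static double hill_rep(double vmax, double K, double h, double r)
{
    double Kh = pow(K, h);
    double rh = (r > 0.0) ? pow(r, h) : 0.0;
    return vmax * Kh / (Kh + rh);
}

/* Michaelis-Menten rate: vmax * s / (K + s) */
static double mm(double vmax, double K, double s)
{
    return vmax * s / (K + s);
}

/* ---- single feedback model: y = (Mx, X, Xn, light) ----
 * Mx  mRNA(X):  Hill-repressed transcription by Xn, MM + linear degradation
 * X   protein:  translation, MM import/export, MM (light-modulated) + linear degr.
 * Xn  nuclear:  import - export, MM + linear degradation
 */
void derivs_single(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    const double *p = p_single;
    double S1 = p[0], S2 = p[1], K1 = p[2];
    double T1 = p[3], T2 = p[4], U1 = p[5], U2 = p[6];
    double D1 = p[7], D2 = p[8], D3 = p[9];
    double D4 = p[10], D5 = p[11], D6 = p[12];
    double L1 = p[13], L2 = p[14], L3 = p[15];
    double h = p[16], delta = p[17];

    double Mx = y[0], X = y[1], Xn = y[2], light = y[3];
    double lf = 1.0 + delta * light;
    double imp = mm(T1, T2, X), exp_ = mm(U1, U2, Xn);

    ydot[0] = hill_rep(S1, K1, h, Xn) - mm(D1, L1, Mx) - D4 * Mx;
    ydot[1] = S2 * Mx - imp + exp_ - lf * mm(D2, L2, X) - D5 * X;
    ydot[2] = imp - exp_ - mm(D3, L3, Xn) - D6 * Xn;
    ydot[3] = 0.0;
}

/* ---- semi-dual / dual feedback: y = (Mx, X, My, Y, C, Cn, light) ----
 * C = X:Y cytoplasmic complex, Cn = X:Y in nucleus (the output).
 * Equation 3 (mRNA(Y)) is constitutive for semi-dual (dual = 0) and
 * Hill-repressed by Cn for dual (dual = 1); all other equations coincide.
 */
static void derivs_duo(double *y, double *ydot, int dual)
{
    const double *p = p_duo;
    double S1 = p[0], S2 = p[1], S3 = p[2], S4 = p[3];
    double K1 = p[4], K2 = p[5], A = p[6], B = p[7];
    double T1 = p[8], T2 = p[9], U1 = p[10], U2 = p[11];
    const double *D = p + 12;   /* D1..D12 */
    const double *L = p + 24;   /* L1..L6  */
    double h = p[30], delta = p[31];

    double Mx = y[0], X = y[1], My = y[2], Y = y[3];
    double C = y[4], Cn = y[5], light = y[6];
    double lf = 1.0 + delta * light;

    double assoc = A * X * Y, dissoc = B * C;
    double imp = mm(T1, T2, C), exp_ = mm(U1, U2, Cn);

    ydot[0] = hill_rep(S1, K1, h, Cn) - mm(D[0], L[0], Mx) - D[6] * Mx;
    ydot[1] = S2 * Mx - assoc + dissoc - lf * mm(D[1], L[1], X) - D[7] * X;
    ydot[2] = (dual ? hill_rep(S3, K2, h, Cn) : S3)
              - mm(D[2], L[2], My) - D[8] * My;
    ydot[3] = S4 * My - assoc + dissoc - mm(D[3], L[3], Y) - D[9] * Y;
    ydot[4] = assoc - dissoc - imp + exp_ - lf * mm(D[4], L[4], C) - D[10] * C;
    ydot[5] = imp - exp_ - mm(D[5], L[5], Cn) - D[11] * Cn;
    ydot[6] = 0.0;
}

void derivs_semidual(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    derivs_duo(y, ydot, 0);
}

void derivs_dual(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    derivs_duo(y, ydot, 1);
}

/* ---- redundant feedback: y = (Mx, X, Xn, My, Y, Yn, light) ----
 * Two independent single-type loops; only the X loop's cytoplasmic
 * degradation (D2) is light-modulated.  Output is Xn + Yn.
 */
void derivs_redundant(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    const double *p = p_red;
    double S1 = p[0], S2 = p[1], S3 = p[2], S4 = p[3];
    double K1 = p[4], K2 = p[5];
    double T1 = p[6], T2 = p[7], T3 = p[8], T4 = p[9];
    double U1 = p[10], U2 = p[11], U3 = p[12], U4 = p[13];
    const double *D = p + 14;   /* D1..D12 */
    const double *L = p + 26;   /* L1..L6  */
    double h = p[32], delta = p[33];

    double Mx = y[0], X = y[1], Xn = y[2];
    double My = y[3], Y = y[4], Yn = y[5], light = y[6];
    double lf = 1.0 + delta * light;

    double impx = mm(T1, T2, X), expx = mm(U1, U2, Xn);
    double impy = mm(T3, T4, Y), expy = mm(U3, U4, Yn);

    ydot[0] = hill_rep(S1, K1, h, Xn) - mm(D[0], L[0], Mx) - D[6] * Mx;
    ydot[1] = S2 * Mx - impx + expx - lf * mm(D[1], L[1], X) - D[7] * X;
    ydot[2] = impx - expx - mm(D[2], L[2], Xn) - D[8] * Xn;
    ydot[3] = hill_rep(S3, K2, h, Yn) - mm(D[3], L[3], My) - D[9] * My;
    ydot[4] = S4 * My - impy + expy - mm(D[4], L[4], Y) - D[10] * Y;
    ydot[5] = impy - expy - mm(D[5], L[5], Yn) - D[11] * Yn;
    ydot[6] = 0.0;
}

/* ---- registration ---- */

static const R_CMethodDef CEntries[] = {
    {"initmod_single",   (DL_FUNC) &initmod_single,   1},
    {"initmod_duo",      (DL_FUNC) &initmod_duo,      1},
    {"initmod_red",      (DL_FUNC) &initmod_red,      1},
    {"derivs_single",    (DL_FUNC) &derivs_single,    6},
    {"derivs_semidual",  (DL_FUNC) &derivs_semidual,  6},
    {"derivs_dual",      (DL_FUNC) &derivs_dual,      6},
    {"derivs_redundant", (DL_FUNC) &derivs_redundant, 6},
    {NULL, NULL, 0}
};

void R_init_clockloops(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
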