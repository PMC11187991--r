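/* Log-density right-hand sides for the phage/lysogen community model,
 * used by deSolve through its compiled-function interface.
 *
 * State (natural logs of densities):
 *   [ x_1..x_ns | y_1..y_nl | (s) | (d_1..d_np) | (e_1..e_ns) ]
 * x: phage, y: lysogens of temperate strains, s: sensitive bacteria,
 * d: double lysogens (unordered class pairs), e: exposed (infected, not
 * yet lysed) cells. Optional blocks are present only when the matching
 * flag in the parameter vector is set.
 *
 * Parameter vector layout (doubles, set via C_lyso_set_parms):
 *   [0] nc  [1] ns  [2] nl  [3] flag_S  [4] flag_D  [5] tau  [6] kappa
 *   [7] npairs  [8] alpha0  [9] root_lo  [10] root_hi  [11] (reserved)
 *   then per strain, stride 8: class (1-based), f, lysogen index (1-based,
 *     0 for obligate lytic), alpha, gamma, delta, k, b
 *   then per pair, stride 2: class1, class2 (1-based)
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <stdlib.h>
#include <string.h>

static double *lyso_p = NULL;
static int lyso_np = 0;
static double *ws = NULL;   /* workspace */
static int ws_len = 0;

SEXP C_lyso_set_parms(SEXP v)
{
    int n = LENGTH(v);
    if (n < 12) error("parameter vector too short");
    if (n > lyso_np) {
        free(lyso_p);
        lyso_p = (double *) malloc(n * sizeof(double));
        if (!lyso_p) error("allocation failure");
    }
    lyso_np = n;
    memcpy(lyso_p, REAL(v), n * sizeof(double));

    int ns = (int) lyso_p[1], nc = (int) lyso_p[0], np = (int) lyso_p[7];
    int need = 3 * ns + 7 * nc + np + 16;
    if (need > ws_len) {
        free(ws);
        ws = (double *) malloc(need * sizeof(double));
        if (!ws) error("allocation failure");
        ws_len = need;
    }
    return R_NilValue;
}

#define P_NC     ((int) lyso_p[0])
#define P_NS     ((int) lyso_p[1])
#define P_NL     ((int) lyso_p[2])
#define P_FS     ((int) lyso_p[3])
#define P_FD     ((int) lyso_p[4])
#define P_TAU    (lyso_p[5])
#define P_KAPPA  (lyso_p[6])
#define P_NP     ((int) lyso_p[7])
#define P_ALPHA0 (lyso_p[8])
#define P_RLO    (lyso_p[9])
#define P_RHI    (lyso_p[10])
#define S_CLS(i) ((int) lyso_p[12 + 8*(i)] - 1)
#define S_F(i)   (lyso_p[12 + 8*(i) + 1])
#define S_LYS(i) ((int) lyso_p[12 + 8*(i) + 2] - 1)   /* -1 if none */
#define S_A(i)   (lyso_p[12 + 8*(i) + 3])
#define S_G(i)   (lyso_p[12 + 8*(i) + 4])
#define S_D(i)   (lyso_p[12 + 8*(i) + 5])
#define S_K(i)   (lyso_p[12 + 8*(i) + 6])
#define S_B(i)   (lyso_p[12 + 8*(i) + 7])
#define PAIR_C1(q) ((int) lyso_p[12 + 8*P_NS + 2*(q)] - 1)
#define PAIR_C2(q) ((int) lyso_p[12 + 8*P_NS + 2*(q) + 1] - 1)

/* Influx terms divided by the compartment's own density give the log-space
 * derivative; when a compartment sits many decades below its inflow scale
 * the ratio can overflow. Capping the log slope bounds the recovery time
 * at ~1e-10 generations without affecting resolved dynamics. */
#define LOG_SLOPE_CAP 1e12
static double capped(double x)
{
    if (!(x < LOG_SLOPE_CAP)) return LOG_SLOPE_CAP;   /* catches Inf/NaN */
    return x;
}

/* Single-copy rhs on y[0..n-1] -> ydot. */
static void lyso_rhs1(double *y, double *ydot)
{
    int ns = P_NS, nl = P_NL, nc = P_NC, np = P_NP;
    int has_s = P_FS, has_d = P_FD;
    double tau = P_TAU, kappa = P_KAPPA;
    int has_e = (tau > 0.0);

    int off_y = ns;
    int off_s = off_y + nl;
    int off_d = off_s + (has_s ? 1 : 0);
    int off_e = off_d + (has_d ? np : 0);

    double *Pd   = ws;             /* phage densities            [ns] */
    double *Lf   = ws + ns;        /* lysogen density per strain [ns] */
    double *feff = ws + 2 * ns;    /* effective f                [ns] */
    double *Lc    = ws + 3 * ns;           /* [nc] */
    double *lysP  = ws + 3 * ns + nc;      /* k (1-f) P by class  [nc] */
    double *lysoP = ws + 3 * ns + 2 * nc;  /* k f P by class      [nc] */
    double *kP    = ws + 3 * ns + 3 * nc;  /* k P by class        [nc] */
    double *gbar  = ws + 3 * ns + 4 * nc;  /* L-weighted gamma    [nc] */
    double *gsum  = ws + 3 * ns + 5 * nc;  /* sum gamma*L         [nc] */
    double *Dwith = ws + 3 * ns + 6 * nc;  /* doubles touching c  [nc] */
    double *Dp    = ws + 3 * ns + 7 * nc;  /* pair densities      [np] */

    double S = has_s ? exp(y[off_s]) : 0.0;
    double Ptot = 0.0, Ltot = 0.0, Dtot = 0.0, kPtot = 0.0;
    int i, c, q;

    for (c = 0; c < nc; c++) {
        Lc[c] = lysP[c] = lysoP[c] = kP[c] = gbar[c] = gsum[c] = Dwith[c] = 0.0;
    }
    for (i = 0; i < ns; i++) {
        Pd[i] = exp(y[i]);
        Ptot += Pd[i];
        Lf[i] = (S_LYS(i) >= 0) ? exp(y[off_y + S_LYS(i)]) : 0.0;
        Lc[S_CLS(i)] += Lf[i];
        Ltot += Lf[i];
        if (S_LYS(i) >= 0) gsum[S_CLS(i)] += S_G(i) * Lf[i];
    }
    for (i = 0; i < ns; i++) {
        double f = S_F(i);
        if (kappa > 0.0)
            f = 1.0 - (1.0 - f) / (1.0 + S_K(i) * Ptot / kappa);
        feff[i] = f;
        c = S_CLS(i);
        lysP[c]  += S_K(i) * (1.0 - f) * Pd[i];
        lysoP[c] += S_K(i) * f * Pd[i];
        kP[c]    += S_K(i) * Pd[i];
        kPtot    += S_K(i) * Pd[i];
    }
    double lysPtot = 0.0, lysoPtot = 0.0;
    for (c = 0; c < nc; c++) {
        lysPtot += lysP[c];
        lysoPtot += lysoP[c];
        gbar[c] = (Lc[c] > 0.0) ? gsum[c] / Lc[c] : 0.0;
    }
    if (has_d) {
        for (q = 0; q < np; q++) {
            Dp[q] = exp(y[off_d + q]);
            Dtot += Dp[q];
            Dwith[PAIR_C1(q)] += Dp[q];
            Dwith[PAIR_C2(q)] += Dp[q];
        }
    }

    /* phage and exposed compartments */
    for (i = 0; i < ns; i++) {
        c = S_CLS(i);
        double B = Ltot + S + Dtot;                  /* adsorbing cells */
        double prey = (Ltot - Lc[c]) + S + (has_d ? (Dtot - Dwith[c]) : 0.0);
        double ind = 0.0;                            /* induction flux */
        if (S_LYS(i) >= 0) {
            ind = S_G(i) * exp(y[off_y + S_LYS(i)] - y[i]);  /* gamma L / P */
            if (has_d && Lc[c] > 0.0)
                ind += S_G(i) * (Lf[i] / Lc[c]) * Dwith[c] / Pd[i];
        }
        if (!has_e) {
            ydot[i] = capped(S_B(i) * ind)
                - (S_D(i) + S_K(i) * B)
                + S_B(i) * S_K(i) * (1.0 - feff[i]) * prey;
        } else {
            double Ei = exp(y[off_e + i]);
            double influx = ind * Pd[i]
                + S_K(i) * (1.0 - feff[i]) * Pd[i] * prey;
            ydot[off_e + i] = capped(influx / Ei) - 1.0 / tau;
            ydot[i] = capped(S_B(i) * exp(y[off_e + i] - y[i]) / tau)
                - (S_D(i) + S_K(i) * B);
        }
    }

    /* single lysogens */
    for (i = 0; i < ns; i++) {
        int li = S_LYS(i);
        if (li < 0) continue;
        c = S_CLS(i);
        double dyi = (S_A(i) - S_G(i)) - (lysPtot - lysP[c]);
        if (has_d) dyi -= (lysoPtot - lysoP[c]);
        if (has_s && S > 0.0)
            dyi += capped(S_K(i) * feff[i] * S * exp(y[i] - y[off_y + li]));
        ydot[off_y + li] = dyi;
    }

    /* sensitive bacteria */
    if (has_s)
        ydot[off_s] = P_ALPHA0 - kPtot;

    /* double lysogens */
    if (has_d) {
        for (q = 0; q < np; q++) {
            int c1 = PAIR_C1(q), c2 = PAIR_C2(q);
            double formation = Lc[c1] * lysoP[c2] + Lc[c2] * lysoP[c1];
            double pressD = lysPtot - lysP[c1] - lysP[c2];
            ydot[off_d + q] = capped(formation / Dp[q])
                + (P_ALPHA0 - gbar[c1] - gbar[c2]) - pressD;
        }
    }
}

void lyso_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    lyso_rhs1(y, ydot);
}

/* Two independent copies of the system, for Benettin-style two-trajectory
 * Lyapunov estimation. */
void lyso_derivs_pair(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    int n = *neq / 2;
    lyso_rhs1(y, ydot);
    lyso_rhs1(y + n, ydot + n);
}

/* Evaluate the rhs once at `z` (for tests and fixed-point checks). */
SEXP C_lyso_eval(SEXP z)
{
    int n = LENGTH(z);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    lyso_rhs1(REAL(z), REAL(out));
    UNPROTECT(1);
    return out;
}

/* Terminal-root function: crosses zero when any log density leaves
 * [root_lo, root_hi] (used to stop runs that have effectively gone
 * extinct or are growing without bound). */
void lyso_root(int *neq, double *t, double *y, int *ng, double *gout,
               double *out, int *ip)
{
    double lo = y[0], hi = y[0];
    for (int i = 1; i < *neq; i++) {
        if (y[i] < lo) lo = y[i];
        if (y[i] > hi) hi = y[i];
    }
    gout[0] = lo - P_RLO;
    gout[1] = P_RHI - hi;
}

#include <R_ext/Rdynload.h>

static const R_CallMethodDef call_entries[] = {
    {"C_lyso_set_parms", (DL_FUNC) &C_lyso_set_parms, 1},
    {"C_lyso_eval",      (DL_FUNC) &C_lyso_eval,      1},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_entries[] = {
    {"lyso_derivs",      (DL_FUNC) &lyso_derivs,      6},
    {"lyso_derivs_pair", (DL_FUNC) &lyso_derivs_pair, 6},
    {"lyso_root",        (DL_FUNC) &lyso_root,        7},
    {NULL, NULL, 0}
};

void R_init_lysochaos(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
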