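/* Right-hand sides of the dimensionless clock ODEs, in the standard
 * deSolve compiled-model form.  One derivs routine covers all model
 * families; the variant is encoded in the parameter vector.
 *
 * parms layout (length 12):
 *   0 law          0 = rate law 0 (A_free/A_T), 1 = rate law 1 (A_free/(K_A+A_T))
 *   1 degradation  0 = linear, 1 = Michaelis-Menten
 *   2 J            number of chain intermediates (N - 2)
 *   3 family       0 = SNF, 1 = NNF, 2 = PNF
 *   4 alpha
 *   5 A_T (SNF) or A_MAX (NNF/PNF)
 *   6 beta_max
 *   7 K_m
 *   8 K_A
 *   9 V_MAX (NNF) or R_MAX (PNF)
 *  10 delta
 *  11 epsilon
 *
 * state layout: M, P_1..P_J, P [, A_T, V-or-R]
 */

#include <R.h>
#include <math.h>

static double parms[12];

void circlock_init(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

/* free activator from the sequestration quadratic (dimensionless K_d = 1),
 * evaluated in the cancellation-safe branch */
static double afree_c(double AT, double P)
{
    double b = AT - P - 1.0;
    double s = sqrt(b * b + 4.0 * AT);
    if (b >= 0.0)
        return 0.5 * (b + s);
    return 2.0 * AT / (s - b);
}

void circlock_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    int law = (int) parms[0], deg = (int) parms[1];
    int J = (int) parms[2], fam = (int) parms[3];
    double alpha = parms[4], beta_max = parms[6];
    double Km = parms[7], KA = parms[8];
    int n = J + 2;              /* core species: M, P_1..P_J, P */
    double M = y[0], P = y[1 + J];
    double AT = (fam == 0) ? parms[5] : y[n];
    double Af = afree_c(AT, P);
    double F = (law == 0) ? Af / AT : Af / (KA + AT);
    double G = (deg == 0) ? P : beta_max * P / (Km + P);
    int j;

    ydot[0] = alpha * F - M;
    ydot[1] = M - y[1];
    for (j = 2; j <= J; j++)
        ydot[j] = y[j - 1] - y[j];
    ydot[1 + J] = y[J] - G;

    if (fam == 1) {             /* NNF: REV-ERB represses Bmal1 */
        double V = y[n + 1], del = parms[10];
        double AMAX = parms[5], VMAX = parms[9];
        ydot[n] = del * (AMAX / (V + 1.0) - AT);
        ydot[n + 1] = del * (VMAX * F - V);
    } else if (fam == 2) {      /* PNF: ROR activates Bmal1 */
        double R = y[n + 1], del = parms[10];
        double AMAX = parms[5], RMAX = parms[9], eps = parms[11];
        ydot[n] = del * (AMAX * (eps + R) / (R + 1.0) - AT);
        ydot[n + 1] = del * (RMAX * F - R);
    }
}
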