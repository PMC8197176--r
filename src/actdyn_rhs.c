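/* Compiled right-hand side for the tumour/CTL ODE system, used through
 * deSolve's compiled-model interface. Parameter vector (set via initfunc):
 * p = (g, s_eff, k_e, k_i, d_i, k_r, d_r, k_q, d_q), where s_eff is the
 * infiltration constant already gated on the transfer day (the integration
 * is split there, so s_eff is constant within one solver call).
 * State y = (T_p, T_q, E, I, R). Per-tumour-cell terms are ramped
 * continuously to zero below one cell (exact T_x/T and E/T above it),
 * mirroring the reference R implementation. */

#include <R.h>
#include <math.h>

static double p[9];

void actdyn_init(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, p);
}

void actdyn_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double g = p[0], s_eff = p[1], k_e = p[2], k_i = p[3], d_i = p[4],
           k_r = p[5], d_r = p[6], k_q = p[7], d_q = p[8];
    double T_p = y[0] > 0 ? y[0] : 0;
    double T_q = y[1] > 0 ? y[1] : 0;
    double E   = y[2] > 0 ? y[2] : 0;
    double I   = y[3] > 0 ? y[3] : 0;
    double R   = y[4] > 0 ? y[4] : 0;
    double T = T_p + T_q;
    double Tc = T > 1 ? T : 1;
    double f_p = T_p / Tc;
    double f_q = T_q / Tc;
    double et = E * T / (Tc * Tc);

    ydot[0] = g * T_p - (k_e + k_q) * f_p * E + d_q * T_q;
    ydot[1] = k_q * f_p * E - k_e * f_q * E - d_q * T_q;
    ydot[2] = s_eff * pow(T, 2.0 / 3.0) + E * (I - R);
    ydot[3] = k_i * et - d_i * I;
    ydot[4] = k_r * et - d_r * R;
}
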