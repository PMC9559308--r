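/* Compiled rhs of the per-zone fed-batch fermentation ODEs for deSolve.
 *
 * State layout (zone-major, 4 species per zone so the Jacobian is
 * banded with half-bandwidth 4):
 *   y[4k+0] = C_x, y[4k+1] = C_s, y[4k+2] = C_p, y[4k+3] = C_o  (kg/m3)
 *
 * Parameter vector layout (padded to P_LEN doubles):
 *   [0]      nz
 *   [1..11]  mu_max, K_s, K_o, K_p, Y_px, r_xp, Y_xs, Y_ps, Y_so, r_ms, r_mo
 *   [12]     K_gate   (substrate starvation gate, kg/m3)
 *   [13]     K_gate_o (oxygen starvation gate, kg/m3)
 *   [14 .. ]            V[nz], Qh[nz-1] (m3/hr), kla[nz] (1/hr),
 *                       C_sat[nz], feed_conc_rate[nz] (kg/m3/hr)
 */
#include <R.h>

#define P_LEN 2048
static double parms[P_LEN];

void initferm(void (*odeparms)(int *, double *))
{
    int n = P_LEN;
    odeparms(&n, parms);
}

static inline double flo(double x) { return x > 0 ? x : 0; }

void ferm_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const int nz = (int) parms[0];
    const double mu_max = parms[1], K_s = parms[2], K_o = parms[3],
        K_p = parms[4], Y_px = parms[5], r_xp = parms[6], Y_xs = parms[7],
        Y_ps = parms[8], Y_so = parms[9], r_ms = parms[10], r_mo = parms[11],
        K_gate = parms[12], K_gate_o = parms[13];
    const double *V = parms + 14;
    const double *Qh = V + nz;
    const double *kla = Qh + (nz - 1);
    const double *Csat = kla + nz;
    const double *feed = Csat + nz;

    for (int k = 0; k < nz; k++) {
        const int b = 4 * k;
        const double Cx = flo(y[b]), Cs = flo(y[b + 1]),
            Cp = flo(y[b + 2]), Co = flo(y[b + 3]);
        const double mu = mu_max * (Cs / (Cs + K_s)) * (Co / (Co + K_o))
            * (1 - Cp / K_p);
        const double gs = Cs / (Cs + K_gate);
        const double rp = Y_px * mu + r_xp * gs;
        const double rs = mu / Y_xs + rp / Y_ps + r_ms * gs;
        const double ro = (rs / Y_so + r_mo) * Co / (Co + K_gate_o);
        ydot[b]     = mu * Cx;
        ydot[b + 1] = -rs * Cx + feed[k];
        ydot[b + 2] = rp * Cx;
        ydot[b + 3] = kla[k] * (Csat[k] - Co) - ro * Cx;
    }
    /* symmetric bidirectional exchange between neighbouring zones */
    for (int i = 0; i < nz - 1; i++) {
        for (int s = 0; s < 4; s++) {
            const int lo = 4 * i + s, hi = lo + 4;
            const double d = Qh[i] * (flo(y[hi]) - flo(y[lo]));
            ydot[lo] += d / V[i];
            ydot[hi] -= d / V[i + 1];
        }
    }
}
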