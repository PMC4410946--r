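/* Right-hand side of the nine-state neural mass model, in the form deSolve
 * expects for compiled models.  Parameter block (12 doubles):
 *   0..9  g1 g2 g3 g4 delta tau_i h_i tau_e h_e u   (canonical order)
 *   10    input onset time (Heaviside, right-continuous)
 *   11    delay mode: 0 = none, 1 = first-order Taylor delay approximation
 */
#include <R.h>
#include <math.h>

static double parms[12];

void nmm_init(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, parms);
}

static double sig(double v)
{
    return 1.0 / (1.0 + exp(-0.56 * v)) - 0.5;
}

void nmm_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double g1 = parms[0], g2 = parms[1], g3 = parms[2], g4 = parms[3];
    double del = parms[4], ti = parms[5], hi = parms[6];
    double te = parms[7], he = parms[8], u = parms[9];
    double onset = parms[10];
    double U = (*t >= onset) ? u : 0.0;
    double d1, d7, d9;

    if (parms[11] > 0.5) {
        /* delayed states via x(t - delta) ~ x(t) - delta * xdot(t), with the
         * position-state derivatives known exactly */
        d9 = y[8] - del * (y[4] - y[5]);
        d1 = y[0] - del * y[3];
        d7 = y[6] - del * y[7];
    } else {
        d9 = y[8];
        d1 = y[0];
        d7 = y[6];
    }

    ydot[0] = y[3];
    ydot[1] = y[4];
    ydot[2] = y[5];
    ydot[3] = he * (g1 * sig(d9) + U) / te - y[0] / (te * te) - 2.0 * y[3] / te;
    ydot[4] = g2 * he * sig(d1) / te - y[1] / (te * te) - 2.0 * y[4] / te;
    ydot[5] = g4 * hi * sig(d7) / ti - y[2] / (ti * ti) - 2.0 * y[5] / ti;
    ydot[6] = y[7];
    ydot[7] = g3 * he * sig(d9) / te - y[6] / (te * te) - 2.0 * y[7] / te;
    ydot[8] = y[4] - y[5];
}
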