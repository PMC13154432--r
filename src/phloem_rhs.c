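/* Right-hand side of the four-compartment phloem tracer model, in the
 * form expected by deSolve's compiled-model interface.
 *
 * State vector y (all concentrations in MBq mL^-1, time in seconds):
 *   y[0]  C2 of the input ROI        y[1]  C3 of the input ROI
 *   y[2..4]   C1, C2, C3 of ROI 1
 *   y[5..7]   C1, C2, C3 of ROI 2
 *   y[8..10]  C1, C2, C3 of ROI 3
 *   y[11] cumulative advective inflow into ROI 1
 *   y[12] cumulative efflux to the atmosphere from ROIs 1-3
 *   y[13] cumulative advective outflow from ROI 3
 *
 * C1 of the input ROI is algebraic: measured total (forcing) minus its
 * own C2 and C3, floored at zero.  It is reported as an extra output.
 */
#include <R.h>

static double parms[5]; /* k = s_Ph/l [1/s], a12, h, b, c */
static double forc[1];  /* measured total concentration of the input ROI */

#define K_ADV parms[0]
#define A12   parms[1]
#define HCONST parms[2]
#define B_STO parms[3]
#define C_EFF parms[4]
#define TOTAL_IN forc[0]

void phloem_initmod(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, parms);
}

void phloem_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

void phloem_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double ret = HCONST * A12;      /* retrieval rate a21 */
    double loss = ret + B_STO + C_EFF;

    double c1_in = TOTAL_IN - y[0] - y[1];
    if (c1_in < 0.0) c1_in = 0.0;

    ydot[0] = A12 * c1_in - loss * y[0];
    ydot[1] = B_STO * y[0];

    double upstream = c1_in;
    for (int i = 0; i < 3; i++) {
        double c1 = y[2 + 3 * i];
        double c2 = y[3 + 3 * i];
        ydot[2 + 3 * i] = K_ADV * upstream - K_ADV * c1 - A12 * c1 + ret * c2;
        ydot[3 + 3 * i] = A12 * c1 - loss * c2;
        ydot[4 + 3 * i] = B_STO * c2;
        upstream = c1;
    }

    ydot[11] = K_ADV * c1_in;
    ydot[12] = C_EFF * (y[3] + y[6] + y[9]);
    ydot[13] = K_ADV * y[8];

    if (ip[0] >= 1) yout[0] = c1_in;
}
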