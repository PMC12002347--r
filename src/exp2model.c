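/* Right-hand side of the pharyngeal muscle membrane model, in the form
 * expected by deSolve's compiled-model interface.
 *
 * State vector (9): V, w, h, mT, hT, mL, hL, gE, gI
 *   V      membrane potential, mV
 *   w      K-current activation
 *   h      K-current inactivation (ignored in the ultrafast variant,
 *          where the instantaneous steady state h_inf(V) is used)
 *   mT,hT  T-type Ca activation / inactivation
 *   mL,hL  L-type Ca activation / inactivation
 *   gE,gI  excitatory / inhibitory synaptic conductances, nS
 *
 * Units: mV, ms, nS, pF, pA; dV/dt = I/C needs no conversion factor.
 */
#include <R.h>
#include <math.h>

static double parms[16];
#define C_m    parms[0]
#define G_L    parms[1]
#define G_K    parms[2]
#define G_CAT  parms[3]
#define G_CAL  parms[4]
#define V_L    parms[5]
#define V_K    parms[6]
#define V_CA   parms[7]
#define V_SYNE parms[8]
#define V_SYNI parms[9]
#define VHALF  parms[10]
#define KINACT parms[11]
#define W_RATE parms[12]
#define TAU_E  parms[13]
#define TAU_I  parms[14]
#define TAU_H  parms[15]   /* <= 0 encodes the ultrafast (instantaneous) variant */

void exp2_initmod(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

void exp2_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double V  = y[0], w  = y[1], h  = y[2];
    const double mT = y[3], hT = y[4], mL = y[5], hL = y[6];
    const double gE = y[7], gI = y[8];

    const double winf  = 0.5 * (1.0 + tanh((V - 12.0) / 17.4));
    const double tauw  = 1.0 / cosh((V - 12.0) / 34.8);
    const double hinf  = 0.5 * (1.0 - tanh((V - VHALF) / KINACT));
    const double mTinf = 0.5 * (1.0 + tanh((V + 45.0) / 6.0));
    const double taumT = 1.0 / (0.5 * cosh((V - 14.5) / 34.8));
    const double hTinf = 0.5 * (1.0 - tanh((V + 40.0) / 3.0));
    const double tauhT = 65.0 / (1.0 + exp((V + 40.0) / 7.0));
    const double mLinf = 1.0 / (1.0 + exp(-(V + 20.0) / 6.5));
    const double taumL = 1.0 / (1.0 + exp((V + 27.0) / 10.0));
    const double hLinf = 1.0 / (1.0 + exp((V - 135.0) / 55.0));
    const double tauhL = 200.0 + 100.0 / (1.0 + exp((V + 40.0) / 7.0));

    const double hK = (TAU_H > 0.0) ? h : hinf;

    const double I = -G_L * (V - V_L)
                     - G_CAT * mT * mT * hT * (V - V_CA)
                     - G_K * w * hK * (V - V_K)
                     - G_CAL * mL * mL * hL * (V - V_CA)
                     - gE * (V - V_SYNE)
                     - gI * (V - V_SYNI);

    ydot[0] = I / C_m;
    ydot[1] = W_RATE * (winf - w) / tauw;
    ydot[2] = (TAU_H > 0.0) ? (hinf - h) / TAU_H : 0.0;
    ydot[3] = (mTinf - mT) / taumT;
    ydot[4] = (hTinf - hT) / tauhT;
    ydot[5] = (mLinf - mL) / taumL;
    ydot[6] = (hLinf - hL) / tauhL;
    ydot[7] = -gE / TAU_E;
    ydot[8] = -gI / TAU_I;
}
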