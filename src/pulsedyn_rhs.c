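/* Right-hand side of the two-species birth-death model, callable from
 * deSolve's lsoda via the compiled-code interface.
 *
 * State y = (w, r): wild-type and resistant abundance in carrying-capacity
 * units.  Parameters (in order):
 *   0 lambda_w  wild-type growth rate
 *   1 lambda_r  resistant growth rate (= lambda_w - cost)
 *   2 delta     death rate (both species)
 *   3 mu_w      switching rate w -> r
 *   4 mu_r      switching rate r -> w
 *   5 grow_w    1 if the environment is below the wild-type MIC, else 0
 *   6 grow_r    1 if the environment is below the resistant MIC, else 0
 *
 * Within one schedule segment the environment flags are constant, so the
 * RHS is smooth; segment boundaries are handled by restarting the solver.
 */
#include <R.h>

static double parms[7];

#define LAMBDA_W parms[0]
#define LAMBDA_R parms[1]
#define DELTA    parms[2]
#define MU_W     parms[3]
#define MU_R     parms[4]
#define GROW_W   parms[5]
#define GROW_R   parms[6]

void pd_initmod(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void pd_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    double w = y[0], r = y[1];
    double open = 1.0 - w - r;           /* shared logistic pool */
    double phi_w = GROW_W * LAMBDA_W * open;
    double phi_r = GROW_R * LAMBDA_R * open;

    ydot[0] = (phi_w - DELTA - MU_W) * w + MU_R * r;
    ydot[1] = MU_W * w + (phi_r - DELTA - MU_R) * r;
}
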