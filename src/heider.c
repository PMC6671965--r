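/* Right-hand side and corner-detection root function of the relation
 * dynamics, in the form deSolve expects from compiled model code.
 *
 * The state vector is the full n x n relation matrix in column-major
 * order; diagonal entries are not dynamical and are held at 0, which
 * makes the matrix product x %*% x equal the sum over k != i, j.
 */
#include <math.h>
#include <R.h>

static double parms[2];
#define N_NODES parms[0]
#define CORNER_THR parms[1] /* 1 - tol */

void heider_init(void (*odeparms)(int *, double *))
{
    int np = 2;
    odeparms(&np, parms);
}

static double clamp1(double x)
{
    if (x > 1.0) return 1.0;
    if (x < -1.0) return -1.0;
    return x;
}

/* The exact flow cannot leave [-1, 1], but an adaptive solver can
 * overshoot the boundary by a rounding error; beyond it the raw vector
 * field may point outwards (finite-time blowup), collapsing the step
 * size.  Evaluating the field on the clamped state removes the spurious
 * exterior dynamics without altering it inside the domain. */
void heider_deriv(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int n = (int) N_NODES;
    for (int j = 0; j < n; j++) {
        for (int i = 0; i < n; i++) {
            int idx = i + n * j;
            if (i == j) {
                ydot[idx] = 0.0;
                continue;
            }
            double s = 0.0;
            for (int k = 0; k < n; k++) {
                if (k == i || k == j)
                    continue;
                s += clamp1(y[i + n * k]) * clamp1(y[k + n * j]);
            }
            double x = clamp1(y[idx]);
            ydot[idx] = (1.0 - x * x) * s;
        }
    }
}

/* Root: crosses zero when the entry of smallest magnitude reaches
 * 1 - tol, i.e. when every |x_ij| is within tol of 1. */
void heider_root(int *neq, double *t, double *y, int *ng, double *gout,
                 double *out, int *ip)
{
    int n = (int) N_NODES;
    double m = 2.0;
    for (int j = 0; j < n; j++) {
        for (int i = 0; i < n; i++) {
            if (i == j)
                continue;
            double a = fabs(y[i + n * j]);
            if (a < m)
                m = a;
        }
    }
    gout[0] = m - CORNER_THR;
}
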