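/* Generic mass-action derivative for deSolve compiled models.
 *
 * The scheme is flattened into the parameter vector:
 *   p[0] = number of species
 *   p[1] = number of reactions
 *   then 7 slots per reaction:
 *     [k, n_reactants, r1, r2, n_products, p1, p2]
 *   species indices are 0-based; unused slots are -1.
 * At most two reactants and two products per elementary step, which covers
 * every uni- and bimolecular step in the polymerase schemes.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

#define POLGKIN_NPMAX 1024

static double parms[POLGKIN_NPMAX];

void polgkin_initmod(void (*odeparms)(int *, double *))
{
    int n = POLGKIN_NPMAX;
    odeparms(&n, parms);
}

void polgkin_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int ns = (int) parms[0];
    int nr = (int) parms[1];
    const double *rp = parms + 2;
    int i, j, a;

    for (i = 0; i < ns; i++)
        ydot[i] = 0.0;

    for (j = 0; j < nr; j++, rp += 7) {
        double v = rp[0];
        int nreac = (int) rp[1];
        int nprod = (int) rp[4];
        for (a = 0; a < nreac; a++)
            v *= y[(int) rp[2 + a]];
        for (a = 0; a < nreac; a++)
            ydot[(int) rp[2 + a]] -= v;
        for (a = 0; a < nprod; a++)
            ydot[(int) rp[5 + a]] += v;
    }
}

static const R_CMethodDef CEntries[] = {
    {"polgkin_initmod", (DL_FUNC) &polgkin_initmod, 1},
    {"polgkin_derivs",  (DL_FUNC) &polgkin_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_polgkin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
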