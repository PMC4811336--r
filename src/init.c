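#include <stddef.h>
#include <R_ext/Rdynload.h>

void ecbstdp_init(void (*odeparms)(int *, double *));
void ecbstdp_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip);

static const R_CMethodDef cMethods[] = {
    {"ecbstdp_init",   (DL_FUNC) &ecbstdp_init,   1},
    {"ecbstdp_derivs", (DL_FUNC) &ecbstdp_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_ecbstdp(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
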