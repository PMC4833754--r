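/* Routine registration. The .Call entries are the Rcpp exports from
 * RcppExports.cpp (whose generated R_init block is replaced by this
 * file); the .C entries expose the kinetics right-hand side to deSolve,
 * which looks compiled derivative functions up by name. */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP _trxss_debye_direct_cpp(SEXP, SEXP, SEXP);
extern SEXP _trxss_debye_hist_cpp(SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP _trxss_clash_penalty_cpp(SEXP, SEXP, SEXP, SEXP, SEXP);

void hbi_initparms(void (*odeparms)(int *, double *));
void hbi_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CallMethodDef CallEntries[] = {
    {"_trxss_debye_direct_cpp", (DL_FUNC) &_trxss_debye_direct_cpp, 3},
    {"_trxss_debye_hist_cpp", (DL_FUNC) &_trxss_debye_hist_cpp, 5},
    {"_trxss_clash_penalty_cpp", (DL_FUNC) &_trxss_clash_penalty_cpp, 5},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"hbi_initparms", (DL_FUNC) &hbi_initparms, 1},
    {"hbi_derivs", (DL_FUNC) &hbi_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_trxss(DllInfo *dll) {
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
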