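/* Right-hand side of the HbI photocycle rate equations, in the form
 * expected by deSolve's compiled-function interface.
 *
 * State vector (concentrations, mM):
 *  0 I1_full   fully photolyzed I1 (2 CO in pocket)
 *  1 I1_part   partially photolyzed I1 (1 pocket + 1 bound CO)
 *  2 I2_fg     fully photolyzed I2, geminate channel
 *  3 I2_fr     fully photolyzed I2, R-T channel
 *  4 I2_pg     partially photolyzed I2, geminate channel
 *  5 I2_pr     partially photolyzed I2, R-T channel
 *  6 I1_lig    ligated I1 (geminate product, 2 bound CO)
 *  7 I3_full   deoxy T-like intermediate, both CO escaped
 *  8 I3_part   T-like intermediate, 1 bound CO
 *  9 G         recovered ground state HbI(CO)2
 * 10 CO        free dissolved CO
 *
 * Parameters (SI seconds; k_bi in 1/(mM s)):
 *  0 tau12  1 tau_gem  2 tau_RT1  3 tau_RT2  4 tau_lig  5 k_bi
 *  6 f_gem  7 (unused here; phi_full enters the initial condition)
 */
#include <R.h>

static double parms[8];

void hbi_initparms(void (*odeparms)(int *, double *)) {
  int n = 8;
  odeparms(&n, parms);
}

void hbi_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  const double k12  = 1.0 / parms[0];
  const double kgem = 1.0 / parms[1];
  const double kRT1 = 1.0 / parms[2];
  const double kRT2 = 1.0 / parms[3];
  const double klig = 1.0 / parms[4];
  const double kbi  = parms[5];
  const double fg   = parms[6];

  const double I1f = y[0], I1p = y[1];
  const double I2fg = y[2], I2fr = y[3], I2pg = y[4], I2pr = y[5];
  const double I1L = y[6], I3f = y[7], I3p = y[8], CO = y[10];

  ydot[0] = -k12 * I1f;
  ydot[1] = -k12 * I1p;
  ydot[2] = fg * k12 * I1f - kgem * I2fg;
  ydot[3] = (1.0 - fg) * k12 * I1f - kRT1 * I2fr;
  ydot[4] = fg * k12 * I1p - kgem * I2pg;
  ydot[5] = (1.0 - fg) * k12 * I1p - kRT2 * I2pr;
  ydot[6] = kgem * (I2fg + I2pg) - klig * I1L;
  ydot[7] = kRT1 * I2fr - kbi * I3f * CO;
  ydot[8] = kRT2 * I2pr - kbi * I3p * CO;
  ydot[9] = klig * I1L + kbi * (I3f + I3p) * CO;
  /* CO escapes to solvent at the I2 -> I3 event (2 per fully, 1 per
   * partially photolyzed molecule) and is consumed 2:1 on recovery */
  ydot[10] = 2.0 * kRT1 * I2fr + kRT2 * I2pr
           - kbi * (2.0 * I3f + I3p) * CO;
}
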