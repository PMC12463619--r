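# Example configuration for the aggnmr command-line interface.
# Unit-bearing values accept SI prefixes: M/mM/uM/nM, s/ms/us, Hz/kHz/MHz.
equilibrium:
  kd1: 70 mM        # m <-> D
  kd1_star: 200 mM  # m <-> D* (off-pathway)
  kd2: 30 uM        # D <-> T
  kd_mi: 50 uM      # m + I <-> mI
totals:
  p_tot: 1.2 mM
  i_tot: 0.8 mM
exchange:
  tau_mdstar: 750 us
  tau_mt: 50 us
  delta_d: 2        # ppm vs monomer
  delta_dstar: 1
  delta_t: 4
  r2_0: 8           # s^-1
  b0_frequency: 60.8  # MHz (15N at 14.1 T)
observables:
  r2_ref: 4         # s^-1, PRD reference linewidth
kinetics:
  k_conv: 2e-6      # s^-1, T -> P
  k_e: 500          # M^-1 s^-1, elongation
  k_2: 1            # M^-2 s^-1 per unit fibril mass, secondary nucleation
  p0: 1 nM          # pre-existing nuclei
  scheme: monomer_binding
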