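# Toy per-element rate tables for hydrogen and oxygen (synthetic; order-of-
# magnitude constants assembled for water-sample simulations).  These tables
# are *inputs* to the engine: binding energies, photoionization cross
# sections at the configured photon energy, inner-shell decay rates and the
# impact-ionization model constant.  They stand for the output of an ab
# initio atomic-structure calculation, which is outside this package's scope.
#
# Units: binding_eV in eV; sigma_ph_Mb in megabarn (1 Mb = 1e-18 cm^2) at
# ~7 keV photon energy (hard X-ray regime, well above the O K edge);
# rates in 1/fs; auger_energy_eV in eV; masses in u.
elements:
  H:
    mass_u: 1.008
    orbitals:
      - name: 1s
        capacity: 1
        occupation: 1
        binding_eV: 13.6
        sigma_ph_Mb: 1.0e-08
    core_hole: null
  O:
    mass_u: 15.999
    orbitals:
      - name: 1s
        capacity: 2
        occupation: 2
        binding_eV: 543.1
        sigma_ph_Mb: 4.0e-05
      - name: 2s
        capacity: 2
        occupation: 2
        binding_eV: 41.6
        sigma_ph_Mb: 2.0e-06
      - name: 2p
        capacity: 6
        occupation: 4
        binding_eV: 13.6
        sigma_ph_Mb: 1.0e-06
    core_hole:
      auger_rate_per_fs: 0.42
      fluor_rate_per_fs: 0.003
      auger_energy_eV: 500.0
impact:
  # Lotz-form electron-impact ionization model sigma(E) = a N ln(E/B)/(E B);
  # a = 4.5e-14 cm^2 eV^2 converted to bohr^2 eV^2
  lotz_a_bohr2_eV2: 1607.0
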