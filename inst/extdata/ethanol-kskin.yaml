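# Ethanol through stratum corneum: the diffusion coefficient used in the
# permeability chain (k_skin = D/L = 3.3e-7 cm/s at L = 15 um).
skin:
  D_cm2_per_s: 5.0e-10
  L_cm: 1.5e-3
  C0_mol_per_cm3: 0.0
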