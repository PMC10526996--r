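# Ethanol through dry stratum corneum: the diffusion coefficient commonly
# used for response-time estimates, with the 15 um rate-limiting layer.
skin:
  D_cm2_per_s: 3.0e-11
  L_cm: 1.5e-3
  C0_mol_per_cm3: 0.0
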