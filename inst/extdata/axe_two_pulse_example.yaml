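# Example run: pulse-independent AXE trajectories on the glycine-like preset,
# repropagated for two different broadband pump pulses. Units: eV and fs at
# the interface, atomic units internally.
model:
  preset: glycine_like
wigner:
  n_geometries: 50
  seed: 1
propagation:
  dt_fs: 0.3
  n_substeps: 51
  t_final_fs: 14.1
  energy_tolerance_eV: 0.5
decoherence:
  scheme: PFM
  omega_pfm: 4.825e-3
  eta: 1.0e-4
pulses:
  - omega_L_eV: 7.0
    delta_omega_eV: 2.83
    polarization: [0, 0, 1]
  - omega_L_eV: 7.0
    delta_omega_eV: 1.59
    polarization: [0, 0, 1]
ensemble:
  scheme: axe
  base_seed: 7
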