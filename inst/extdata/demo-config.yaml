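# Demonstration SEC-MP run configuration. Unit suffixes are part of the
# key names; every report echoes the resolved values.
extinction:
  eps_cap280_per_M_per_cm: 6.35e6
  eps_cap260_per_M_per_cm: 3.75e6
  eps_dna280_mL_per_mg_per_cm: 14.85
  eps_dna260_mL_per_mg_per_cm: 27.0
  cap_mass_kDa: 3736
geometry:
  path_length_cm: 1.0
  injection_volume_mL: 0.01
baseline:
  anchors_mL: [7.85, 9.55]
peak_window:
  v_start_mL: 8.1
  v_end_mL: 9.1
mp:
  total_window_kDa: [3000, 6000]
  half_width_kDa: 150
  sigma_max_kDa: 150
  bin_width_kDa: 25
  min_events: 50
genome:
  n_nt: 2763
  capsid_shell_kDa: 3760
# simulation-only blocks (used by `secmp simulate`)
mix: single_full
noise:
  chrom_sd_mAU: 0.05
  drift_slope_mAU_per_mL: 0.3
  mp_sd_kDa: 120
n_events: 10000
seed: 1
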