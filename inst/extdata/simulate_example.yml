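# Coverage study of the two-arm trial design under jump-to-reference
# imputation, comparing Rubin's rules with the bootstrap-then-impute
# methods.
mode: simulate
scenario:
  kind: trial
  n: 500
  arm_size: 250
  treatment_effect: 0.2
  missing_prob: 0.5
  imputation_method: jump_to_reference
methods:
  - method: rubin
    M: 10
  - method: boot_mi_percentile
    M: 10
    B: 200
  - method: boot_mi_vonhippel
    M: 2
    B: 200
n_reps: 1000
seed: 20260926
out: j2r_study
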