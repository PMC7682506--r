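# Analyse an incomplete CSV dataset with the variance-component
# (bootstrap-then-impute) interval.
mode: analyse
data: trial.csv          # CSV with NA markers
na_string: "NA"
outcome: y               # imputed column
predictors: [x]          # fully observed imputation covariates
imputation: jump_to_reference
treatment: z
analysis:
  outcome: y
  covariates: [x, z]
  target: z
method: boot_mi_vonhippel
M: 2
B: 1000
alpha: 0.05
seed: 20260926
out: report.csv
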