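{
  "_comment": "Carreau-Yasuda parameters for whole blood; standard literature values (Abraham/Boyd parameter set), shipped as a configuration default. NOT measured by, nor taken from, any study this package reproduces.",
  "mu0_pa_s": 0.16,
  "mu_inf_pa_s": 0.0035,
  "lambda_s": 8.2,
  "a": 0.64,
  "n": 0.2128
}
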