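# Example config for `mrdoctwin scenario --config <file>`.
# Fields and defaults are documented in ?validate_config.
scenario: S5
n_mz: 1000
n_dz: 1000
alpha: 0.05
rhoX: 0.90
rhoY: 0.70
master_seed: 1
out_dir: results
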