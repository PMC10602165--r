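# Example parameter file for `mrdoctwin simulate|power --params <file>`.
# Any subset of the mrdoc_params() arguments; omitted keys take defaults
# (VA = VC = 0.10, VE = 0.80 per trait, unit PGS variances, zero paths).
# This is the largest-effect Design-3 cell.
g1: 0.04
g2: 0.04
b1: 0.05
b3: 0.05
ra: 0.2
rc: 0.2
re: 0.2
rf: 0.2
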