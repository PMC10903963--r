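# Partially recessive deleterious allele with gametic selection under
# haploid expression: the mutation-selection-balance workhorse scheme.
s_AA_f: 0.0
s_Aa_f: -0.01
s_aa_f: -0.05
sigma: 0.12
d: 0.0
H: 2.0
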