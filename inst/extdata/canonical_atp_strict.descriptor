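# Canonical ATP aptamer motif strict
h1 s1 h2 s2 h2' s3 h1'
h1 0:0 NNNN:NNNN
h2 0:0 NNNN:NNNN
s1 0 GGAAGAAACTG
s2 0 N[30]N
s3 0 G
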