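origin,families,families_with_survivors,deployed,survivors
PGxIO,8,5,1031,20
IO,6,3,237,5
PG,6,2,1068,3
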