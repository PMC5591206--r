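# Example user-supplied rule file: one pattern per line, "b b b b -> b".
# A 3-pattern rule over the four input neurons.
1 0 0 0 -> 1
0 1 0 0 -> 1
1 1 0 0 -> 0
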