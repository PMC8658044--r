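graph G1
n v1 [1]
n v2 [6]
n v3 [5]
n v4 [7]
e v1 v2 -
e v2 v3 -
e v3 v4 -

graph G2
n w0 [5]
n w2 [6]
n w3 [5]
n w4 [2]
e w0 w2 -
e w2 w3 -
e w3 w4 =
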