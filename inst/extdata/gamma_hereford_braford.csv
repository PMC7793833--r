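# Reference metafounder relationship matrix (generalised least squares
# estimates) for a multibreed Hereford/Braford/Zebu tick-resistance
# evaluation; "U" is the unknown breed-of-origin group.
"",H,B,Z,U
H,0.61,0.46,0.34,0.49
B,0.46,0.53,0.57,0.50
Z,0.34,0.57,0.96,0.52
U,0.49,0.50,0.52,0.51
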