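# Reference (co)variance components and printed genetic parameters for a
# multibreed Hereford/Braford tick-resistance evaluation, per model
# (pedigree BLUP, single-step GBLUP, single-step GBLUP with metafounders;
# metafounder-model values already rescaled to the unrelated base).
model,trait,sigma_a,sigma_d,sigma_e,sigma_p_printed,h2_printed,r_printed,ra_printed
blup,H,0.003,0.018,0.060,0.081,0.040,0.260,0.670
blup,B,0.027,0.006,0.074,0.106,0.250,0.310,0.670
ssgblup,H,0.009,0.013,0.060,0.082,0.110,0.260,0.450
ssgblup,B,0.018,0.013,0.074,0.105,0.170,0.300,0.450
ssgblupm,H,0.013,0.009,0.060,0.082,0.160,0.270,0.410
ssgblupm,B,0.018,0.013,0.074,0.105,0.180,0.300,0.410
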