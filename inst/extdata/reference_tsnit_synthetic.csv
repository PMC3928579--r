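# synthetic normative peripapillary RNFL profile (TSNIT-style double hump)
theta_deg,thickness_um
0,50
15,56
30,72.5
45,95
60,117.5
75,134
90,140
105,134
120,117.5
135,95
150,72.5
165,56
180,50
195,56
210,72.5
225,95
240,117.5
255,134
270,140
285,134
300,117.5
315,95
330,72.5
345,56
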