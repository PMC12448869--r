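protein	kind	position
EPO_synthetic	N-linked	24
EPO_synthetic	N-linked	38
EPO_synthetic	N-linked	83
EPO_synthetic	O-Ser	126
GPC1_synthetic	O-Ser	40
GPC1_synthetic	O-Ser	60
GPC1_synthetic	O-Ser	130
BIKUNIN_synthetic	O-Ser	10
DAG1_synthetic	O-Thr	30
SIGLEC2_synthetic	N-linked	67
SIGLEC2_synthetic	N-linked	101
SIGLEC2_synthetic	N-linked	112
SIGLEC2_synthetic	N-linked	135
SIGLEC2_synthetic	N-linked	164
SIGLEC2_synthetic	N-linked	185
SIGLEC2_synthetic	N-linked	206
SIGLEC2_synthetic	N-linked	231
SIGLEC2_synthetic	N-linked	252
SIGLEC2_synthetic	N-linked	275
SIGLEC2_synthetic	N-linked	292
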