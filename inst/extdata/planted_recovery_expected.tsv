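metric	value
seed	20170501
n_proteins	1000
n_modules	500
rho	0.8
base_rate	0.1
n_conditions	88
n_pairs_scanned	4325
n_called	236
n_true_positive	236
recall	0.47199999999999998
precision	1
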