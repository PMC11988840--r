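label	rh	temperature	d_spacing	d_b	n_orders
D	80	60	49.4	NA	2
D	80	80	49.8	NA	2
D	95	60	50.0	39	3
D	95	70	50.0	36	3
D	95	80	47.0	NA	3
T	80	60	51.0	NA	4
T	80	70	51.5	NA	4
T	80	80	51.0	41	4
T	95	60	56.0	44	4
T	95	70	55.3	44	4
T	95	80	56.0	44	4
DT11	80	60	56.0	NA	4
DT11	80	80	56.0	NA	4
DT11	95	60	55.0	43	4
DT11	95	70	55.3	43	4
DT11	95	90	55.0	42	4
DT21	80	60	55.0	NA	4
DT21	80	80	55.0	NA	4
DT21	95	60	54.0	42	4
DT21	95	70	54.3	42	4
DT21	95	80	54.0	41	4
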