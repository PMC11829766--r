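cell_id	clone_id	parent_id	birth_hpf	division_hpf	division_mode	fate	condition	true_r	true_g	true_b	unrecombined
f0001_c001	f0001	NA	30	31	PP	P	control	0.5	0	0.5	FALSE
f0001_c002	f0001	f0001_c001	31	NA	NA	P	control	0.5	0	0.5	FALSE
f0001_c003	f0001	f0001_c001	31	NA	NA	P	control	0.5	0	0.5	FALSE
f0002_c001	f0002	NA	30	31	PP	P	control	0	0.5	0.5	FALSE
f0002_c002	f0002	f0002_c001	31	NA	NA	P	control	0	0.5	0.5	FALSE
f0002_c003	f0002	f0002_c001	31	NA	NA	P	control	0	0.5	0.5	FALSE
f0003_c001	f0003	NA	30	31	PP	P	control	0	1	0	FALSE
f0003_c002	f0003	f0003_c001	31	NA	NA	P	control	0	1	0	FALSE
f0003_c003	f0003	f0003_c001	31	NA	NA	P	control	0	1	0	FALSE
f0004_c001	f0004	NA	30	31	PP	P	control	1	0	0	FALSE
f0004_c002	f0004	f0004_c001	31	NA	NA	P	control	1	0	0	FALSE
f0004_c003	f0004	f0004_c001	31	NA	NA	P	control	1	0	0	FALSE
f0005_c001	f0005	NA	30	31	PP	P	control	0.5	0.5	0	FALSE
f0005_c002	f0005	f0005_c001	31	41	PP	P	control	0.5	0.5	0	FALSE
f0005_c003	f0005	f0005_c001	31	NA	NA	P	control	0.5	0.5	0	FALSE
f0005_c004	f0005	f0005_c002	41	NA	NA	P	control	0.5	0.5	0	FALSE
f0005_c005	f0005	f0005_c002	41	NA	NA	P	control	0.5	0.5	0	FALSE
f0006_c001	f0006	NA	30	31	PP	P	control	0	1	0	FALSE
f0006_c002	f0006	f0006_c001	31	NA	NA	P	control	0	1	0	FALSE
f0006_c003	f0006	f0006_c001	31	NA	NA	P	control	0	1	0	FALSE
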