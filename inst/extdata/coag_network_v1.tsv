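# coagsim default coagulation-network parameter table
# Units: baselines nM; kdeg 1/h; kcat 1/s; Km nM; bimolecular k 1/(nM s);
# first-order k 1/s. Reaction tags: vkor = warfarin-inhibited vitamin-K
# regeneration, xa_site = factor-Xa catalytic activity (rivaroxaban target),
# contact = contact-phase reactions active during aPTT preincubation.
version	coag-v1
# --- plasma species: id, role, baseline_nM, kdeg_per_h, vk_dep ---
species	Fg	fibrin-related	9000	0.0069	0
species	Fibrin	fibrin-related	0	0	0
species	XLFibrin	fibrin-related	0	0	0
species	II	zymogen	1400	0.0116	1
species	V	zymogen	20	0.0462	0
species	VII	zymogen	10	0.1386	1
species	VIII	zymogen	0.7	0.0578	0
species	IX	zymogen	90	0.0289	1
species	X	zymogen	170	0.0193	1
species	XI	zymogen	30	0.0116	0
species	XII	zymogen	375	0.0116	0
species	XIII	zymogen	70	0.0046	0
species	PC	zymogen	60	0.0866	1
species	PS	zymogen	300	0.0165	1
species	IIa	active	0	36	0
species	Va	active	0	0.4	0
species	VIIa	active	0	0.4	0
species	VIIIa	active	0	18	0
species	IXa	active	0	0.7	0
species	Xa	active	0	18	0
species	XIa	active	0	0	0
species	XIIa	active	0	18	0
species	XIIIa	active	0	0.7	0
species	APC	active	0	1.2	0
species	Va_i	active	0	0	0
species	VIIIa_i	active	0	0	0
species	XIa_i	active	0	0	0
species	TF	cofactor	0	0	0
species	CA	cofactor	0	0	0
species	TFVIIa	complex	0	1.8	0
species	IXaVIIIa	complex	0	3.6	0
species	XaVa	complex	0	3.6	0
species	APCPS	complex	0	3.6	0
species	VK	vitamin	100	0.1	0
species	VKO	vitamin	47.619	1.0	0
species	warfarin	drug	0	0	0
species	rivaroxaban	drug	0	0	0
# --- reactions: kind, catalyst, substrate_a, substrate_b, product, kcat_per_s, km_nM, k, tag ---
reaction	complex_formation	.	TF	VII	TFVIIa	.	.	0.002	.
reaction	mm_activation	TFVIIa	X	.	Xa	0.01	450	.	.
reaction	mm_activation	TFVIIa	IX	.	IXa	1	240	.	.
reaction	mm_activation	CA	XII	.	XIIa	0.1	600	.	contact
reaction	mm_activation	XIIa	XI	.	XIa	0.05	2000	.	contact
reaction	first_order	.	XIa	.	XIa_i	.	.	0.008	contact
reaction	mm_activation	XIa	IX	.	IXa	0.01	50	.	.
reaction	mm_activation	IXa	X	.	Xa	0.002	160	.	.
reaction	complex_formation	.	VIIIa	IXa	IXaVIIIa	.	.	0.01	.
reaction	mm_activation	IXaVIIIa	X	.	Xa	1	160	.	.
reaction	complex_formation	.	Xa	Va	XaVa	.	.	0.5	.
reaction	mm_activation	XaVa	II	.	IIa	400	300	.	xa_site
reaction	mm_activation	Xa	II	.	IIa	0.004	300	.	xa_site
reaction	mm_activation	IIa	Fg	.	Fibrin	84	7200	.	.
reaction	mm_activation	IIa	V	.	Va	2	70	.	.
reaction	mm_activation	IIa	VIII	.	VIIIa	0.9	150	.	.
reaction	mm_activation	IIa	XIII	.	XIIIa	0.1	2000	.	.
reaction	mm_activation	XIIIa	Fibrin	.	XLFibrin	0.2	4000	.	.
reaction	mm_activation	IIa	PC	.	APC	0.005	1000	.	.
reaction	complex_formation	.	APC	PS	APCPS	.	.	0.0005	.
reaction	mm_activation	APCPS	Va	.	Va_i	0.2	50	.	.
reaction	mm_activation	APCPS	VIIIa	.	VIIIa_i	0.2	50	.	.
# vitamin K cycle: oxidation sink and warfarin-inhibited regeneration (per-second ks; 10/h and 20/h)
reaction	first_order	.	VK	.	VKO	.	.	0.00277778	.
reaction	first_order	.	VKO	.	VK	.	.	0.00555556	vkor
# --- model constants ---
param	vk_normal_nM	100
param	vk_km_nM	50
param	vk_hill	2
param	warfarin_imax	1
param	warfarin_ic50_nM	650
param	rivaroxaban_ki_nM	8.5
param	aptt_xia_frac	0.148
param	aptt_xi_frac	0.339
param	fibrin_species	Fibrin
param	fibrinogen_species	Fg
# default PK (only the warfarin *1 clearance of 0.2 L/h is a reported value)
param	warfarin_cl_L_h	0.2
param	warfarin_v_L	10
param	warfarin_f	0.9
param	warfarin_ka_per_h	1
param	warfarin_mw	308.3
param	rivaroxaban_cl_L_h	6
param	rivaroxaban_v_L	50
param	rivaroxaban_f	0.8
param	rivaroxaban_ka_per_h	1
param	rivaroxaban_mw	435.9
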