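id	category	chemotype	antibiotic_name	chain_length	first_cyclization	priming_unit
SYNREF001	antibiotic	angucycline	synthetic_compound_1	22	C9-C14	hexadienoate
SYNREF002	antibiotic	angucycline	synthetic_compound_2	24	C2-C19	malonamate
SYNREF003	antibiotic	angucycline	synthetic_compound_3	28	C7-C12	malonamate
SYNREF004	antibiotic	angucycline	synthetic_compound_4	16	C7-C12	acetate
SYNREF005	antibiotic	angucycline	synthetic_compound_5	28	C5-C14	hexadienoate
SYNREF006	antibiotic	angucycline	synthetic_compound_6	30	C2-C19	hexadienoate
SYNREF007	antibiotic	angucycline	synthetic_compound_7	18	C9-C14	acetate
SYNREF008	antibiotic	angucycline	synthetic_compound_8	16	C9-C14	acetate
SYNREF009	antibiotic	angucycline	synthetic_compound_9	22	C9-C14	acetate
SYNREF010	antibiotic	anthracycline	synthetic_compound_10	16	C5-C14	propionate
SYNREF011	antibiotic	anthracycline	synthetic_compound_11	30	C9-C14	acetate
SYNREF012	antibiotic	anthracycline	synthetic_compound_12	24	C5-C14	propionate
SYNREF013	antibiotic	anthracycline	synthetic_compound_13	22	C9-C14	malonamate
SYNREF014	antibiotic	anthracycline	synthetic_compound_14	16	C7-C12	hexadienoate
SYNREF015	antibiotic	anthracycline	synthetic_compound_15	26	C5-C14	propionate
SYNREF016	antibiotic	tetracycline	synthetic_compound_16	30	C9-C14	hexadienoate
SYNREF017	antibiotic	tetracycline	synthetic_compound_17	22	C9-C14	malonamate
SYNREF018	antibiotic	tetracycline	synthetic_compound_18	30	C5-C14	hexadienoate
SYNREF019	antibiotic	tetracycline	synthetic_compound_19	18	C2-C19	acetate
SYNREF020	antibiotic	tetracycline	synthetic_compound_20	28	C9-C14	hexadienoate
SYNREF021	antibiotic	aureolic_acid	synthetic_compound_21	22	C5-C14	propionate
SYNREF022	antibiotic	aureolic_acid	synthetic_compound_22	26	C2-C19	hexadienoate
SYNREF023	antibiotic	aureolic_acid	synthetic_compound_23	26	C2-C19	propionate
SYNREF024	antibiotic	aureolic_acid	synthetic_compound_24	26	C2-C19	acetate
SYNREF025	antibiotic	aureolic_acid	synthetic_compound_25	18	C7-C12	acetate
SYNREF026	antibiotic	tetracenomycin	synthetic_compound_26	28	C9-C14	propionate
SYNREF027	antibiotic	tetracenomycin	synthetic_compound_27	28	C7-C12	malonamate
SYNREF028	antibiotic	tetracenomycin	synthetic_compound_28	22	C2-C19	propionate
SYNREF029	antibiotic	tetracenomycin	synthetic_compound_29	24	C9-C14	propionate
SYNREF030	antibiotic	isochromanequinone	synthetic_compound_30	22	C5-C14	malonamate
SYNREF031	antibiotic	isochromanequinone	synthetic_compound_31	16	C9-C14	hexadienoate
SYNREF032	antibiotic	isochromanequinone	synthetic_compound_32	18	C9-C14	hexadienoate
SYNREF033	antibiotic	isochromanequinone	synthetic_compound_33	16	C7-C12	hexadienoate
SYNREF034	antibiotic	pentangular_polyphenol	synthetic_compound_34	30	C9-C14	malonamate
SYNREF035	antibiotic	pentangular_polyphenol	synthetic_compound_35	16	C9-C14	acetate
SYNREF036	antibiotic	pentangular_polyphenol	synthetic_compound_36	18	C9-C14	propionate
SYNREF037	antibiotic	pentangular_polyphenol	synthetic_compound_37	26	C2-C19	propionate
SYNREF038	antibiotic	pradimicin	synthetic_compound_38	28	C9-C14	hexadienoate
SYNREF039	antibiotic	pradimicin	synthetic_compound_39	24	C5-C14	acetate
SYNREF040	antibiotic	pradimicin	synthetic_compound_40	24	C2-C19	propionate
SYNREF041	antibiotic	enterocin	synthetic_compound_41	24	C2-C19	malonamate
SYNREF042	antibiotic	enterocin	synthetic_compound_42	24	C2-C19	hexadienoate
SYNREF043	antibiotic	enterocin	synthetic_compound_43	20	C2-C19	propionate
SYNREF044	antibiotic	resistomycin	synthetic_compound_44	28	C9-C14	propionate
SYNREF045	antibiotic	resistomycin	synthetic_compound_45	30	C9-C14	propionate
SYNREF046	antibiotic	resistomycin	synthetic_compound_46	18	C9-C14	hexadienoate
SYNREF047	antibiotic	fredericamycin	synthetic_compound_47	22	C2-C19	malonamate
SYNREF048	antibiotic	fredericamycin	synthetic_compound_48	18	C7-C12	propionate
SYNREF049	antibiotic	fredericamycin	synthetic_compound_49	16	C9-C14	hexadienoate
SYNREF050	antibiotic	benastatin	synthetic_compound_50	26	C5-C14	propionate
SYNREF051	antibiotic	benastatin	synthetic_compound_51	26	C9-C14	malonamate
SYNREF052	antibiotic	griseorhodin	synthetic_compound_52	28	C5-C14	acetate
SYNREF053	antibiotic	griseorhodin	synthetic_compound_53	24	C2-C19	propionate
SYNREF054	antibiotic	rubromycin	synthetic_compound_54	18	C9-C14	acetate
SYNREF055	antibiotic	rubromycin	synthetic_compound_55	26	C7-C12	hexadienoate
SYNREF056	antibiotic	hedamycin	synthetic_compound_56	28	C9-C14	acetate
SYNREF057	antibiotic	hedamycin	synthetic_compound_57	30	C2-C19	acetate
SYNREF058	antibiotic	jadomycin	synthetic_compound_58	26	C2-C19	hexadienoate
SYNREF059	antibiotic	jadomycin	synthetic_compound_59	30	C2-C19	malonamate
SYNREF060	antibiotic	landomycin	synthetic_compound_60	20	C5-C14	malonamate
SYNREF061	antibiotic	oxytetracycline_like	synthetic_compound_61	16	C2-C19	acetate
SYNREF062	antibiotic	spiroketal	synthetic_compound_62	26	C9-C14	acetate
SYNREF063	antibiotic	naphthacenequinone	synthetic_compound_63	18	C5-C14	propionate
SYNREF064	spore_pigment			24	C7-C12	acetate
SYNREF065	spore_pigment			24	C7-C12	acetate
SYNREF066	spore_pigment			24	C7-C12	acetate
SYNREF067	spore_pigment			24	C7-C12	acetate
SYNREF068	spore_pigment			24	C7-C12	acetate
SYNREF069	spore_pigment			24	C7-C12	acetate
SYNREF070	spore_pigment			24	C7-C12	acetate
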