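population	parent_1	parent_2	design	n_individuals	n_polymorphic	n_mapped	n_skeleton
AxC	Avalon	Cadenza	DH	128	8498	7328	997
SxR	Savannah	Rialto	DH	64	6997	6303	626
OxS	Opata	Synthetic	RIL_F6	60	9978	8820	1509
AxP	Apogee	Paragon	SSD_F5	349	6772	2997	1537
CSxP	ChineseSpring	Paragon	RIL_F7	269	11720	9434	2472
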