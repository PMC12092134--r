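# Aggregated hindlimb actuator parameters for the helmeted guineafowl reference model.
# Single-limb values: fl = range-of-motion fibre length (mm); m1/m2/m3 = PCSA (mm^2)
# under the measured, schematic-partitioning and regression reconstructions;
# m2_pct/m3_pct = printed percentage of the m1 value (integer, half away from zero).
actuator	fl	m1	m2	m3	m2_pct	m3_pct	region
hip ext	20.854	566.144	930.188	282.115	164	50	proximal
hip ext knee ext	33.814	594.958	1003.959	116.584	169	20	proximal
hip ext knee flx	29.682	1457.053	1049.824	289.241	72	20	proximal
hip flx	8.426	1625.218	1861.331	559.835	115	34	proximal
hip flx knee ext	42.968	343.063	703.599	109.607	205	32	proximal
knee ext	15.383	1326.183	945.784	272.122	71	21	proximal
knee flx ankle ext	18.790	948.424	1401.101	362.748	148	38	distal
ankle ext	17.639	992.099	825.64	635.110	83	64	distal
ankle flx	18.304	280.401	856.851	215.809	306	77	distal
pes dfx	18.263	18.289	429.374	156.694	2348	857	distal
pes pfx	24.436	186.948	595.992	522.668	319	280	distal
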