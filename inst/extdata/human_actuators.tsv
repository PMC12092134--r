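# Aggregated hindlimb actuator parameters for the adult human reference model.
# Single-limb values: fl = range-of-motion fibre length (mm); m1/m2/m3 = PCSA (mm^2)
# under the measured, schematic-partitioning and regression reconstructions;
# m2_pct/m3_pct = printed percentage of the m1 value (integer, half away from zero).
actuator	fl	m1	m2	m3	m2_pct	m3_pct	region
hip ext	172.295	5534.583	8125.023	6195.388	147	112	proximal
hip ext knee flx	123.632	6444.721	14425.111	3052.271	224	47	proximal
hip flx	45.389	33435.136	16607.251	19982.571	50	60	proximal
hip flx knee ext	138.213	1913.731	13183.589	880.254	689	46	proximal
knee ext	129.079	13922.225	8276.688	15344.503	59	110	proximal
knee flx	108.875	1454.071	3522.453	1022.853	242	70	proximal
knee flx ankle ext	59.142	7891.753	20811.168	19720.55	264	250	distal
ankle ext	50.426	16678.017	16803.977	35014.739	101	210	distal
ankle flx	28.742	6597.919	31747.279	38448.22	481	583	distal
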