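condition	h2_aq_uM	delta_co2_to	delta_co2_tf	delta_ch4_tf	epsilon_printed
Chemostat R1	83	-35.1	-29.0	-55.9	28.5
Chemostat R2	80	-34.6	-28.2	-55.9	29.3
Chemostat R3	80	-35.2	-28.4	-55.8	29.0
Chemostat R4	18	-35.9	-33.3	-75.7	45.9
Chemostat R5	15	-35.7	-31.8	-74.2	45.8
Chemostat R6	27	-35.8	-32.0	-72.5	43.7
Bottle B1	1200	-26.1	22.6	-32.9	22.1
Bottle B2	1200	-26.1	19.2	-34.2	23.0
Bottle B3 (formate)	0	-26.7	-22.8	-99.4	85.1
Bottle B4 (formate)	0	-26.7	-23.0	-99.4	84.8
Bottle B5 (maltose)	0	-25.5	-24.4	-91.2	73.5
Bottle B6 (maltose)	0	-25.5	-21.6	-89.0	73.9
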