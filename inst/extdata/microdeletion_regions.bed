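chr4	0	4500000	Wolf-Hirschhorn syndrome associated region
chr5	9800000	33800000	Cri-du-Chat syndrome associated region
chr11	0	2800000	Beckwith-Wiedemann syndrome associated region
chr12	0	35800000	Pallister-Killian syndrome associated region
chr15	8700000	33600000	Prader Willi syndrome associated region
chr15	8700000	33600000	Angelman syndrome associated region
chr17	0	3300000	Miller-Dieker lissencephaly syndrome associated region
chr17	16000000	22200000	Smith-Magenis /dup(17)(p11.2p11.2) syndrome associated region
chr17	31800000	38100000	Renal cysts and diabetes (RCAD) associated region
chr22	14700000	17900000	Cat-eye syndrome associated region
chr22	17900000	25900000	dup(22)(q11.2q11.2) syndrome associated region
chr22	17900000	25900000	DiGeorge syndrome 1/ Velocardiofacial syndrome associated region
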