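Protein.Group	Genes	biopsy_01	biopsy_02	biopsy_03	biopsy_04	biopsy_05	biopsy_06
Q41721	GENE01	506280.9	698974.0	346795.1	837413.2	645729.3	1129461.5
Q80018	GENE02	4606166.8	1915165.0	0.0	319938.5	224001.4	804757.3
Q24673	GENE03	354644.2	1304923.5	0.0	2371197.9	368359.1	377564.8
Q47570	GENE04	1049851.5	2798193.2	1913244.5	316806.4	656075.0	1325198.6
Q57582	GENE05	3258288.1	156951.6	2479249.5	1342914.6	1482488.2	160887.8
Q39472	GENE06	371223.1	20721145.2	0.0	0.0	1769904.6	3122893.9
Q70565	GENE07	1828520.0	89352.4	1262226.7	1278273.7	2310232.6	904049.1
Q66324	GENE08	921962.2	567555.2	6164295.4	744692.1	156635.4	0.0
Q43882	GENE09	9496437.4	382923.5	576166.2	2340963.2	1800054.4	1692392.2
Q41370	GENE10	217368.9	1273983.5	504914.9	231736.1	0.0	1984799.4
Q62332	GENE11	1367200	7668851	801025	2832442	2468262	1220074
Q55696	GENE12	5012546.1	0.0	7750993.3	1704183.6	131168.9	536994.9
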