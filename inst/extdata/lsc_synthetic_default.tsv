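# provenance: synthetic: calibrate() on 5 simulated 1 Mb Markov-mixture genomes (3 components, 5 kb blocks, alpha=1), 200 pairs/bin, seed 20260912
kb	mean_intra	sd_intra	n_samples
10	0.93898624030240985	0.058938692815235012	200
20	0.95465655715914677	0.038285822517244272	200
30	0.9963143711310557	0.0023187151424458293	200
40	0.98188878459199413	0.01199181233750915	200
50	0.98899668523820272	0.007102061122998808	200
60	0.99815313218822921	0.0012175316923918589	200
70	0.99515372428532833	0.0037411246807704476	200
80	0.99520411667584485	0.0031867783191543739	200
90	0.99874846063196154	0.00080109908572970046	200
100	0.99655268520113394	0.0021510364829682911	200
110	0.99741207237357643	0.0016939981769848566	200
120	0.99907885222922921	0.00066624269569316935	200
130	0.99782059692878122	0.0013180039164732667	200
140	0.99809834490825977	0.0012034354505035614	200
150	0.99925149196923924	0.00048820521786447371	200
160	0.99858749068264929	0.00080562854323731165	200
170	0.99860754382836103	0.0008475258962182343	200
180	0.99939742556885369	0.00041019950888716579	200
190	0.99886945020996021	0.00063860963546370189	200
200	0.99890353107521634	0.00061581199601324439	200
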