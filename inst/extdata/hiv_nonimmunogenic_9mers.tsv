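peptide	ic50_nM	rank	scheme_cis25	scheme_any
WLWYIKIFI	24.1	0.5		
MLQLTVWGI	34.8	0.6		
LTFGWCFEL	43.5	0.8		
SITNWLWYI	44.9	0.8		
LLNATAIAV	50.7	0.9		Q9P273|TEN3_HUMAN.1504-1506/1405-1410
QLAEVVQKV	50.5	0.9	Q14764|MVP_HUMAN.786-790/762-765	Q9NRD9|DUOX1_HUMAN.895-900/687-689
ALQDSGLEV	56.3	1.1		Q13263|TIF1B_HUMAN.655-658/601-605
ALQDSGSEV	90.5	1.5		sp|Q8IZJ1|UNC5B_HUMAN.458-462/31-34
LLQYWSQEL	87.9	1.5		
IVGAETFYV	93.9	1.6		
QMHEDVISL	93.9	1.6		
QLQARILAV	109.4	1.8		Q9P2M7|CING_HUMAN.1138-1143/660-662
HLEGKIILV	150.6	2.3		
RMYSPISIL	162.9	2.3		Q9P225|DYH2_HUMAN.1840-1843/3935-3939
HLEGKVILV	177.4	2.5		Q8N2C7|UNC80_HUMAN.264-267/2799-2803
EMMTACQGV	210.4	2.9		
TLQEQIAWM	259.4	3.3		
FLQSRPEPT	371.6	4.1		
MTNNPPIPV	427.6	4.4		
QLTEVVQKI	424.7	4.4		
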