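# 44-probe prognostic signature annotation table.
# 30 probes carry a gene symbol as printed; go_immune = Yes marks the 14
# genes annotated to GO:0002376 (immune system process).
# The 14 probes without an associated gene symbol are not printed in the
# source table; the rows with ids "unannotated_probe_NN" below are
# SYNTHETIC placeholders standing in for them (empty gene_symbol).
probe_id	gene_symbol	gene_name	go_immune
A_23_P138635	BNIP3	BCL2/adenovirus E1B 19 kDa interacting protein 3	Yes
A_23_P55270	CCL18	chemokine (C-C motif) ligand 18 (pulmonary and activation-regulated)	Yes
A_23_P70095	CD74	CD74 molecule, major histocompatibility complex, class II invariant chain	Yes
A_24_P131589	CD86	CD86 molecule	Yes
A_24_P510357	CKAP2	cytoskeleton associated protein 2	
A_23_P125278	CXCL11	chemokine (C-X-C motif) ligand 11	Yes
A_23_P18452	CXCL9	chemokine (C-X-C motif) ligand 9	Yes
A_23_P254944	GSTT1	glutathione S-transferase theta 1	
A_23_P42306	HLA-DMA	major histocompatibility complex, class II, DM alpha	Yes
A_23_P258769	HLA-DPB1	major histocompatibility complex, class II, DP beta 1	Yes
A_24_P370472	HLA-DRB4	major histocompatibility complex, class II, DR beta 4	Yes
A_23_P31006	HLA-DRB5	major histocompatibility complex, class II, DR beta 5	Yes
A_23_P112026	IDO1	indoleamine 2,3-dioxygenase 1	Yes
A_23_P119943	IGFBP2	insulin-like growth factor binding protein 2, 36 kDa	
A_23_P158817	IGHG1	immunoglobulin heavy locus	
A_24_P92683	IGHA1	immunoglobulin heavy constant alpha 1	Yes
A_24_P204727	IGHG1	immunoglobulin heavy constant gamma 1 (G1m marker)	
A_24_P315941	IGHG1	immunoglobulin heavy constant gamma 1 (G1m marker)	
A_23_P21249	IGHG1	immunoglobulin heavy constant gamma 1 (G1m marker)	
A_24_P519504	IGL@	immunoglobulin lambda locus	
A_24_P83102	IGLL1	immunoglobulin lambda-like polypeptide 1	Yes
A_23_P76249	KRT6B	keratin 6B	
A_23_P1691	MMP1	matrix metallopeptidase 1 (interstitial collagenase)	
A_23_P169494	ORM1	orosomucoid 1	Yes
A_23_P213508	PCSK1	proprotein convertase subtilisin/kexin type 1	
A_24_P174793	PCSK1	proprotein convertase subtilisin/kexin type 1	
A_23_P149517	PIGR	polymeric immunoglobulin receptor	
A_24_P844984	PIGR	polymeric immunoglobulin receptor	
A_23_P1962	RARRES3	retinoic acid receptor responder (tazarotene induced) 3	
A_23_P81898	UBD	ubiquitin D	
unannotated_probe_01			
unannotated_probe_02			
unannotated_probe_03			
unannotated_probe_04			
unannotated_probe_05			
unannotated_probe_06			
unannotated_probe_07			
unannotated_probe_08			
unannotated_probe_09			
unannotated_probe_10			
unannotated_probe_11			
unannotated_probe_12			
unannotated_probe_13			
unannotated_probe_14			
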