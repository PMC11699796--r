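glycolysis_I	Glycolysis I (from glucose 6-phosphate); synthetic membership for the simulated gene namespace	GENE01995	GENE03513	GENE01560	GENE03642	GENE00039	GENE03624	GENE00962	GENE02157	GENE04890	GENE01918	GENE02369	GENE04858	GENE01817	GENE02789	GENE01904	GENE04224	GENE02198	GENE01530	GENE03640	GENE04969	GENE02451	GENE04261	GENE01388	GENE01105
glucose_fermentation_superpathway	Superpathway of glucose fermentation; synthetic membership	GENE04662	GENE02242	GENE01073	GENE02938	GENE00486	GENE04540	GENE04278	GENE00117	GENE02942	GENE03811	GENE04118	GENE00316	GENE04152	GENE00059	GENE02006	GENE02362	GENE02672	GENE00418	GENE02748	GENE01768	GENE02821	GENE04052	GENE03895	GENE03801	GENE03408	GENE04374	GENE01675	GENE04675	GENE04193	GENE04910
tca_aerobic_respiration	TCA cycle, aerobic respiration; synthetic membership	GENE03351	GENE00479	GENE01510	GENE01618	GENE03988	GENE00342	GENE00729	GENE01258	GENE03204	GENE00483	GENE03183	GENE01782	GENE01917	GENE02169	GENE02429	GENE04204	GENE00948	GENE04168	GENE04987	GENE02309	GENE01710	GENE03308	GENE04037	GENE04990	GENE03448	GENE00614	GENE04198	GENE01740
electron_transport_chain	Aerobic respiration, electron transport chain; synthetic membership	GENE04025	GENE04554	GENE04325	GENE00570	GENE01925	GENE00506	GENE04527	GENE01328	GENE01599	GENE01868	GENE03989	GENE01731	GENE01302	GENE04552	GENE04407	GENE02444	GENE00959	GENE03606	GENE01783	GENE02000	GENE03471	GENE02325
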