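# Pan-assay interference (PAINS) substructure alerts - representative
# fixture subset of the published A/B/C families, one alert per line:
# id <TAB> SMARTS
# The set is user-replaceable; pass any file of the same layout to
# pains_screen(alerts = read_alerts(path)).
quinone_A	O=C1C=CC(=O)C=C1
quinone_methide	C=C1C=CC(=O)C=C1
catechol_A	c1ccc(O)c(O)c1
rhodanine	O=C1CSC(=S)N1
ene_one_ene	C=CC(=O)C=C
hzone_aryl	c1ccccc1C=N[NH1]
azo_aryl	c1ccccc1N=Nc1ccccc1
thiourea_aryl	c1ccccc1NC(=S)N
imine_imine	C=NN=C
anil_alk_ene	C=Cc1ccc(N)cc1
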