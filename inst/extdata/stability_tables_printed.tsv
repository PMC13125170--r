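factor	level1	level2	tissue	pct_ndfo
bird_type	broilers	layers	ileum	30.9
bird_type	broilers	others	ileum	30.4
bird_type	layers	others	ileum	37.6
bird_type	broilers	layers	ceca	42.7
bird_type	broilers	others	ceca	44.7
bird_type	layers	others	ceca	39.7
housing	cages	floor_pens	ileum	32.7
housing	cages	mixed	ileum	41.6
housing	floor_pens	mixed	ileum	25.4
housing	cages	floor_pens	ceca	26.5
housing	cages	mixed	ceca	38.9
housing	floor_pens	mixed	ceca	32.7
continent	NorthAmerica	Europe	ileum	24.6
continent	NorthAmerica	Asia	ileum	44.8
continent	NorthAmerica	Africa	ileum	NA
continent	NorthAmerica	Hawaii	ileum	NA
continent	Europe	Asia	ileum	35.5
continent	Europe	Africa	ileum	NA
continent	Europe	Hawaii	ileum	NA
continent	Asia	Africa	ileum	NA
continent	Asia	Hawaii	ileum	NA
continent	Africa	Hawaii	ileum	NA
continent	NorthAmerica	Europe	ceca	38.7
continent	NorthAmerica	Asia	ceca	66.4
continent	NorthAmerica	Africa	ceca	77.4
continent	NorthAmerica	Hawaii	ceca	69.1
continent	Europe	Asia	ceca	55.5
continent	Europe	Africa	ceca	72.7
continent	Europe	Hawaii	ceca	81.4
continent	Asia	Africa	ceca	68.4
continent	Asia	Hawaii	ceca	79.3
continent	Africa	Hawaii	ceca	79.5
doa	0-5	5-19	ileum	NA
doa	0-5	20-49	ileum	NA
doa	0-5	50+	ileum	43.8
doa	5-19	20-49	ileum	NA
doa	5-19	50+	ileum	NA
doa	20-49	50+	ileum	NA
doa	0-5	5-19	ceca	NA
doa	0-5	20-49	ceca	50.1
doa	0-5	50+	ceca	50.7
doa	5-19	20-49	ceca	47.4
doa	5-19	50+	ceca	NA
doa	20-49	50+	ceca	NA
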