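slotu_id	reference_distance
Streptococcus anginosus	10.0
Oceanobacillus sp.	11.6
Corynebacterium tuberculostearicum	13.2
Clostridium paraputrificum	14.8
Burkholderiales ND	16.4
Clostridium favososporum	18.0
Streptococcus thermophilus	19.6
Bacillus cereus group	21.2
Clostridium tertium	22.8
Rothia mucilaginosa	24.4
Staphylococcus haemolyticus	26.0
Veillonella parvula	27.6
Clostridium butyricum	29.2
Enterococcus durans group	30.8
Staphylococcus sp.	32.4
Propionibacterium sp.	34.0
Clostridium disporicum group	35.6
Staphylococcus warneri	37.2
Streptococcus sanguinis group	38.8
Pseudomonas sp.	40.4
Clostridium symbosium group	42.0
Streptococcus parasanguinis group	43.6
Aquabacterium commune	45.2
Veillonella sp.	46.8
Staphylococcus cohnii	48.4
Escherichia coli	50.0
Veillonella dispar	51.6
Enterobacter cloacae	53.2
Streptococcus oralis group	54.8
Bifidobacterium breve	56.4
Staphylococcus epidermidis group	58.0
Staphylococcus hominis	59.6
Enterococcus faecalis	61.2
Clostridium innocuum	62.8
Aquabacterium citratiphilum	64.4
Clostridium glycolicum	66.0
Sarcina ventriculi	67.6
Clostridium corinoforum	69.2
Clostridium sp.	70.8
Streptococcus salivarius	72.4
Klebsiella pneumoniae	74.0
Klebsiella oxytoca	75.6
Propionibacterium acnes	77.2
Sneathia sanguinegens	78.8
Streptococcus oralis/parasanguinis	80.4
Clostridium difficile	82.0
Anaerococcus octavius	83.6
Clostridium perfringens	85.2
Clostridium neonatale	86.8
Bifidobacterium longum	88.4
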