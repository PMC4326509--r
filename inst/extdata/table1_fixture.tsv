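slotu_id	glotu_id	is_slotu	n_samples	pct_samples_printed	n_infants	pct_infants_printed	first_day	last_day	score1_n	score2_n	score3_n	remarks
Staphylococcus epidermidis group	Staphylococcus	TRUE	268	75.7	30	100	3	53	45	67	156
Staphylococcus haemolyticus	Staphylococcus	TRUE	185	52.3	26	86.7	4	51	34	69	82
Staphylococcus warneri	Staphylococcus	TRUE	45	12.7	16	53.3	3	33	10	16	19
Staphylococcus hominis	Staphylococcus	TRUE	13	13.7	6	20	7	45	4	4	5	printed sample percentage 13.7 inconsistent with 13/354 = 3.7 (apparent typo)
Staphylococcus sp.	Staphylococcus	TRUE	6	1.7	3	10	3	25	2	3	1
Staphylococcus cohnii	Staphylococcus	TRUE	4	1.1	1	3.3	27	33	4	0	0
Not determined	ND	FALSE	93	26.3	24	80	3	56	60	16	17	bands off-ladder and too faint to sequence; 37 distinct migration distances
Enterococcus faecalis	Enterococcus	TRUE	98	27.7	18	60	3	56	13	19	66
Enterococcus durans group	Enterococcus	TRUE	7	2	2	6.7	31	53	1	2	4
Clostridium butyricum	Clostridium/Clostridiaceae	TRUE	40	11.3	12	40	18	53	8	11	21
Clostridium difficile	Clostridium/Clostridiaceae	TRUE	34	9.6	11	36.7	24	56	14	17	3
Clostridium neonatale	Clostridium/Clostridiaceae	TRUE	29	8.2	10	33.3	16	53	12	12	5
Clostridium perfringens	Clostridium/Clostridiaceae	TRUE	23	6.5	9	30	17	50	8	4	11
Clostridium sp.	Clostridium/Clostridiaceae	TRUE	9	2.5	4	13.3	27	42	6	1	2
Clostridium paraputrificum	Clostridium/Clostridiaceae	TRUE	5	1.4	3	10	15	18	2	2	1
Clostridium tertium	Clostridium/Clostridiaceae	TRUE	9	2.5	3	10	22	49	3	3	3
Clostridium disporicum group	Clostridium/Clostridiaceae	TRUE	5	1.4	2	6.7	15	24	2	2	1
Clostridium corinoforum	Clostridium/Clostridiaceae	TRUE	1	0.3	1	3.3	34	34	1	0	0
Clostridium glycolicum	Clostridium/Clostridiaceae	TRUE	1	0.3	1	3.3	50	50	1	0	0
Clostridium favososporum	Clostridium/Clostridiaceae	TRUE	5	1.4	1	3.3	31	50	3	1	1
Clostridium symbosium group	Clostridium/Clostridiaceae	TRUE	2	0.6	1	3.3	21	27	0	1	1
Sarcina ventriculi	Sarcina/Clostridiaceae	TRUE	1	0.3	1	3.3	17	17	0	0	1
Escherichia coli	Enterobacteriaceae	TRUE	22	6.2	8	26.7	6	56	11	0	11
Klebsiella oxytoca	Enterobacteriaceae	TRUE	13	3.7	4	13.3	12	56	4	1	8
Klebsiella pneumoniae	Enterobacteriaceae	TRUE	3	0.8	2	6.7	39	49	0	0	3
Enterobacter cloacae	Enterobacteriaceae	TRUE	5	1.4	1	3.3	38	56	1	0	4
Veillonella dispar	Veillonella	TRUE	31	8.8	6	20	4	56	20	3	8
Veillonella parvula	Veillonella	TRUE	9	2.5	3	10	28	45	1	5	3
Veillonella sp.	Veillonella	TRUE	7	2	2	6.7	19	42	2	2	3
Rothia mucilaginosa	Rothia	TRUE	10	2.8	4	13.3	37	52	3	3	4
Aquabacterium commune	Aquabacterium/Burkholderiales	TRUE	7	2	4	13.3	3	41	5	2	0
Aquabacterium citratiphilum	Aquabacterium/Burkholderiales	TRUE	2	0.6	1	3.3	28	30	1	1	0
Burkholderiales ND	Burkholderiales	TRUE	7	2	1	3.3	16	33	5	1	1
Streptococcus oralis group	Streptococcus	TRUE	4	1.1	3	10	24	50	2	1	1
Streptococcus salivarius	Streptococcus	TRUE	10	2.8	2	6.7	31	56	5	5	0
Streptococcus anginosus	Streptococcus	TRUE	1	0.3	1	3.3	30	30	0	1	0
Streptococcus oralis/parasanguinis	Streptococcus	TRUE	1	0.3	1	3.3	49	49	1	0	0
Streptococcus parasanguinis group	Streptococcus	TRUE	1	0.3	1	3.3	42	42	0	1	0
Streptococcus sanguinis group	Streptococcus	TRUE	1	0.3	1	3.3	28	28	1	0	0
Streptococcus thermophilus	Streptococcus	TRUE	5	1.4	1	3.3	16	28	2	1	2
Bacillus cereus group	Bacillus/Bacillaceae	TRUE	4	1.1	4	13.3	9	56	3	0	1
Oceanobacillus sp.	Oceanobacillus/Bacillaceae	TRUE	3	0.8	1	3.3	18	24	3	0	0
Bifidobacterium breve	Bifidobacterium	TRUE	9	2.5	2	6.7	3	49	3	6	0
Bifidobacterium longum	Bifidobacterium	TRUE	5	1.4	2	6.7	22	50	3	2	0
Clostridium innocuum	Erysipelotrichaceae	TRUE	9	2.5	1	3.3	10	36	3	6	0	family Erysipelotrichaceae despite Clostridium genus name
Propionibacterium sp.	Propionibacterium	TRUE	3	0.8	1	3.3	18	24	1	0	2
Propionibacterium acnes	Propionibacterium	TRUE	2	0.6	1	3.3	43	45	0	2	0
Sneathia sanguinegens	Sneathia	TRUE	2	0.6	1	3.3	3	4	1	0	1
Pseudomonas sp.	Pseudomonas	TRUE	1	0.3	1	3.3	37	37	0	1	0
Anaerococcus octavius	Anaerococcus	TRUE	2	0.6	1	3.3	32	37	0	2	0
Corynebacterium tuberculostearicum	Corynebacterium	TRUE	2	0.6	1	3.3	14	15	0	2	0
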