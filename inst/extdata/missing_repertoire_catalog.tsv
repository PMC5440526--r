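species	obligate_anaerobe	phylum	class	order	family	genus	novelty	probiotic	probiotic_function
Acinetobacter lwoffii	0	Proteobacteria	Gammaproteobacteria	Pseudomonadales	Moraxellaceae	Acinetobacter	known_gut	0
Alistipes indistinctus	1	Bacteroidetes	Bacteroidia	Bacteroidales	Rikenellaceae	Alistipes	known_gut	1	Common member of the gut microbiota of healthy humans
Alistipes putredinis	1	Bacteroidetes	Bacteroidia	Bacteroidales	Rikenellaceae	Alistipes	known_gut	0
Alistipes senegalensis	1	Bacteroidetes	Bacteroidia	Bacteroidales	Rikenellaceae	Alistipes	known_gut	0
Alloscardovia omnicolens	0	Actinobacteria	Actinobacteria	Bifidobacteriales	Bifidobacteriaceae	Alloscardovia	known_gut	0
Anaerostipes caccae	1	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae	Anaerostipes	known_gut	1	Common member of the gut microbiota of healthy humans
Arthrobacter agilis	0	Actinobacteria	Actinobacteria	Micrococcales	Micrococcaceae	Arthrobacter	known_gut	0
Asaccharospora irregularis	1	Firmicutes	Clostridia	Clostridiales	Peptostreptococcaceae	Asaccharospora	known_gut	0
Bacillus cereus	0	Firmicutes	Bacilli	Bacillales	Bacillaceae	Bacillus	known_gut	0
Bacillus firmus	0	Firmicutes	Bacilli	Bacillales	Bacillaceae	Bacillus	known_gut	0
Bacillus idriensis	0	Firmicutes	Bacilli	Bacillales	Bacillaceae	Bacillus	known_gut	0
Bacillus licheniformis	0	Firmicutes	Bacilli	Bacillales	Bacillaceae	Bacillus	known_gut	1	Antibacterial potential
Bacillus niabensis	0	Firmicutes	Bacilli	Bacillales	Bacillaceae	Bacillus	known_gut	0
Bacillus subtilis	0	Firmicutes	Bacilli	Bacillales	Bacillaceae	Bacillus	known_gut	1	Antibacterial potential
Bacillus thermoamylovorans	0	Firmicutes	Bacilli	Bacillales	Bacillaceae	Bacillus	known_gut	0
Bacteroides salyersiae	1	Bacteroidetes	Bacteroidia	Bacteroidales	Bacteroidaceae	Bacteroides	known_gut	1	Mutualistic association with Terrisporobacter glycolicus for polysaccharides fermentation
Bifidobacterium adolescentis	1	Actinobacteria	Actinobacteria	Bifidobacteriales	Bifidobacteriaceae	Bifidobacterium	known_gut	1	Common member of the gut microbiota in healthy breastfed infants
Clostridium amygdalinum	1	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae	Lachnoclostridium	known_gut	0
Clostridium cadaveris	1	Firmicutes	Clostridia	Clostridiales	Clostridiaceae	Clostridium	known_gut	0
Clostridium glycolicum	1	Firmicutes	Clostridia	Clostridiales	Peptostreptococcaceae	Terrisporobacter	known_gut	1	Mutualistic association with acetogenic Bacteroides for polysaccharides fermentation
Clostridium hylemonae	1	Firmicutes	Clostridia	Clostridiales	Clostridiaceae	Clostridium	known_gut	0
Clostridium neonatale	1	Firmicutes	Clostridia	Clostridiales	Clostridiaceae	Clostridium	known_gut	0
Clostridium oroticum	1	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae	Lachnoclostridium	known_gut	0
Clostridium paraputrificum	1	Firmicutes	Clostridia	Clostridiales	Clostridiaceae	Clostridium	known_gut	0
Clostridium saccharolyticum	1	Firmicutes	Clostridia	Clostridiales	Clostridiaceae	Clostridium	known_gut	0
Clostridium sordellii	1	Firmicutes	Clostridia	Clostridiales	Peptostreptococcaceae	Peptoclostridium	known_gut	0
Dialister pneumosintes	1	Firmicutes	Negativicutes	Selenomonadales	Veillonellaceae	Dialister	known_gut	0
Enterococcus dispar	0	Firmicutes	Bacilli	Lactobacillales	Enterococcaceae	Enterococcus	known_gut	0
Faecalitalea cylindroides	1	Firmicutes	Erysipelotrichia	Erysipelotrichales	Erysipelotrichaceae	Faecalitalea	known_gut	0
Gemella sanguinis	0	Firmicutes	Bacilli	Bacillales	Bacillales Family XI Incertae Sedis	Gemella	known_gut	0
Intestinimonas butyriciproducens	1	Firmicutes	Clostridia	Clostridiales	Unclassified clostridiales	Intestinimonas	known_gut	1	Butyrate production
Lactobacillus parabuchneri	0	Firmicutes	Bacilli	Lactobacillales	Lactobacillaceae	Lactobacillus	known_gut	1	Common member of the gut microbiota of healthy breastfed infants
Lactobacillus perolens	0	Firmicutes	Bacilli	Lactobacillales	Lactobacillaceae	Lactobacillus	known_gut	1	Common member of the gut microbiota of healthy breastfed infants
Lactobacillus vaccinostercus	0	Firmicutes	Bacilli	Lactobacillales	Lactobacillaceae	Lactobacillus	known_gut	1	Common member of the gut microbiota of healthy breastfed infants
Micrococcus lylae	0	Actinobacteria	Actinobacteria	Micrococcales	Micrococcaceae	Micrococcus	known_gut	0
Neisseria flavescens	0	Proteobacteria	Betaproteobacteria	Neisseriales	Neisseriaceae	Neisseria	known_gut	0
Pantoea septica	0	Proteobacteria	Gammaproteobacteria	Enterobacteriales	Enterobacteriaceae	Pantoea	known_gut	0
Paraclostridium bifermentans	1	Firmicutes	Clostridia	Clostridiales	Peptostreptococcaceae	Paraclostridium	known_gut	0
Slackia exigua	1	Actinobacteria	Coriobacteriia	Eggerthellales	Eggerthellaceae	Slackia	known_gut	0
Staphylococcus haemolyticus	0	Firmicutes	Bacilli	Bacillales	Staphylococcaceae	Staphylococcus	known_gut	0
Staphylococcus hominis	0	Firmicutes	Bacilli	Bacillales	Staphylococcaceae	Staphylococcus	known_gut	0
Streptococcus vestibularis	0	Firmicutes	Bacilli	Lactobacillales	Streptococcaceae	Streptococcus	known_gut	0
Sutterella wadsworthensis	1	Proteobacteria	Betaproteobacteria	Burkholderiales	Sutterellaceae	Sutterella	known_gut	0
Veillonella dispar	1	Firmicutes	Negativicutes	Selenomonadales	Veillonellaceae	Veillonella	known_gut	0
Weissella confusa	0	Firmicutes	Bacilli	Lactobacillales	Leuconostocaceae	Wesseila	known_gut	1	Antioxidant metabolism
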