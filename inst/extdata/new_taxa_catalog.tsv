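species	family	obligate_anaerobe	origin	novelty
Africanella massiliensis	Ruminococcaceae	1	control	new_genus
Bacillus massilionigeriensis	Bacillaceae	0	control	new_species
Bacillus mediterraneensis	Bacillaceae	0	control	new_species
Bacillus phoceensis	Bacillaceae	0	control	new_species
Bacillus testis	Bacillaceae	0	control	new_species
Bacillus touaregensis	Bacillaceae	0	control	new_species
Brachybacterium massiliense	Dermabacteraceae	0	control	new_species
Brevibacterium phoceense	Brevibacteriaceae	0	control	new_species
Clostridium massiliodielmoense	Clostridiaceae	1	control	new_species
Clostridium nigeriense	Clostridiaceae	1	control	new_species
Enterobacter timonensis	Enterobacteriaceae	0	control	new_species
Khelaifiabacterium massiliensis	Clostridiaceae	1	control	new_genus
Lachnoclostridium massiliosenegalense	Lachnospiraceae	1	control	new_species
Lachnoclostridium touaregense	Lachnospiraceae	1	control	new_species
Lagierella massiliensis	Peptoniphilaceae	1	control	new_genus
Lascolabacillus massiliensis	Porphyromonadaceae	1	control	new_genus
Massiliobacillus massiliensis	Sporomusaceae	1	control	new_genus
Murdochiella massiliensis	Peptoniphilaceae	1	control	new_species
Ndiopella massiliensis	Peptoniphilaceae	1	control	new_genus
Neofamilia massiliensis	Neofamiliaceae	1	control	new_family
Niameyia massiliensis	Lachnospiraceae	1	control	new_genus
Paenibacillus phoceensis	Paenibacillaceae	0	control	new_species
Paenibacillus senegalomassiliensis	Paenibacillaceae	0	control	new_species
Paenibacillus touaregensis	Paenibacillaceae	0	control	new_species
Peptoniphilus phoceensis	Peptoniphilaceae	1	control	new_species
Senegalia massiliensis	Clostridiaceae	1	control	new_genus
Anaerococcus rubiinfantis	Peptoniphilaceae	1	case	new_species
Anaeromassilibacillus senegalensis	Ruminococcaceae	1	case	new_genus
Anaerotruncus rubiinfantis	Ruminococcaceae	1	case	new_species
Bacillus andreraoultii	Bacillaceae	0	case	new_species
Bacillus niameyensis	Bacillaceae	0	case	new_species
Bacillus rubiinfantis	Bacillaceae	0	case	new_species
Desnuesiella massiliensis	Clostridiaceae	0	case	new_genus
Flaviflexus massiliensis	Actinomycetaceae	0	case	new_species
Inediibacterium massiliense	Clostridiaceae	1	case	new_genus
Massilibacterium senegalense	Bacillaceae	0	case	new_genus
Mediannikovella massiliensis	Clostridiaceae	1	case	new_genus
Mobilicoccus massiliensis	Dermatophilaceae	0	case	new_species
Nigerium massiliensis	Propionibacteriaceae	1	case	new_genus
Olsenella massiliensis	Atopobiaceae	1	case	new_species
Paenibacillus rubiinfantis	Paenibacillaceae	0	case	new_species
Rubeoparvulum massiliense	Bacillaceae	1	case	new_genus
Rubiinfantum massiliense	Bacillaceae	0	case	new_genus
Tessaracoccus massiliensis	Propionibacteriaceae	0	case	new_species
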