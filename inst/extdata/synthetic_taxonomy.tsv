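asv_id	kingdom	phylum	class	order	family	genus	species_hint
ASV01	Bacteria	Firmicutes	Bacilli	Lactobacillales	Lactobacillaceae	Lactobacillus	L. iners
ASV02	Bacteria	Firmicutes	Bacilli	Lactobacillales	Lactobacillaceae	Lactobacillus	L. crispatus/acidophilus/gallinarum
ASV03	Bacteria	Actinobacteria	Actinobacteria	Bifidobacteriales	Bifidobacteriaceae	Gardnerella	G. vaginalis
ASV04	Bacteria	Actinobacteria	Coriobacteriia	Coriobacteriales	Coriobacteriaceae	Atopobium	A. vaginae
ASV05	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Prevotellaceae	Prevotella	P. bivia
ASV06	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Prevotellaceae	Prevotella	P. timonensis
ASV07	Bacteria	Fusobacteria	Fusobacteriia	Fusobacteriales	Leptotrichiaceae	Sneathia	
ASV08	Bacteria	Firmicutes	Negativicutes	Selenomonadales	Veillonellaceae	Megasphaera	
ASV09	Bacteria	Firmicutes	Negativicutes	Selenomonadales	Veillonellaceae	Dialister	D. propionicifaciens
ASV10	Bacteria	Firmicutes	Bacilli	Lactobacillales	Streptococcaceae	Streptococcus	S. agalactiae
ASV11	Bacteria	Firmicutes	Clostridia	Clostridiales	Peptoniphilaceae	Anaerococcus	
ASV12	Bacteria	Firmicutes	Negativicutes	Selenomonadales	Veillonellaceae	Veillonella	
ASV13	Bacteria	Fusobacteria	Fusobacteriia	Fusobacteriales	Leptotrichiaceae	Streptobacillus	
ASV14	Bacteria	Proteobacteria	Gammaproteobacteria	Enterobacteriales	Enterobacteriaceae	Escherichia_Shigella	
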