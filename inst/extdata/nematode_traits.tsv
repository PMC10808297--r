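# Soil nematode genus-level reference traits.
# trophic_group: BF bacterivore, FF fungivore, PP plant-parasite, OP omnivore-predator.
# cp_class: Bongers colonizer-persister score (1-5).
# fresh_weight: mean individual fresh body mass, micrograms; implementer-compiled
#   reference values in the style of the Nemaplex expert-system tables.
# op_subtype: Om omnivore / Ca carnivore (guild letter for OP genera); NA otherwise.
genus	trophic_group	cp_class	fresh_weight	op_subtype
Acrobeles	BF	2	0.52	NA
Acrobeloides	BF	2	0.29	NA
Alaimus	BF	4	0.29	NA
Cephalobus	BF	2	0.49	NA
Eucephalobus	BF	2	0.44	NA
Mesorhabditis	BF	1	0.36	NA
Panagrolaimus	BF	1	0.68	NA
Plectus	BF	2	0.68	NA
Prismatolaimus	BF	3	0.47	NA
Protorhabditis	BF	1	0.23	NA
Rhabditis	BF	1	2.50	NA
Isolaimium	BF	4	1.10	NA
Wilsonema	BF	2	0.12	NA
Aphelenchus	FF	2	0.33	NA
Aphelenchoides	FF	2	0.15	NA
Ditylenchus	FF	2	0.22	NA
Filenchus	FF	2	0.12	NA
Miculenchus	FF	2	0.10	NA
Tylencholaimus	FF	4	0.26	NA
Aporcelaimellus	OP	5	10.50	Om
Eudorylaimus	OP	4	1.60	Om
Mesodorylaimus	OP	4	0.85	Om
Thonus	OP	4	0.90	Om
Discolaimus	OP	5	3.00	Ca
Mylonchulus	OP	4	1.20	Ca
Helicotylenchus	PP	3	0.40	NA
Pratylenchus	PP	3	0.12	NA
Tylenchorhynchus	PP	3	0.35	NA
Paratylenchus	PP	2	0.04	NA
Longidorus	PP	5	6.50	NA
Hoplotylus	PP	3	0.30	NA
Heterodera	PP	3	0.26	NA
Meloidogyne	PP	3	0.10	NA
Boleodorus	PP	2	0.09	NA
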