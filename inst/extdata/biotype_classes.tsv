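biotype	class	subclass
protein_coding	protein_coding	protein_coding
IG_C_gene	protein_coding	protein_coding
IG_D_gene	protein_coding	protein_coding
IG_J_gene	protein_coding	protein_coding
IG_LV_gene	protein_coding	protein_coding
IG_V_gene	protein_coding	protein_coding
TR_C_gene	protein_coding	protein_coding
TR_D_gene	protein_coding	protein_coding
TR_J_gene	protein_coding	protein_coding
TR_V_gene	protein_coding	protein_coding
pseudogene	pseudogene	pseudogene
processed_pseudogene	pseudogene	pseudogene
unprocessed_pseudogene	pseudogene	pseudogene
transcribed_processed_pseudogene	pseudogene	pseudogene
transcribed_unprocessed_pseudogene	pseudogene	pseudogene
transcribed_unitary_pseudogene	pseudogene	pseudogene
translated_processed_pseudogene	pseudogene	pseudogene
translated_unprocessed_pseudogene	pseudogene	pseudogene
unitary_pseudogene	pseudogene	pseudogene
polymorphic_pseudogene	pseudogene	pseudogene
IG_C_pseudogene	pseudogene	pseudogene
IG_D_pseudogene	pseudogene	pseudogene
IG_J_pseudogene	pseudogene	pseudogene
IG_V_pseudogene	pseudogene	pseudogene
TR_J_pseudogene	pseudogene	pseudogene
TR_V_pseudogene	pseudogene	pseudogene
snoRNA	short_ncRNA	snoRNA
snRNA	short_ncRNA	snRNA
miRNA	short_ncRNA	miRNA
rRNA	short_ncRNA	rRNA
Mt_rRNA	short_ncRNA	rRNA
misc_RNA	short_ncRNA	miscRNA
Mt_tRNA	short_ncRNA	miscRNA
scaRNA	short_ncRNA	miscRNA
sRNA	short_ncRNA	miscRNA
ribozyme	short_ncRNA	miscRNA
scRNA	short_ncRNA	miscRNA
lincRNA	lncRNA	lincRNA
antisense	lncRNA	antisense
sense_intronic	lncRNA	sense_intronic
sense_overlapping	lncRNA	sense_overlapping
3prime_overlapping_ncRNA	lncRNA	sense_overlapping
bidirectional_promoter_lncRNA	lncRNA	lincRNA
macro_lncRNA	lncRNA	lincRNA
processed_transcript	processed_transcript	processed_transcript
TEC	other	other
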