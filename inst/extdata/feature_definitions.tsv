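name	modality	source	direction_note
age	clinical	clinical table	importance-dominant demographic
tumour_size	clinical	clinical table	larger tumours respond less
grade	clinical	clinical table	higher grade toward pCR
er_positive	clinical	clinical table	ER- toward pCR
her2_positive	clinical	clinical table	anti-HER2 treated stratum
ln_positive	clinical	clinical table	node involvement toward residual disease
tmb	DNA	compute_tmb	higher burden toward pCR
pct_subclonal	DNA	pct_subclonal	subclonality toward residual disease
n_neoantigens	DNA	filter_neoantigens	higher load toward pCR
hrd_score	DNA	compute_hrd	HRD toward pCR
cna_fraction	DNA	genome_altered_fraction	instability toward pCR
mut_TP53	DNA	driver_flags	TP53 toward pCR
mut_PIK3CA	DNA	driver_flags	PIK3CA toward residual disease
hla_loh	DNA	call_hla_loh	immune escape toward residual disease
sig_hrd_exposure	DNA	normalize_exposures	HRD signature toward pCR
sig_apobec_exposure	DNA	normalize_exposures	APOBEC signature toward pCR
ggi_score	RNA	ssgsea_score	proliferation toward pCR
escell_score	RNA	ssgsea_score	dedifferentiation toward pCR
stat1_score	RNA	ssgsea_score	immune activation toward pCR
cytolytic_score	RNA	metagene_score	cytotoxic activity toward pCR
taxane_metagene	RNA	metagene_score	mitotic minus ceramide metagene
danaher_cd8	RNA	metagene_score	CD8 T cell enrichment toward pCR
danaher_mast	RNA	metagene_score	mast cells toward residual disease
tcell_dysfunction	RNA	tide input	dysfunction toward residual disease
tcell_exclusion	RNA	tide input	exclusion toward residual disease
expr_ESR1	RNA	log2 TPM	ER axis
expr_PGR	RNA	log2 TPM	ER axis
expr_ERBB2	RNA	log2 TPM	HER2 axis
lymphocyte_density	DigPath	knn_density	infiltration toward pCR
lymphocyte_fraction	DigPath	cell_fractions	infiltration toward pCR
received_anthracycline	treatment	clinical table	one-hot regimen flag
received_anti_her2	treatment	clinical table	one-hot regimen flag
taxane_first	treatment	clinical table	sequence flag
anthracycline_first	treatment	clinical table	sequence flag
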