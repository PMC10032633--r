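# Default gene-specific configuration (tab-delimited: gene, parameter, value).
# GENERAL is inherited by every gene without its own rows.
#
# NOTE: the allele-frequency thresholds (ba1_af, bs1_af, pm2_af) shipped here
# are documented SYNTHETIC defaults chosen for testing; published gene-specific
# guideline values should be substituted in deployments via an override file.
# The SpliceAI cut-offs (pp3_splice_min 0.5, bp4_splice_max 0.15) are the
# calibrated defaults; REVEL cut-offs are configurable placeholders.
gene	parameter	value
GENERAL	ba1_af	0.005
GENERAL	bs1_af	0.001
GENERAL	pm2_af	0.00002
GENERAL	pm2_strength	moderate
GENERAL	use_ci_lower	TRUE
GENERAL	ci_confidence	0.95
GENERAL	exclude_founder	TRUE
GENERAL	pp3_protein_min	0.70
GENERAL	bp4_protein_max	0.25
GENERAL	pp3_splice_min	0.5
GENERAL	bp4_splice_max	0.15
GENERAL	bp7_requires_nonconserved	TRUE
GENERAL	conservation_max_phastcons	1.0
GENERAL	pvs1_mode	general_tree
GENERAL	pvs1_override_boundary	NA
GENERAL	protein_loss_fraction	0.10
GENERAL	ps1_enabled	TRUE
GENERAL	pm5_mode	classic_codon
GENERAL	bs2_mode	flossies_or_homozygote
GENERAL	bs2_flossies_min	2
GENERAL	bs2_homozygote_min	1
GENERAL	bp2_mode	off
GENERAL	mmr_splice_combination	FALSE
GENERAL	mmr_prior_min	0.5
GENERAL	pm1_applicable	TRUE
GENERAL	pp2_enabled	FALSE
GENERAL	ps3_bs3_covered	TRUE
GENERAL	bs3_covered	TRUE
GENERAL	expert_panel_only	TRUE
# ATM: BS2 does not apply; PM1 does not apply
ATM	bs2_mode	off
ATM	pm1_applicable	FALSE
# CHEK2: BS2 does not apply
CHEK2	bs2_mode	off
# CDH1: PM2 downgraded to supporting (guideline v3); site-specific PVS1 splice
# table; PS1 retired and PM5 redefined for truncating/NMD variants; BS2 not
# automated; BP2 partially automated (homozygote, supporting only); BP7 no
# longer requires non-conservation; PM1 does not apply; no curated PS3/BS3.
CDH1	pm2_strength	supporting
CDH1	pvs1_mode	cdh1_site_specific
CDH1	ps1_enabled	FALSE
CDH1	pm5_mode	cdh1_truncating
CDH1	bs2_mode	not_automated
CDH1	bp2_mode	homozygote_supporting
CDH1	bp7_requires_nonconserved	FALSE
CDH1	pm1_applicable	FALSE
CDH1	ps3_bs3_covered	FALSE
# Mismatch-repair genes: splice prediction combines SpliceAI with the
# MMR-specific prior; BS2 not automated; BP2 not applicable; PM1 not applicable
MLH1	mmr_splice_combination	TRUE
MLH1	bs2_mode	not_automated
MLH1	bp2_mode	not_applicable
MLH1	pm1_applicable	FALSE
MSH2	mmr_splice_combination	TRUE
MSH2	bs2_mode	not_automated
MSH2	bp2_mode	not_applicable
MSH2	pm1_applicable	FALSE
MSH6	mmr_splice_combination	TRUE
MSH6	bs2_mode	not_automated
MSH6	bp2_mode	not_applicable
MSH6	pm1_applicable	FALSE
PMS2	mmr_splice_combination	TRUE
PMS2	bs2_mode	not_automated
PMS2	bp2_mode	not_applicable
PMS2	pm1_applicable	FALSE
PMS2	ps3_bs3_covered	FALSE
# PTEN: truncating variants 5' of c.1121 forced very strong; PP2 applies;
# no curated BS3 assays
PTEN	pvs1_mode	pten_override
PTEN	pvs1_override_boundary	1121
PTEN	pp2_enabled	TRUE
PTEN	bs3_covered	FALSE
# TP53: general profile; PS1/PM5 restricted to expert-panel entries (default)
TP53	expert_panel_only	TRUE
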