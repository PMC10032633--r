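# Curated functional-assay table (tab-delimited), curator-extensible.
# The records shipped here are SYNTHETIC example entries used by the test
# fixtures; deployments should replace them with the calibrated assays
# listed in the applicable gene-specific guidelines.
gene	variant_key	source_id	result	strength	guideline_listed
TP53	c.524G>A	SYNTH-TP53-ASSAY-1	abnormal	strong	TRUE
TP53	c.215C>G	SYNTH-TP53-ASSAY-1	normal	strong	TRUE
ATM	c.301C>T	SYNTH-ATM-ASSAY-1	abnormal	strong	FALSE
ATM	c.404T>C	SYNTH-ATM-ASSAY-2	intermediate	strong	FALSE
MLH1	c.350C>T	SYNTH-MMR-ASSAY-1	abnormal	strong	TRUE
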