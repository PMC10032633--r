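# Criterion pairs that must not be combined (same underlying evidence).
code_a	code_b	rationale
PVS1	PP3	splice/protein prediction already underlies the loss-of-function call
PVS1	PM1	loss-of-function call already covers the functional-domain evidence
PM1	PP3	PM1 is restricted to missense/in-frame variants whose prediction PP3 re-counts
PVS1	PM4	protein-length change is part of the loss-of-function mechanism
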