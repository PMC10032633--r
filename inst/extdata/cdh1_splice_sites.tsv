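# CDH1 site-specific canonical-splice PVS1 strengths (guideline v3.1 splicing
# table entries used by the engine; curator-extensible).
# site = cDNA position with intronic offset, without the "c." prefix.
site	strength
1137+1	strong
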