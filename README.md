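# hcvarclass

Deterministic ACMG/AMP variant classification for hereditary-cancer genes,
as an R package. `hcvarclass` evaluates the coded evidence criteria
(PVS1, PS1–PS4, PM1–PM6, PP1–PP4; BA1, BS1–BS4, BP1–BP7) from locally
supplied *evidence bundles*, applies gene-specific rule variants for ATM,
CDH1, CHEK2, MLH1, MSH2, MSH6, PMS2, PTEN and TP53 (and a general ruleset
for every other gene), removes overlapping-evidence double counting, and
classifies with the naturally scaled point system.

It is written for variant-curation teams and pipeline authors who need
reproducible, explainable criterion calls: every criterion comes back with
a state (`assigned` / `denied` / `not_automated` / `not_applicable` /
`warning`), a strength, its points and a human-readable explanation, and
the full result can be exported as a TSV or spreadsheet report.

## The model

Each assigned pathogenic criterion at supporting, moderate, strong or
very-strong strength adds **+1, +2, +4 or +8** points; benign criteria
subtract the same magnitudes. The signed total *S* maps to a five-tier
class:

- S ≥ 10 → pathogenic
- 6 ≤ S ≤ 9 → likely pathogenic
- 0 ≤ S ≤ 5 → unknown significance (VUS)
- −5 ≤ S ≤ −1 → likely benign
- S ≤ −6 → benign

BA1 is standalone: reaching the BA1 frequency threshold short-circuits the
class to benign. Before summation, named criterion pairs that encode the
same underlying evidence (PVS1×PP3, PVS1×PM1, PM1×PP3, PVS1×PM4 by
default) are reduced to their stronger member.

Key evaluation components:

- a loss-of-function (PVS1) decision tree over NMD prediction (50-nt
  last-junction rule), exon relevance and fraction of protein lost, with
  SpliceAI integration for canonical splice variants, a PTEN c.1121
  override and a CDH1 site-specific splice table;
- frequency criteria (BA1/BS1/PM2/BS2) on one-sided 95% Clopper–Pearson
  lower bounds of subpopulation allele frequencies, with founder-population
  exclusion;
- in silico criteria (PP3/BP4/BP7) at the calibrated SpliceAI cut-offs
  (≥ 0.5 pathogenic, ≤ 0.15 benign) and configurable REVEL cut-offs;
- codon-context criteria (PS1/PM5) against expert-panel classified
  variants, curated functional assays (PS3/BS3), and intake of
  curator-supplied manual criteria (the retired PP5/BP6 are refused).

## Worked example

The package ships a deterministic fixture generator whose scenarios declare
the outcome they are built to produce. A rare nonsense variant with a high
splice score:

```r
library(hcvarclass)
sc  <- make_evidence_scenario("rare_truncating")
cfg <- scenario_config(sc)
res <- combine_criteria(sc$bundle, cfg)
print(res)
#> PALB2 NM_SYNTH_PALB2.1 c.300C>T
#> classification: likely_pathogenic (+9 points)
#>   PM2   supporting   +1  variant absent from all coverage-passing populations
#>   PVS1  very_strong  +8  decision path: nonsense > nmd_predicted > in_relevant_region
#>   PP3   supporting   +1  SpliceAI max delta 0.6 >= PP3 cut-off 0.5
#>   dropped PP3 (kept PVS1): splice/protein prediction already underlies the loss-of-function call
```

Reading the output: the variant is absent from all coverage-passing
populations (PM2, +1 at this gene's configured strength), is a nonsense
change predicted to undergo nonsense-mediated decay inside the biologically
relevant region (PVS1 very strong, +8), and the splice predictor also fires
(PP3) — but PP3 encodes the same evidence as PVS1, so it is dropped before
summation. Total +9 points → likely pathogenic.

Classification from files works the same way
(`classify_single(gene, transcript, cdna, evidence.json)`), batches run via
`classify_batch(table.tsv, out_dir)` with one log entry per row, and
`inst/cli/hcvarclass.R` exposes `classify`, `batch`, `validate-config` and
`make-fixtures` subcommands for shell use. Gene-specific cut-offs are
overridable with a 3-column tab-delimited file (see
`inst/extdata/gene_config_defaults.tsv`; the shipped allele-frequency
thresholds are documented synthetic defaults).

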