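---
title: "How hcvarclass classifies variants: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How hcvarclass classifies variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcvarclass)
```

## The problem and the model

Germline variants in hereditary-cancer genes are classified under the
ACMG/AMP framework: a set of coded evidence criteria (PVS1, PS1–PS4, PM1–PM6,
PP1–PP4 in favour of pathogenicity; BA1, BS1–BS4, BP1–BP5 and BP7 in favour
of benignity), each assignable at a strength level, whose combination yields
a five-tier clinical class. `hcvarclass` implements this as a deterministic
rules engine over locally supplied *evidence bundles* — structured JSON files
carrying everything an evaluation needs (subpopulation allele counts,
predictor scores, expert-panel codon context, functional-assay records,
region flags, optional curator-supplied criteria). There is no network
access and no database scraping: reproducibility is the point.

Criterion combination uses the naturally scaled point system: an assigned
pathogenic criterion at supporting / moderate / strong / very-strong
strength contributes +1 / +2 / +4 / +8 points, a benign criterion the
negative of the same magnitudes, and the signed total maps onto five bands:

| total points | class |
|---|---|
| ≥ 10 | pathogenic |
| 6 – 9 | likely pathogenic |
| 0 – 5 | unknown significance (VUS) |
| −5 – −1 | likely benign |
| ≤ −6 | benign |

BA1 is *standalone*: when the population frequency reaches the BA1
threshold, the class is benign regardless of the total. The engine still
evaluates and reports every other criterion for such variants — curators
want the full picture — but the classification is decided by the standalone
rule, so the reported point total for a BA1 variant is informational only.

Before summation, pairwise *overlap exclusions* (in the spirit of the
CanVIG-UK consensus) remove double counting: pairs of assigned criteria that
encode the same underlying evidence must not both score. The shipped pairs
are PVS1×PP3, PVS1×PM1, PM1×PP3 and PVS1×PM4; the file
`extdata/exclusion_rules.tsv` is user-replaceable. Within a triggered pair
the lower-point call is dropped; on a points tie the code later in canonical
strength-class order (PVS1 < PS < PM < PP) is dropped, which deterministically
preserves the stronger evidence category. The result is conflict-free and
invariant under input reordering (this is property-tested).

## Tri-state evidence

Every evidence block in a bundle is tri-state: present, absent, or unknown.
A predictor score of 0 and a missing predictor are different things, and the
engine never converts "no evidence" into a denial — a criterion whose inputs
are unavailable comes back `not_automated`, distinct from `denied`
(evidence argues against) and `not_applicable` (the gene's guidelines
exclude the criterion). This separation mirrors how curation teams audit
automated calls, and it is what the report files expose per criterion.

## Gene-specific rule variants

Nine genes carry specific profiles (ATM, CDH1, CHEK2, MLH1, MSH2, MSH6,
PMS2, PTEN, TP53); every other gene inherits the GENERAL profile. The
configuration is a flat tab-delimited table (`gene`, `parameter`, `value`)
so laboratories can override any cut-off or mode without touching code.
Highlights of the shipped defaults:

* **CDH1** — PM2 downgraded to supporting strength; PS1 retired and PM5
  redefined to truncating variants predicted or proven to undergo NMD (and
  canonical splice variants explicitly marked eligible); a site-specific
  splice table caps PVS1 for listed positions (c.1137+1 → strong); BP7 no
  longer requires non-conservation; PM1 and curated PS3/BS3 do not apply;
  BP2 can be assigned, at supporting strength only, from homozygous
  occurrence in the non-cancer dataset.
* **PTEN** — truncating variants starting 5′ of c.1121 are forced to
  very-strong PVS1; PP2 applies; curated benign assays (BS3) are not used.
* **MMR genes (MLH1/MSH2/MSH6/PMS2)** — pathogenic splice calls require the
  SpliceAI score *and* the MMR-specific splice prior to agree; PM1 and BP2
  do not apply; BS2 is not automated. PMS2 additionally has no curated
  assay coverage.
* **ATM / CHEK2** — BS2 does not apply; ATM also excludes PM1.

The retired PP5/BP6 codes (reputable-source assertions without access to
primary data) are rejected everywhere, including curator input.

## Frequency criteria

Population evidence comes as per-subpopulation records (allele count, allele
number, homozygote count, a founder flag, a coverage flag for the 20×
minimum). Two refinements are configurable and on by default:

* **Founder exclusion.** Bottleneck populations (the defaults mark Ashkenazi
  Jewish and Finnish) are excluded from the BA1/BS1 popmax, because drift
  can inflate frequencies that negative selection would otherwise keep low.
  The founder set is data, not code: records carry the flag.
* **CI lower bound.** Comparisons use the one-sided 95% Clopper–Pearson
  (exact binomial) lower confidence limit of the allele frequency rather
  than the point estimate, so sparsely sampled populations cannot trigger
  benign criteria on unstable estimates. The exact binomial was chosen
  because it is conservative, parameter-free and reproducible; the level is
  configurable (`ci_confidence`). For zero observed alleles the bound is 0.

BA1 uses an inclusive `≥` at its threshold (covered by a boundary test);
BS1 fires below it; PM2 requires absence from all coverage-passing
populations or a global statistic at or below its threshold, and is never
combined with BA1/BS1. Absence is only meaningful when at least one
population passed coverage — otherwise the criteria are `not_automated`.

The *numeric* BA1/BS1/PM2 thresholds shipped in
`extdata/gene_config_defaults.tsv` (0.005 / 0.001 / 2×10⁻⁵) are documented
synthetic defaults: published guideline values differ per gene and should
be substituted in deployments. All tests use these documented values.

## The loss-of-function (PVS1) tree

For nonsense and frameshift variants the engine predicts nonsense-mediated
decay with the 50-nt rule: NMD is expected when the premature termination
codon lies more than 50 nt upstream of the 3′-most exon–exon junction
(single-exon transcripts escape). The tree then assigns:

* NMD predicted, PTC within the biologically relevant region → very strong.
* NMD predicted but the PTC lies beyond an annotated relevant-region
  boundary → the call falls through to the NMD-escape logic below. The
  framework's language for this branch is a *reduced* strength; routing it
  through the removed-region/fraction rules makes the reduction concrete
  and keeps one code path, at the cost of treating "beyond the relevant
  region" identically to NMD escape.
* NMD escape → strong if the removed region overlaps an annotated relevant
  region; otherwise strong when more than `protein_loss_fraction` (default
  10%) of the protein is lost, else moderate. With no relevant-region
  annotation (`relevant_region_end = NULL`) NMD-predicted truncations are
  very strong and NMD-escaping ones are weighed purely by the fraction
  rule; the asymmetry in the meaning of the missing annotation is
  deliberate and matches how the framework treats unannotated transcripts.

Canonical ±1/±2 splice variants integrate the splice prediction:

* If the largest SpliceAI delta is a *gain* (acceptor-gain or donor-gain),
  the outcome is deliberately conservative — supporting strength plus a
  warning suggesting an RNA assay — because the transcriptional consequence
  of a novel site cannot be inferred from the score alone.
* Predicted skipping of the first or last exon yields no strength and a
  warning: terminal-exon skipping frequently re-initiates or escapes decay.
* Otherwise the skipped exon's length decides: in-frame skips are weighed
  by removed-region relevance and fraction removed; frameshifting skips
  re-enter the truncation logic with the PTC approximated at the exon
  start.

Start-loss takes the moderate branch. SpliceAI deltas are aggregated as the
maximum of the four scores; gain detection is "the argmax is a gain type".
All tree parameters (relevant region, fraction cut, override boundary,
site table) live in the transcript model and gene configuration, not in
code.

## In silico criteria

PP3/BP4 evaluate up to two arms at fixed supporting strength — the paper
trail behind the calibrated SpliceAI cut-offs justifies stronger weights,
but supporting is deliberately retained:

* splice arm: `s = max(ΔAG, ΔAL, ΔDG, ΔDL)`; pathogenic at `s ≥ 0.5`,
  benign at `s ≤ 0.15`, no call in the gap (both cut-offs inclusive).
* protein arm (missense only): REVEL at the configured cut-offs. The
  shipped 0.70/0.25 are placeholders for the externally optimised values
  and are plain configuration.

PP3 fires if either arm supports pathogenicity; BP4 only if every evaluable
arm supports benignity — so the two are mutually exclusive by construction,
and over a sweep of the splice score the call sequence is a two-change-point
step function (tested on a 0.01 grid). For MMR genes the pathogenic splice
call is conjunctive with the MMR splice prior: disagreement yields no call
with an explanation, and a missing prior leaves PP3 unconfirmable
(`not_automated`) rather than assigned. Benign splice calls use SpliceAI
alone — the conjunction only gates assignments of pathogenic evidence.

BP7 (synonymous / deep-intronic, no predicted impact) requires the benign
splice condition and, where the gene profile demands it, a PhastCons score
strictly below `conservation_max_phastcons` (default 1.0) — so a fully
conserved nucleotide (PhastCons = 1) blocks BP7, and CDH1, whose current
guidelines dropped the conservation condition, sets the requirement off.
PhyloP is carried in the bundle but unused by default: no published
threshold is adopted.

## Codon context and functional evidence

PS1/PM5 consult only expert-panel-reviewed pathogenic entries by default
(`expert_panel_only`, relaxable per gene): PS1 for an identical protein
change via a different nucleotide change, PM5 for a different substitution
at the same codon (missense only, never together with PS1). "Proven NMD"
for the CDH1 truncating PM5 rule is an explicit RNA-evidence flag in the
bundle, distinct from the 50-nt prediction; the eligible canonical splice
variants under that rule are likewise gated behind an explicit bundle flag
rather than guessed.

PS3/BS3 are looked up in a packaged, curator-extensible table of
clinically calibrated assays keyed by gene and normalised cDNA. The shipped
rows are synthetic examples (see the file header); deployments substitute
the assays their guidelines list. Absence of a record abstains
(`not_automated`) — the absence of an assay is not evidence of anything.
Conflicting records for one variant are resolved in favour of
guideline-listed sources; unresolved conflicts suppress both calls with a
warning.

## Numerical and degenerate-input choices

* Clopper–Pearson lower bound: `qbeta(1 − conf, x, n − x + 1)`, 0 at
  `x = 0`; verified in tests against an independent inversion of the
  binomial tail by root finding, to 10⁻⁹.
* All threshold comparisons at printed cut-offs are inclusive on the side
  the rule states (`≥` for assignments toward pathogenicity and BA1,
  `≤` for benign cut-offs).
* Exclusion tie-breaks are resolved by canonical code order (see above) so
  results never depend on input order.
* Variant scope: substitutions, deletions, duplications, insertions and
  single-anchor deletion–insertions up to 25 nt, with intronic offsets and
  UTR positions; inversions, two-sided delins and longer indels are
  rejected with machine-readable reasons before any evaluation.
* Unreadable rows in a batch never abort the run; each input row produces
  exactly one log entry with its outcome and wall time (timing is recorded
  but never asserted in tests).

## The synthetic-data generator, and what the tests do not show

The fixture module generates every test input in code: arithmetic
transcript models, subpopulation record sets, and ~30 named evidence
scenarios, each *declaring* the exact post-exclusion criterion set, class
and point total it is built to produce. The suite runs every scenario
through the engine and checks the declaration, so generator and engine
cannot drift apart silently. Generation is a pure function of
(scenario, seed) and byte-reproducible.

The generator emulates the *structure* of real evidence — labelled AC/AN
records with founder and coverage flags, predictor score vectors, codon
context entries — not its messiness. It does not model real gnomAD
subpopulation covariance, transcript-annotation ambiguity, HGVS dialect
variation, or the biases of real functional assays. Passing tests therefore
demonstrate that the rules are implemented as specified, not that the
shipped synthetic thresholds reproduce any published gene's classification
distribution; for that, deployments must load their guideline thresholds
and curated assay tables.

Problem sizes used by the test-suite checks were chosen to exercise the
mathematics exhaustively while staying desk-scale: all 4,096 subsets of a
12-criterion universe against the brute-force combination oracle, 1,000
random criterion sets for exclusion/monotonicity properties, a 200-point
(AC, AN) grid for the CI oracle, 0.01-resolution sweeps for the splice
step function, and a 50-variant batch for the logging contract.

## Known limitations

* No nomenclature correction: descriptions must be syntactically normalised
  HGVS-c; there is no VCF/genome-coordinate input or build liftover.
* The PTC position for frameshift variants is approximated by the variant
  start; true termination positions depend on the downstream sequence.
* The PVS1 tree's relevant-region logic is linear (a single 3′ boundary per
  transcript); discontinuous critical domains need the PM1 region flag
  instead.
* The xlsx report writer is a minimal single-sheet inline-string
  implementation — sufficient for spreadsheet viewers and `readxl`, but not
  styled; TSV is the canonical format.
* Exclusion handling is pairwise only; consensus recommendations beyond
  pairwise double-counting prohibitions are out of the shipped defaults.
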