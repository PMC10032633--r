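test_that("PS1/PM5 classic mode compares expert-panel codon context", {
  ctx_entry <- function(cdna, ref, codon, alt, cls = "P", panel = TRUE) {
    list(cdna = cdna, protein_change = list(ref_aa = ref, codon = codon,
                                            alt_aa = alt),
         classification = cls, expert_panel_reviewed = panel,
         nmd_predicted = NULL)
  }
  mk <- function(ctx) {
    fx_missense_bundle(cdna = "c.91A>T",
                       protein_change = list(ref_aa = "Ser", codon = 31,
                                             alt_aa = "Cys"),
                       codon_context = ctx)
  }
  cfg <- fx_cfg()
  # identical protein change via a different nucleotide change: PS1
  calls <- evaluate_ps1_pm5(mk(list(ctx_entry("c.91_93delinsTGT", "Ser", 31,
                                              "Cys"))), cfg)
  expect_identical(calls[[1]]$state, "assigned")
  expect_identical(calls[[2]]$state, "denied")  # never together with PS1
  # same codon, different substitution: PM5
  calls <- evaluate_ps1_pm5(mk(list(ctx_entry("c.92G>C", "Ser", 31, "Thr"))),
                            cfg)
  expect_identical(calls[[1]]$state, "denied")
  expect_identical(calls[[2]]$state, "assigned")
  expect_identical(calls[[2]]$strength, "moderate")
  # non-expert-panel and non-pathogenic entries are ignored
  calls <- evaluate_ps1_pm5(mk(list(
    ctx_entry("c.92G>C", "Ser", 31, "Thr", panel = FALSE),
    ctx_entry("c.93C>A", "Ser", 31, "Arg", cls = "VUS"))), cfg)
  expect_identical(calls[[1]]$state, "denied")
  expect_identical(calls[[2]]$state, "denied")
  # relaxing the expert-panel requirement admits the first entry again
  calls <- evaluate_ps1_pm5(mk(list(
    ctx_entry("c.92G>C", "Ser", 31, "Thr", panel = FALSE))),
    fx_cfg(expert_panel_only = FALSE))
  expect_identical(calls[[2]]$state, "assigned")
  # missing context is not denial
  calls <- evaluate_ps1_pm5(fx_missense_bundle(), cfg)
  expect_identical(calls[[1]]$state, "not_automated")
  expect_identical(calls[[2]]$state, "not_automated")
})

test_that("CDH1 truncating PM5 follows NMD and the splice eligibility flag", {
  cfg <- fx_cfg("CDH1")
  sc <- make_evidence_scenario("cdh1_truncating_pm5")
  calls <- evaluate_ps1_pm5(sc$bundle, cfg)
  expect_identical(calls[[1]]$state, "not_applicable")
  expect_identical(calls[[2]]$state, "assigned")
  # NMD-escaping truncation: denied unless proven by RNA evidence
  b <- sc$bundle
  b$descriptor <- parse_cdna_description("c.2600G>T", gene_symbol = "CDH1",
                                         transcript_id = "NM_SYNTH_CDH1.1")
  expect_identical(evaluate_ps1_pm5(b, cfg)[[2]]$state, "denied")
  b$flags$nmd_proven <- TRUE
  expect_identical(evaluate_ps1_pm5(b, cfg)[[2]]$state, "assigned")
  # canonical splice variants are gated by the explicit eligibility flag
  sp <- make_evidence_scenario("cdh1_splice_site")$bundle
  expect_identical(evaluate_ps1_pm5(sp, cfg)[[2]]$state, "denied")
  sp$flags$cdh1_pm5_splice_eligible <- TRUE
  expect_identical(evaluate_ps1_pm5(sp, cfg)[[2]]$state, "assigned")
})

test_that("PS1 and PM5 are never co-assigned across all scenarios", {
  for (nm in scenario_names()) {
    sc <- make_evidence_scenario(nm)
    calls <- evaluate_ps1_pm5(sc$bundle, scenario_config(sc, fx_configs))
    expect_false(calls[[1]]$state == "assigned" &&
                   calls[[2]]$state == "assigned", label = nm)
  }
})

test_that("functional assay lookup assigns, abstains and resolves conflicts", {
  sc <- make_evidence_scenario("missense_hotspot")
  calls <- evaluate_functional(sc$bundle, fx_cfg("TP53"))
  expect_identical(calls[[1]]$state, "assigned")
  expect_identical(calls[[1]]$strength, "strong")
  expect_match(calls[[1]]$explanation, "SYNTH-TP53-ASSAY-1")
  # lookup is pure: identical inputs give identical calls
  expect_identical(evaluate_functional(sc$bundle, fx_cfg("TP53")), calls)
  # uncovered genes abstain rather than deny
  cdh1 <- make_evidence_scenario("bp2_homozygote")
  calls <- evaluate_functional(cdh1$bundle, fx_cfg("CDH1"))
  expect_identical(calls[[1]]$state, "not_automated")
  expect_identical(calls[[2]]$state, "not_automated")
  # PTEN: BS3 uncovered, PS3 still consultable
  pten <- make_evidence_scenario("pten_missense")
  calls <- evaluate_functional(pten$bundle, fx_cfg("PTEN"))
  expect_identical(calls[[2]]$state, "not_automated")
  # unresolvable conflict suppresses the call with a warning
  conf <- make_evidence_scenario("conflicting_assays")
  calls <- evaluate_functional(conf$bundle, fx_cfg("ATM"))
  expect_identical(calls[[1]]$state, "warning")
  expect_match(calls[[1]]$explanation, "conflicting")
  # guideline-listed sources outrank others when strengths conflict
  tbl <- list(
    functional_assay_record("ATM", "c.301C>T", "SRC-LISTED", "abnormal",
                            "strong", guideline_listed = TRUE),
    functional_assay_record("ATM", "c.301C>T", "SRC-OTHER", "normal",
                            "strong"))
  b <- conf$bundle
  b$functional <- NULL
  calls <- evaluate_functional(b, fx_cfg("ATM"), assay_table = tbl)
  expect_identical(calls[[1]]$state, "assigned")
  # absence of any record is abstention, never denial
  b2 <- fx_missense_bundle(gene = "ATM", cdna = "c.999G>A")
  calls <- evaluate_functional(b2, fx_cfg("ATM"))
  expect_identical(calls[[1]]$state, "not_automated")
})

test_that("PM1/PP2/BP2 applicability matches the gene matrix", {
  genes <- c("ATM", "CDH1", "CHEK2", "MLH1", "MSH2", "MSH6", "PMS2",
             "PTEN", "TP53", "PALB2")
  pm1_na <- c("ATM", "CDH1", "MLH1", "MSH2", "MSH6", "PMS2")
  pp2_on <- "PTEN"
  bp2_na <- c("MLH1", "MSH2", "MSH6", "PMS2")
  bp2_partial <- "CDH1"
  for (g in genes) {
    cfg <- fx_cfg(g)
    b <- fx_missense_bundle(gene = g, flags = list(in_pm1_region = TRUE))
    calls <- evaluate_pm1_pp2(b, cfg)
    expect_identical(calls[[1]]$state,
                     if (g %in% pm1_na) "not_applicable" else "assigned",
                     label = paste("PM1", g))
    expect_identical(calls[[2]]$state,
                     if (g %in% pp2_on) "assigned" else "not_applicable",
                     label = paste("PP2", g))
    bp2 <- evaluate_bp2(b, cfg)
    expect_identical(bp2$state,
                     if (g %in% bp2_na) "not_applicable" else "not_automated",
                     label = paste("BP2", g))
    app <- criterion_applicability(cfg)
    expect_identical(app[["PM1"]],
                     if (g %in% pm1_na) "not_applicable" else "automated")
  }
  # PM1 restricted to missense / in-frame consequences
  b <- fx_missense_bundle(gene = "TP53", flags = list(in_pm1_region = TRUE))
  b$flags$protein_consequence <- "nonsense"
  b$flags$is_missense <- FALSE
  expect_identical(evaluate_pm1_pp2(b, fx_cfg("TP53"))[[1]]$state, "denied")
  # CDH1 homozygote rule: supporting strength from homozygous observations
  b <- fx_missense_bundle(gene = "CDH1", homozygote_count_noncancer = 2L)
  bp2 <- evaluate_bp2(b, fx_cfg("CDH1"))
  expect_identical(bp2$state, "assigned")
  expect_identical(bp2$strength, "supporting")
})

test_that("manual criteria are ingested, flagged, and PP5/BP6 rejected", {
  calls <- ingest_manual_criteria(list(list(code = "PP1", strength = "strong"),
                                       list(code = "PS4",
                                            strength = "moderate")))
  expect_identical(calls[[1]]$source, "manual")
  expect_equal(calls[[1]]$points, 4)
  expect_equal(calls[[2]]$points, 2)
  expect_error(ingest_manual_criteria(list(list(code = "PP5",
                                                strength = "supporting"))),
               "retired")
  expect_error(ingest_manual_criteria(list(list(code = "BP6",
                                                strength = "supporting"))),
               "retired")
  # a manual code colliding with an automated assignment overrides with a
  # logged warning
  sc <- make_evidence_scenario("rare_truncating")
  b <- sc$bundle
  b$manual_criteria <- list(list(code = "PVS1", strength = "moderate"))
  res <- combine_criteria(b, scenario_config(sc, fx_configs))
  pvs1 <- Filter(function(cl) cl$code == "PVS1", res$calls)[[1]]
  expect_identical(pvs1$source, "manual")
  expect_identical(pvs1$strength, "moderate")
  expect_match(paste(res$warnings, collapse = " "), "overrides")
})
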