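test_that("NMD prediction applies the 50-nt last-junction rule", {
  t <- transcript_model("T1", data.frame(index = 1:3,
                                         cdna_first = c(1, 501, 1001),
                                         cdna_last = c(500, 1000, 1500)))
  lj <- t$last_junction_cdna  # 1000
  d_at <- function(pos) parse_cdna_description(sprintf("c.%dG>T", pos))
  expect_true(predict_nmd(d_at(100), t))
  expect_false(predict_nmd(d_at(lj - 30), t))
  # boundary: strictly more than 50 nt upstream of the junction
  expect_true(predict_nmd(d_at(lj - 51), t))
  expect_false(predict_nmd(d_at(lj - 50), t))
  expect_false(predict_nmd(d_at(lj - 49), t))
  t1 <- transcript_model("T2", data.frame(index = 1, cdna_first = 1,
                                          cdna_last = 300))
  expect_false(predict_nmd(d_at(100), t1))
  expect_error(predict_nmd(parse_cdna_description("c.100+3G>T"), t),
               "intronic")
})

test_that("PTEN-style override forces very strong 5' of the boundary only", {
  sc <- make_evidence_scenario("pten_truncating")
  res <- evaluate_pvs1(sc$bundle, fx_cfg("PTEN"))
  expect_identical(res$state, "assigned")
  expect_identical(res$strength, "very_strong")

  strength_at <- function(pos, cfg) {
    b <- sc$bundle
    b$descriptor <- parse_cdna_description(sprintf("c.%dC>T", pos),
                                           gene_symbol = "PTEN",
                                           transcript_id = "NM_SYNTH_PTEN.1")
    evaluate_pvs1(b, cfg)$strength
  }
  cfg_over <- fx_cfg("PTEN")
  cfg_tree <- fx_cfg("PTEN", pvs1_mode = "general_tree")
  # below the boundary the override forces very strong even where the
  # general tree would not (NMD-escaping positions)
  expect_identical(strength_at(1120, cfg_over), "very_strong")
  expect_false(identical(strength_at(1120, cfg_tree), "very_strong"))
  # at and beyond the boundary the general tree's output is returned
  for (pos in c(1121, 1150, 1200)) {
    expect_identical(strength_at(pos, cfg_over), strength_at(pos, cfg_tree))
  }
  for (pos in c(10, 300, 600, 900, 1120)) {
    expect_identical(strength_at(pos, cfg_over), "very_strong")
  }
})

test_that("CDH1 site-specific table caps c.1137+1 at strong", {
  sc <- make_evidence_scenario("cdh1_splice_site")
  res <- evaluate_pvs1(sc$bundle, fx_cfg("CDH1"))
  expect_identical(res$strength, "strong")
  expect_match(res$explanation, "site_specific")
  # the same variant under the general tree would take the splice arm
  res2 <- evaluate_pvs1(sc$bundle, fx_cfg("CDH1", pvs1_mode = "general_tree"))
  expect_false(identical(res2$explanation, res$explanation))
})

test_that("canonical splice arm: gain is conservative, edge exons warn", {
  gain <- make_evidence_scenario("splice_region_gain")
  res <- evaluate_pvs1(gain$bundle, fx_cfg())
  expect_identical(res$strength, "supporting")
  expect_match(paste(res$warnings, collapse = " "), "RNA assay")

  edge <- make_evidence_scenario("first_exon_splice")
  res <- evaluate_pvs1(edge$bundle, fx_cfg())
  expect_identical(res$state, "warning")
  expect_identical(res$strength, "none")
  expect_equal(res$points, 0)
  expect_match(paste(res$warnings, collapse = " "), "first or last exon")

  # missing SpliceAI scores make the splice arm non-automatable
  b <- gain$bundle
  for (f in c("spliceai_ag", "spliceai_al", "spliceai_dg", "spliceai_dl")) {
    b$predictions[f] <- list(NULL)
  }
  expect_identical(evaluate_pvs1(b, fx_cfg())$state, "not_automated")
})

test_that("every loss-of-function tree leaf is reachable by a scenario", {
  paths <- vapply(scenario_names(), function(nm) {
    sc <- make_evidence_scenario(nm)
    evaluate_pvs1(sc$bundle, scenario_config(sc, fx_configs))$explanation
  }, "")
  hit <- function(x) any(grepl(x, paths, fixed = TRUE))
  expect_true(hit("in_relevant_region"))        # NMD-yes very strong
  expect_true(hit("outside_relevant_region"))   # NMD-yes, region-bounded
  expect_true(hit("removed_region_relevant"))   # NMD-escape, relevant region
  expect_true(hit("nmd_escape"))
  expect_true(hit("splice_site_gain"))
  expect_true(hit("first_or_last_exon"))
  expect_true(hit("in_frame"))
  expect_true(hit("startloss"))
  expect_true(hit("gene_override"))
  expect_true(hit("site_specific"))
  strengths <- vapply(scenario_names(), function(nm) {
    sc <- make_evidence_scenario(nm)
    evaluate_pvs1(sc$bundle, scenario_config(sc, fx_configs))$strength
  }, "")
  expect_true(all(strengths %in% c("very_strong", "strong", "moderate",
                                   "supporting", "none")))
  expect_setequal(intersect(c("very_strong", "strong", "moderate",
                              "supporting", "none"), strengths),
                  c("very_strong", "strong", "moderate", "supporting", "none"))
})

test_that("splice PP3/BP4 is a two-change-point step function", {
  cfg <- fx_cfg()
  b <- fx_missense_bundle()
  b$flags$protein_consequence <- "intronic"
  b$flags$is_missense <- FALSE
  call_at <- function(s) {
    b$predictions$spliceai_ag <- 0
    b$predictions$spliceai_al <- 0
    b$predictions$spliceai_dg <- 0
    b$predictions$spliceai_dl <- s
    calls <- evaluate_pp3_bp4(b, cfg)
    if (calls[[1]]$state == "assigned") "PP3"
    else if (calls[[2]]$state == "assigned") "BP4"
    else "none"
  }
  grid <- seq(0, 1, by = 0.01)
  seq_calls <- vapply(grid, call_at, "")
  expect_identical(unique(seq_calls), c("BP4", "none", "PP3"))
  changes <- which(seq_calls[-1] != seq_calls[-length(seq_calls)])
  expect_length(changes, 2)
  # change points at the configured (printed) cut-offs, boundaries inclusive
  expect_identical(call_at(0.15), "BP4")
  expect_identical(call_at(0.16), "none")
  expect_identical(call_at(0.5), "PP3")
  expect_identical(call_at(0.49), "none")
  expect_identical(call_at(0.3), "none")
})

test_that("PP3/BP4 combine protein and splice arms correctly", {
  cfg <- fx_cfg()
  mk <- function(revel, sai) {
    b <- fx_missense_bundle()
    b$predictions$revel <- revel
    b$predictions$spliceai_ag <- 0
    b$predictions$spliceai_al <- 0
    b$predictions$spliceai_dg <- 0
    b$predictions$spliceai_dl <- sai
    evaluate_pp3_bp4(b, cfg)
  }
  # either arm pathogenic fires PP3
  calls <- mk(0.9, 0.05)
  expect_identical(calls[[1]]$state, "assigned")
  expect_identical(calls[[2]]$state, "denied")
  # BP4 needs every evaluable arm benign
  calls <- mk(0.1, 0.3)   # protein benign, splice indeterminate
  expect_identical(calls[[1]]$state, "denied")
  expect_identical(calls[[2]]$state, "denied")
  calls <- mk(0.1, 0.05)  # both benign
  expect_identical(calls[[2]]$state, "assigned")
  # PP3 and BP4 never co-assigned across a random sweep
  set.seed(7)
  for (i in 1:50) {
    calls <- mk(runif(1), runif(1))
    expect_false(calls[[1]]$state == "assigned" &&
                   calls[[2]]$state == "assigned")
  }
})

test_that("MMR splice calls require predictor agreement", {
  cfg <- fx_cfg("MLH1")
  mk <- function(sai, prior) {
    b <- fx_missense_bundle(gene = "MLH1")
    b$flags$protein_consequence <- "intronic"
    b$flags$is_missense <- FALSE
    b$predictions$spliceai_ag <- 0
    b$predictions$spliceai_al <- 0
    b$predictions$spliceai_dg <- 0
    b$predictions$spliceai_dl <- sai
    b$predictions$mmr_prior <- prior
    evaluate_pp3_bp4(b, cfg)
  }
  expect_identical(mk(0.7, 0.9)[[1]]$state, "assigned")
  res <- mk(0.7, 0.2)
  expect_identical(res[[1]]$state, "denied")
  expect_match(res[[1]]$explanation, "disagree")
  # prior missing: the pathogenic splice call cannot be confirmed
  expect_identical(mk(0.7, NULL)[[1]]$state, "not_automated")
  # benign splice calls use SpliceAI alone
  expect_identical(mk(0.05, NULL)[[2]]$state, "assigned")
})

test_that("BP7 requires benign splice prediction and applies conservation", {
  mk <- function(gene, phastcons, cons = "synonymous") {
    b <- fx_missense_bundle(gene = gene)
    b$flags$protein_consequence <- cons
    b$flags$is_missense <- cons == "missense"
    b$predictions$phastcons <- phastcons
    b
  }
  cfg <- fx_cfg()
  # strongly conserved nucleotide (PhastCons 1) blocks BP7
  expect_identical(evaluate_bp7(mk("PALB2", 1.0), cfg, TRUE)$state, "denied")
  expect_identical(evaluate_bp7(mk("PALB2", 0.3), cfg, TRUE)$state, "assigned")
  # CDH1 no longer applies the conservation condition
  cdh1 <- fx_cfg("CDH1")
  expect_identical(evaluate_bp7(mk("CDH1", 1.0), cdh1, TRUE)$state, "assigned")
  # prerequisites
  expect_identical(evaluate_bp7(mk("PALB2", 0.3), cfg, FALSE)$state, "denied")
  expect_identical(evaluate_bp7(mk("PALB2", NULL), cfg, TRUE)$state,
                   "not_automated")
  expect_identical(evaluate_bp7(mk("PALB2", 0.3, "missense"), cfg, TRUE)$state,
                   "not_applicable")
})

test_that("PM4/BP3 split on repeat-region membership and are exclusive", {
  mk <- function(cons, repeat_region) {
    b <- fx_missense_bundle(cdna = "c.100_102del")
    b$flags$protein_consequence <- cons
    b$flags$is_missense <- FALSE
    b$flags$in_repeat_region <- repeat_region
    evaluate_pm4_bp3(b, fx_cfg())
  }
  calls <- mk("inframe_indel", FALSE)
  expect_identical(calls[[1]]$state, "assigned")
  expect_identical(calls[[2]]$state, "denied")
  calls <- mk("inframe_indel", TRUE)
  expect_identical(calls[[1]]$state, "denied")
  expect_identical(calls[[2]]$state, "assigned")
  calls <- mk("stoploss", FALSE)
  expect_identical(calls[[1]]$state, "assigned")
  calls <- mk("nonsense", FALSE)
  expect_identical(calls[[1]]$state, "not_applicable")
  expect_identical(calls[[2]]$state, "not_applicable")
})
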