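test_that("HGVS parser extracts positions, offsets and alleles", {
  d <- parse_cdna_description("c.1137+1delG")
  expect_equal(d$variant_type, "deletion")
  expect_equal(d$cdna_start, 1137)
  expect_equal(d$intron_offset_start, 1)
  expect_equal(d$indel_length, 1)

  d <- parse_cdna_description("c.100A>T")
  expect_equal(d$variant_type, "substitution")
  expect_equal(d$cdna_start, 100)
  expect_equal(d$cdna_end, 100)
  expect_equal(d$ref_allele, "A")
  expect_equal(d$alt_allele, "T")
  expect_equal(d$indel_length, 0)

  d <- parse_cdna_description("c.892G>T")
  expect_equal(d$cdna_start, 892)
  expect_equal(d$ref_allele, "G")
  expect_equal(d$alt_allele, "T")

  # duplication length comes from the duplicated span
  expect_equal(parse_cdna_description("c.100_105dup")$indel_length, 6)
  # UTR positions
  d <- parse_cdna_description("c.-15C>T")
  expect_equal(d$cdna_start, -15)
  d <- parse_cdna_description("c.*52+3A>G")
  expect_true(d$utr3_start)
  expect_equal(d$cdna_start, 52)
  expect_equal(d$intron_offset_start, 3)
})

test_that("HGVS parser rejects malformed and protein-level input", {
  expect_error(parse_cdna_description("g.100A>T"), "must begin with 'c\\.'")
  expect_error(parse_cdna_description("p.Arg175His"), "protein-level")
  expect_error(parse_cdna_description("c.100A>"), "unrecognised form")
  expect_error(parse_cdna_description("c.foo"), "unrecognised form")
  expect_error(parse_cdna_description(""), "non-empty")
})

test_that("parse . format is the identity on the supported subset", {
  cases <- c("c.100A>T", "c.892G>T", "c.1137+1delG", "c.-15C>T",
             "c.*52A>G", "c.4072-1G>A", "c.100_102del", "c.100_102delATG",
             "c.100_105dup", "c.100_101insATG", "c.100delinsTT",
             "c.100_102delinsA", "c.300+5_300+7del", "c.2T>C",
             "c.100_110inv")
  for (s in cases) {
    d <- parse_cdna_description(s)
    expect_identical(format_cdna(d), s)
    d2 <- parse_cdna_description(format_cdna(d))
    expect_identical(unclass(d2), unclass(d))
  }
})

test_that("variant validation accepts exactly the supported type/length set", {
  # deletions and insertions across lengths 1..30: the 25-bp limit is sharp
  for (len in 1:30) {
    del <- if (len == 1) "c.100del" else sprintf("c.100_%ddel", 99 + len)
    ins <- sprintf("c.100_101ins%s", strrep("A", len))
    dup <- if (len == 1) "c.100dup" else sprintf("c.100_%ddup", 99 + len)
    for (s in c(del, ins, dup)) {
      v <- validate_supported_variant(parse_cdna_description(s))
      expect_identical(v$accepted, len <= 25, label = s)
      if (len > 25) expect_identical(v$reason, "indel_length_exceeds_25")
    }
  }
  expect_true(validate_supported_variant(
    parse_cdna_description("c.100A>T"))$accepted)
  v <- validate_supported_variant(parse_cdna_description("c.100_110inv"))
  expect_false(v$accepted)
  expect_identical(v$reason, "unsupported_type_inversion")
  # delins with >1 nt on both sides is unsupported; single-anchor is fine
  v <- validate_supported_variant(parse_cdna_description("c.100_102delinsAT"))
  expect_identical(v$reason, "delins_both_sides_gt1")
  expect_true(validate_supported_variant(
    parse_cdna_description("c.100delinsAT"))$accepted)
  expect_true(validate_supported_variant(
    parse_cdna_description("c.100_102delinsA"))$accepted)
})

test_that("evidence bundles round-trip through JSON on canonical form", {
  sc <- make_evidence_scenario("rare_truncating")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_evidence_bundle(sc$bundle, p1)
  b1 <- load_evidence_bundle(p1)
  write_evidence_bundle(b1, p2)
  b2 <- load_evidence_bundle(p2)
  expect_identical(unclass(b2$descriptor), unclass(b1$descriptor))
  expect_equal(b2$transcript$exons, b1$transcript$exons)
  expect_identical(b2$predictions, b1$predictions)
  expect_identical(b2$flags, b1$flags)
  expect_equal(length(b2$population), length(b1$population))
  expect_identical(readLines(p1), readLines(p2))
})

test_that("missing evidence stays missing and drives not_automated calls", {
  sc <- make_evidence_scenario("missense_hotspot")
  b <- sc$bundle
  b$predictions["revel"] <- list(NULL)
  b$predictions["spliceai_dl"] <- list(NULL)
  b$predictions["spliceai_ag"] <- list(NULL)
  b$predictions["spliceai_al"] <- list(NULL)
  b$predictions["spliceai_dg"] <- list(NULL)
  calls <- evaluate_pp3_bp4(b, fx_cfg("TP53"))
  expect_identical(calls[[1]]$state, "not_automated")
  expect_identical(calls[[2]]$state, "not_automated")
  # and after a JSON round-trip the predictor is still absent, not zero
  p <- withr::local_tempfile(fileext = ".json")
  write_evidence_bundle(b, p)
  expect_null(load_evidence_bundle(p)$predictions$revel)
})

test_that("bundle validation reports every failing field path", {
  sc <- make_evidence_scenario("rare_truncating")
  p <- withr::local_tempfile(fileext = ".json")
  write_evidence_bundle(sc$bundle, p)
  j <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  j$population[[1]]$allele_count <- -5
  j$predictions$spliceai$dl <- 2.0
  j$flags$protein_consequence <- "bogus"
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(j, bad, auto_unbox = TRUE, null = "null")
  err <- tryCatch(load_evidence_bundle(bad), error = conditionMessage)
  expect_match(err, "population\\[1\\].allele_count")
  expect_match(err, "predictions.spliceai.dl")
  expect_match(err, "flags.protein_consequence")
})

test_that("gene config defaults encode the gene-specific rule variants", {
  cfgs <- fx_configs
  expect_identical(cfgs$CDH1$pm2_strength, "supporting")
  expect_identical(cfgs$GENERAL$pm2_strength, "moderate")
  expect_identical(cfgs$PTEN$pvs1_mode, "pten_override")
  expect_equal(cfgs$PTEN$pvs1_override_boundary, 1121)
  expect_identical(cfgs$CDH1$pvs1_mode, "cdh1_site_specific")
  expect_false(cfgs$CDH1$ps1_enabled)
  expect_identical(cfgs$MLH1$bp2_mode, "not_applicable")
  expect_true(cfgs$MSH6$mmr_splice_combination)
  expect_identical(cfgs$ATM$bs2_mode, "off")
  # genes without rows inherit GENERAL
  expect_identical(gene_config_for(cfgs, "PALB2")$pm2_strength, "moderate")
  expect_identical(gene_config_for(cfgs, "PALB2")$gene_symbol, "PALB2")
})

test_that("gene config overrides apply, validate and are idempotent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# test overrides", "CHEK2\tpm2_strength\tsupporting",
               "GENERAL\tbs1_af\t0.002"), f)
  cfgs <- load_gene_config(f)
  expect_identical(cfgs$CHEK2$pm2_strength, "supporting")
  expect_equal(cfgs$GENERAL$bs1_af, 0.002)
  # idempotent: the override file restated changes nothing
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(readLines(f), readLines(f)[-1]), f2)
  expect_identical(load_gene_config(f2), cfgs)
  # empty override file equals shipped defaults
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing", f3)
  expect_identical(load_gene_config(f3), load_gene_config())
  # threshold-ordering violations are configuration errors naming the gene
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("MSH2\tpp3_splice_min\t0.10", "MSH2\tbp4_splice_max\t0.15"), f4)
  expect_error(load_gene_config(f4), "MSH2.*pp3_splice_min")
  f5 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("TP53\tbs1_af\t0.9", f5)
  expect_error(load_gene_config(f5), "TP53.*ba1_af")
})
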