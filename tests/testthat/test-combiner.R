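test_that("exclusion rules drop the lower-point member of named pairs", {
  res <- apply_exclusion_rules(list(acall("PVS1", "very_strong"),
                                    acall("PP3", "supporting")))
  expect_identical(vapply(res$active, `[[`, "", "code"), "PVS1")
  expect_identical(res$dropped$code, "PP3")
  expect_identical(res$dropped$kept_code, "PVS1")

  res <- apply_exclusion_rules(list(acall("PM1", "moderate"),
                                    acall("PP3", "supporting")))
  expect_identical(vapply(res$active, `[[`, "", "code"), "PM1")
  expect_identical(res$dropped$code, "PP3")

  # no conflicting pair: identity
  calls <- list(acall("PS3", "strong"), acall("PM2", "moderate"))
  res <- apply_exclusion_rules(calls)
  expect_length(res$active, 2)
  expect_equal(nrow(res$dropped), 0)

  # tie on points keeps the earlier code in canonical order
  res <- apply_exclusion_rules(list(acall("PVS1", "supporting"),
                                    acall("PP3", "supporting")))
  expect_identical(vapply(res$active, `[[`, "", "code"), "PVS1")
})

test_that("exclusion output is conflict-free and order-independent", {
  rules <- load_exclusion_rules()
  set.seed(101)
  universe <- list(acall("PVS1", "very_strong"), acall("PM1", "moderate"),
                   acall("PP3", "supporting"), acall("PM4", "moderate"),
                   acall("PM2", "moderate"), acall("BP4", "supporting"),
                   acall("PS3", "strong"))
  for (i in 1:25) {
    sub <- universe[sample(length(universe), sample(length(universe), 1))]
    ref <- apply_exclusion_rules(sub, rules)
    codes <- sort(vapply(ref$active, `[[`, "", "code"))
    # no named pair survives
    for (j in seq_len(nrow(rules))) {
      expect_false(all(c(rules$code_a[j], rules$code_b[j]) %in% codes))
    }
    # permutation invariance
    perm <- apply_exclusion_rules(sub[sample(length(sub))], rules)
    expect_identical(sort(vapply(perm$active, `[[`, "", "code")), codes)
    expect_identical(perm$dropped[order(perm$dropped$code), ],
                     ref$dropped[order(ref$dropped$code), ],
                     ignore_attr = TRUE)
  }
})

test_that("point totals follow the 1/2/4/8 scheme with benign negation", {
  expect_equal(total_points(list(acall("PVS1", "very_strong"),
                                 acall("PS3", "strong"))), 12)
  expect_equal(total_points(list()), 0)
  expect_equal(total_points(list(acall("BS1", "strong"),
                                 acall("BP4", "supporting"))), -5)
  expect_equal(acall("PP1", "supporting")$points, 1)
  expect_equal(acall("PM2", "moderate")$points, 2)
  expect_equal(acall("PS4", "strong")$points, 4)
  expect_equal(acall("PVS1", "very_strong")$points, 8)
  expect_equal(acall("BP4", "supporting")$points, -1)
  expect_equal(acall("BS1", "strong")$points, -4)
  # non-assigned calls carry no points, standalone is BA1-only
  expect_equal(criterion_call("PP3", "denied")$points, 0)
  expect_error(criterion_call("PS1", "assigned", "standalone"), "BA1")
})

test_that("five-tier bands partition the integers and are monotone", {
  for (p in -30:30) {
    expect_identical(classify_five_tier(p), band_lookup(p), label = p)
  }
  ranks <- class_rank[vapply(-30:30, classify_five_tier, "")]
  expect_true(all(diff(ranks) >= 0))
  # printed boundaries
  expect_identical(classify_five_tier(10), "pathogenic")
  expect_identical(classify_five_tier(9), "likely_pathogenic")
  expect_identical(classify_five_tier(6), "likely_pathogenic")
  expect_identical(classify_five_tier(5), "VUS")
  expect_identical(classify_five_tier(0), "VUS")
  expect_identical(classify_five_tier(-1), "likely_benign")
  expect_identical(classify_five_tier(-5), "likely_benign")
  expect_identical(classify_five_tier(-6), "benign")
  # BA1 short-circuit overrides the bands
  expect_identical(classify_five_tier(3, ba1_standalone = TRUE), "benign")
})

test_that("combiner equals brute-force enumeration over 4096 subsets", {
  universe <- data.frame(
    code = c("PVS1", "PS1", "PS3", "PM1", "PM2", "PM5", "PP1", "PP3",
             "BS1", "BS3", "BP4", "BP7"),
    strength = c("very_strong", "strong", "strong", "moderate", "moderate",
                 "moderate", "supporting", "supporting", "strong", "strong",
                 "supporting", "supporting"),
    stringsAsFactors = FALSE)
  oracle <- combination_oracle(universe)
  expect_equal(nrow(oracle), 4096)
  no_rules <- data.frame(code_a = character(), code_b = character(),
                         rationale = character())
  items <- lapply(seq_len(nrow(universe)), function(i) {
    acall(universe$code[i], universe$strength[i])
  })
  for (mask in oracle$subset_id) {
    sel <- items[bitwAnd(mask, bitwShiftL(1, seq_len(12) - 1)) != 0]
    act <- apply_exclusion_rules(sel, no_rules)$active
    pts <- total_points(act)
    row <- oracle[oracle$subset_id == mask, ]
    expect_identical(pts, row$points)
    expect_identical(classify_five_tier(pts), row$class)
  }
})

test_that("classification is monotone in added evidence without exclusions", {
  no_rules <- data.frame(code_a = character(), code_b = character(),
                         rationale = character())
  path_codes <- criterion_codes()$pathogenic
  ben_codes <- setdiff(criterion_codes()$benign, "BA1")
  strengths <- c("supporting", "moderate", "strong", "very_strong")
  set.seed(2024)
  for (i in 1:300) {
    n <- sample(0:6, 1)
    codes <- sample(c(path_codes, ben_codes), n)
    calls <- lapply(codes, function(cd) acall(cd, sample(strengths, 1)))
    base_class <- classify_five_tier(
      total_points(apply_exclusion_rules(calls, no_rules)$active))
    extra_p <- acall(sample(setdiff(path_codes, codes), 1),
                     sample(strengths, 1))
    with_p <- classify_five_tier(
      total_points(apply_exclusion_rules(c(calls, list(extra_p)),
                                         no_rules)$active))
    expect_gte(class_rank[with_p], class_rank[base_class])
    extra_b <- acall(sample(setdiff(ben_codes, codes), 1),
                     sample(strengths, 1))
    with_b <- classify_five_tier(
      total_points(apply_exclusion_rules(c(calls, list(extra_b)),
                                         no_rules)$active))
    expect_lte(class_rank[with_b], class_rank[base_class])
  }
})

test_that("the orchestrator reproduces hand-summed fixture results", {
  sc <- make_evidence_scenario("rare_truncating")
  cfg <- scenario_config(sc, fx_configs)
  res <- combine_criteria(sc$bundle, cfg)
  expect_identical(res$dropped$code, "PP3")
  expect_identical(res$dropped$kept_code, "PVS1")
  expect_equal(res$total_points, 9)
  expect_identical(res$classification, "likely_pathogenic")
  # adding a strong functional assay lifts it to pathogenic (8 + 1 + 4 = 13)
  b <- sc$bundle
  b$functional <- list(functional_assay_record("PALB2", "c.300C>T",
                                               "SYNTH-X", "abnormal",
                                               "strong"))
  res2 <- combine_criteria(b, cfg)
  expect_equal(res2$total_points, 13)
  expect_identical(res2$classification, "pathogenic")
  # BA1 standalone short-circuits to benign
  ben <- make_evidence_scenario("benign_common")
  res3 <- combine_criteria(ben$bundle, scenario_config(ben, fx_configs))
  expect_true(res3$ba1_standalone)
  expect_identical(res3$classification, "benign")
  # every call is reported, assigned or not
  expect_setequal(
    vapply(res3$calls, `[[`, "", "code"),
    c("BA1", "BS1", "PM2", "BS2", "PVS1", "PP3", "BP4", "BP7", "PM4", "BP3",
      "PS1", "PM5", "PS3", "BS3", "PM1", "PP2", "BP2"))
  # totals reconcile with the active set
  expect_equal(res$total_points,
               sum(vapply(res$active, `[[`, 0L, "points")))
})
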