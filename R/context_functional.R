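# PS1/PM5 from expert-panel codon context, PS3/BS3 from a curated
# functional-assay table, PM1/PP2 applicability rules, BP2, and intake of
# curator-supplied (non-automatable) criteria.

#' Construct a functional-assay record
#'
#' One row of the curated table of clinically calibrated functional assays.
#' An abnormal result maps to PS3, a normal result to BS3, and intermediate
#' results to no criterion.
#'
#' @param gene Gene symbol.
#' @param variant_key Normalised coding-DNA description (with `c.` prefix).
#' @param source_id Publication tag cited in explanations.
#' @param result `"abnormal"`, `"normal"` or `"intermediate"`.
#' @param strength Strength at which the criterion applies.
#' @param guideline_listed Logical: the source is listed in the gene-specific
#'   guidelines (outranks other sources on conflict).
#' @return A list of class `functional_assay_record` with the derived
#'   `criterion` field (`PS3`, `BS3` or `NA`).
#' @export
functional_assay_record <- function(gene, variant_key, source_id, result,
                                    strength = "strong",
                                    guideline_listed = FALSE) {
  result <- match.arg(result, c("abnormal", "normal", "intermediate"))
  criterion <- switch(result, abnormal = "PS3", normal = "BS3",
                      intermediate = NA_character_)
  structure(list(gene = gene, variant_key = variant_key,
                 source_id = source_id, result = result,
                 criterion = criterion,
                 strength = match.arg(strength, .strength_levels),
                 guideline_listed = isTRUE(guideline_listed)),
            class = "functional_assay_record")
}

#' Load the packaged curated functional-assay table
#'
#' @param path Optional path to a curator-extended table (same tab-delimited
#'   layout as the packaged one); `NULL` loads the packaged table.
#' @return List of [functional_assay_record()]s.
#' @export
load_functional_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_assays.tsv",
                        package = "hcvarclass", mustWork = TRUE)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    functional_assay_record(df$gene[i], df$variant_key[i], df$source_id[i],
                            df$result[i], df$strength[i],
                            guideline_listed = isTRUE(df$guideline_listed[i]))
  })
}

.pc_equal <- function(a, b) {
  identical(a$ref_aa, b$ref_aa) && identical(a$codon, b$codon) &&
    identical(a$alt_aa, b$alt_aa)
}

#' Evaluate PS1 and PM5 (codon-context criteria)
#'
#' Classic mode (`cfg$pm5_mode = "classic_codon"`): PS1 is assigned when an
#' expert-panel pathogenic context entry has the identical protein change via
#' a different nucleotide change (and PS1 is enabled for the gene); PM5 when
#' an expert-panel pathogenic entry affects the same codon with a different
#' amino-acid substitution, the test variant is missense, and PS1 was not
#' assigned. Only expert-panel-reviewed entries are consulted (relaxable via
#' `cfg$expert_panel_only`).
#'
#' CDH1 truncating mode (`cfg$pm5_mode = "cdh1_truncating"`): PS1 is not
#' applicable; PM5 applies to nonsense/frameshift variants predicted (50-nt
#' rule) or proven (RNA evidence flag) to undergo NMD, and to canonical
#' splice variants explicitly marked eligible in the bundle.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @return List of two [criterion_call()]s (PS1, PM5).
#' @export
evaluate_ps1_pm5 <- function(bundle, cfg) {
  if (cfg$pm5_mode == "cdh1_truncating") {
    cons <- bundle$flags$protein_consequence
    ps1 <- criterion_call("PS1", "not_applicable",
      explanation = "PS1 no longer applies under this gene's guidelines")
    if (cons %in% c("nonsense", "frameshift")) {
      nmd <- isTRUE(bundle$flags$nmd_proven) ||
        (bundle$descriptor$intron_offset_start == 0L &&
         predict_nmd(bundle$descriptor, bundle$transcript))
      pm5 <- if (nmd) {
        criterion_call("PM5", "assigned", "moderate",
          explanation = sprintf("%s variant %s to undergo NMD", cons,
                                if (isTRUE(bundle$flags$nmd_proven))
                                  "proven" else "predicted"))
      } else {
        criterion_call("PM5", "denied",
          explanation = "truncating variant not predicted or proven to undergo NMD")
      }
    } else if (bundle$flags$is_canonical_splice) {
      pm5 <- if (isTRUE(bundle$flags$cdh1_pm5_splice_eligible)) {
        criterion_call("PM5", "assigned", "moderate",
          explanation = "canonical splice variant marked eligible under the truncating PM5 rule")
      } else {
        criterion_call("PM5", "denied",
          explanation = "canonical splice variant not marked eligible under the truncating PM5 rule")
      }
    } else {
      pm5 <- criterion_call("PM5", "denied",
        explanation = "consequence outside the truncating PM5 rule")
    }
    return(list(ps1, pm5))
  }
  if (cfg$pm5_mode == "off") {
    return(list(
      criterion_call("PS1", "not_applicable",
                     explanation = "PS1/PM5 disabled for this gene"),
      criterion_call("PM5", "not_applicable",
                     explanation = "PS1/PM5 disabled for this gene")))
  }

  ctx <- bundle$codon_context
  if (is.null(ctx)) {
    why <- "no codon-context entries retrieved"
    return(list(criterion_call("PS1", "not_automated", explanation = why),
                criterion_call("PM5", "not_automated", explanation = why)))
  }
  pc <- bundle$protein_change
  if (is.null(pc)) {
    why <- "test variant protein change unknown"
    return(list(criterion_call("PS1", "not_automated", explanation = why),
                criterion_call("PM5", "not_automated", explanation = why)))
  }
  usable <- Filter(function(e) {
    (!cfg$expert_panel_only || isTRUE(e$expert_panel_reviewed)) &&
      identical(e$classification, "P") && !is.null(e$protein_change)
  }, ctx)

  same_protein <- Filter(function(e) {
    .pc_equal(e$protein_change, pc) && !identical(e$cdna, bundle$descriptor$cdna)
  }, usable)
  ps1_hit <- cfg$ps1_enabled && length(same_protein) > 0
  ps1 <- if (!cfg$ps1_enabled) {
    criterion_call("PS1", "not_applicable",
                   explanation = "PS1 disabled for this gene")
  } else if (ps1_hit) {
    criterion_call("PS1", "assigned", "strong",
      explanation = sprintf(
        "expert-panel pathogenic variant %s causes the same protein change via a different nucleotide change",
        same_protein[[1]]$cdna))
  } else {
    criterion_call("PS1", "denied",
      explanation = "no expert-panel pathogenic entry with the identical protein change")
  }

  same_codon <- Filter(function(e) {
    identical(e$protein_change$codon, pc$codon) &&
      !identical(e$protein_change$alt_aa, pc$alt_aa)
  }, usable)
  pm5 <- if (ps1_hit) {
    criterion_call("PM5", "denied",
      explanation = "PS1 assigned; PM5 not combined with PS1")
  } else if (!bundle$flags$is_missense) {
    criterion_call("PM5", "denied",
      explanation = "PM5 (classic) applies to missense variants only")
  } else if (length(same_codon) > 0) {
    criterion_call("PM5", "assigned", "moderate",
      explanation = sprintf(
        "expert-panel pathogenic variant %s affects the same codon (%d) with a different substitution",
        same_codon[[1]]$cdna, pc$codon))
  } else {
    criterion_call("PM5", "denied",
      explanation = "no expert-panel pathogenic entry at the same codon")
  }
  list(ps1, pm5)
}

#' Evaluate PS3 and BS3 (functional assays)
#'
#' Looks the variant up in the curated assay table by gene and normalised
#' cDNA key. Genes without curated literature coverage (per configuration)
#' return `not_automated`; an absent table entry also returns
#' `not_automated`, never a denial (absence of an assay is not evidence).
#' Conflicting records (same variant, opposing criteria) are resolved in
#' favour of guideline-listed sources; unresolved conflicts suppress both
#' calls with a warning.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @param assay_table List of [functional_assay_record()]s; defaults to the
#'   packaged table merged with any records carried in the bundle.
#' @return List of two [criterion_call()]s (PS3, BS3).
#' @export
evaluate_functional <- function(bundle, cfg, assay_table = NULL) {
  gene <- bundle$descriptor$gene_symbol
  if (is.null(assay_table)) assay_table <- load_functional_table()
  if (!is.null(bundle$functional)) {
    assay_table <- c(assay_table, bundle$functional)
  }
  not_auto <- function(code, why) criterion_call(code, "not_automated",
                                                 explanation = why)
  if (!cfg$ps3_bs3_covered) {
    why <- "no curated functional-assay literature is used for this gene"
    return(list(not_auto("PS3", why), not_auto("BS3", why)))
  }
  key <- bundle$descriptor$cdna
  hits <- Filter(function(r) {
    identical(r$gene, gene) && identical(r$variant_key, key) &&
      !is.na(r$criterion)
  }, assay_table)
  if (!cfg$bs3_covered) {
    hits <- Filter(function(r) r$criterion != "BS3", hits)
  }
  bs3_blocked <- if (!cfg$bs3_covered) {
    not_auto("BS3", "no curated benign functional-assay literature for this gene")
  } else NULL

  if (length(hits) == 0) {
    res <- list(not_auto("PS3", "no curated assay record for this variant"),
                bs3_blocked %||%
                  not_auto("BS3", "no curated assay record for this variant"))
    return(res)
  }
  crits <- unique(vapply(hits, `[[`, "", "criterion"))
  if (length(crits) > 1) {
    listed <- Filter(function(r) r$guideline_listed, hits)
    listed_crits <- unique(vapply(listed, `[[`, "", "criterion"))
    if (length(listed_crits) == 1) {
      hits <- listed
      crits <- listed_crits
    } else {
      warn <- sprintf(
        "conflicting functional-assay records for %s (%s): no call made",
        key, paste(vapply(hits, `[[`, "", "source_id"), collapse = ", "))
      return(list(
        criterion_call("PS3", "warning", explanation = warn, warnings = warn),
        bs3_blocked %||%
          criterion_call("BS3", "warning", explanation = warn,
                         warnings = warn)))
    }
  }
  rec <- hits[[1]]
  expl <- sprintf("calibrated assay (%s): %s result", rec$source_id, rec$result)
  if (crits == "PS3") {
    list(criterion_call("PS3", "assigned", rec$strength, explanation = expl),
         bs3_blocked %||%
           criterion_call("BS3", "denied",
                          explanation = "assay result supports abnormal function"))
  } else {
    list(criterion_call("PS3", "denied",
                        explanation = "assay result supports normal function"),
         criterion_call("BS3", "assigned", rec$strength, explanation = expl))
  }
}

#' Evaluate PM1 and PP2 (mutational hotspots and missense constraint)
#'
#' PM1 is not applicable for genes whose guidelines exclude it; otherwise it
#' is assigned when the variant lies in an annotated hotspot/functional
#' domain and its consequence is missense or a small in-frame indel. PP2
#' applies only where enabled (PTEN) and only to missense variants.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @return List of two [criterion_call()]s (PM1, PP2).
#' @export
evaluate_pm1_pp2 <- function(bundle, cfg) {
  cons <- bundle$flags$protein_consequence
  pm1 <- if (!cfg$pm1_applicable) {
    criterion_call("PM1", "not_applicable",
      explanation = "PM1 does not apply under this gene's guidelines")
  } else if (!(cons %in% c("missense", "inframe_indel"))) {
    criterion_call("PM1", "denied",
      explanation = "PM1 applies only to missense variants and small in-frame indels")
  } else if (isTRUE(bundle$flags$in_pm1_region)) {
    criterion_call("PM1", "assigned", "moderate",
      explanation = "variant lies in an annotated mutational hotspot / functional domain")
  } else {
    criterion_call("PM1", "denied",
      explanation = "variant is outside annotated hotspot / functional domains")
  }
  pp2 <- if (!cfg$pp2_enabled) {
    criterion_call("PP2", "not_applicable",
      explanation = "PP2 is not used for this gene")
  } else if (cons == "missense") {
    criterion_call("PP2", "assigned", "supporting",
      explanation = "missense variant in a gene where missense is a common disease mechanism")
  } else {
    criterion_call("PP2", "denied",
      explanation = "PP2 applies only to missense variants")
  }
  list(pm1, pp2)
}

#' Evaluate BP2 (observed in homozygosity)
#'
#' Mode `not_applicable` (mismatch-repair genes) returns not applicable;
#' mode `homozygote_supporting` (CDH1) assigns supporting strength when the
#' variant is seen in homozygosity in the non-cancer dataset and otherwise
#' returns `not_automated` (no public resource distinguishes healthy
#' individuals); mode `off` returns `not_automated`.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @return A [criterion_call()] for BP2.
#' @export
evaluate_bp2 <- function(bundle, cfg) {
  switch(cfg$bp2_mode,
    not_applicable = criterion_call("BP2", "not_applicable",
      explanation = "BP2 does not apply under this gene's guidelines"),
    off = criterion_call("BP2", "not_automated",
      explanation = "BP2 requires allelic data not available in public databases"),
    homozygote_supporting = {
      hz <- bundle$homozygote_count_noncancer
      if (!is.null(hz) && hz >= 1L) {
        criterion_call("BP2", "assigned", "supporting",
          explanation = sprintf(
            "observed in homozygosity in the non-cancer dataset (%d homozygotes); supporting strength only",
            hz))
      } else {
        criterion_call("BP2", "not_automated",
          explanation = "no homozygous observations; BP2 requires manual review")
      }
    })
}

#' Ingest curator-supplied manual criteria
#'
#' Criteria that cannot be automated (segregation, de novo, phenotype,
#' allelic and case-control data: PP1, BS4, PS2, PM6, PP4, BP5, PM3, PS4,
#' ...) may be supplied by the curator with a strength; they are merged
#' downstream exactly like automated calls but flagged `source = "manual"`.
#' The retired PP5/BP6 codes are rejected.
#'
#' @param manual List of `list(code=, strength=)` pairs.
#' @return List of [criterion_call()]s with `source = "manual"`.
#' @export
ingest_manual_criteria <- function(manual) {
  lapply(manual, function(m) {
    if (m$code %in% .retired_codes) {
      stop("criterion ", m$code, " was retired by ClinGen (reputable-source ",
           "assertions without access to primary evidence) and cannot be ",
           "supplied", call. = FALSE)
    }
    criterion_call(m$code, "assigned", m$strength,
                   explanation = "curator-supplied criterion",
                   source = "manual")
  })
}
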