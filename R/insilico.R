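# In silico prediction criteria: PP3/BP4 (splice and protein arms), BP7
# (synonymous/deep-intronic with no predicted splice impact and, where
# required, no strong nucleotide conservation), and PM4/BP3 (protein-length
# changes in or out of repeat regions).

.spliceai_max <- function(predictions) {
  deltas <- predictions[c("spliceai_ag", "spliceai_al",
                          "spliceai_dg", "spliceai_dl")]
  have <- !vapply(deltas, is.null, TRUE)
  if (!any(have)) return(NULL)
  max(unlist(deltas[have]))
}

#' Evaluate PP3 and BP4 (in silico predictions)
#'
#' Two evidence arms are scored at fixed supporting strength:
#'
#' * splice arm: `s = max` of the four SpliceAI delta scores; pathogenic when
#'   `s >= cfg$pp3_splice_min` (default 0.5), benign when
#'   `s <= cfg$bp4_splice_max` (default 0.15), indeterminate in the gap.
#'   For mismatch-repair genes with `cfg$mmr_splice_combination`, a
#'   pathogenic splice call additionally requires the MMR splice prior to
#'   reach `cfg$mmr_prior_min`; predictor disagreement yields no call.
#' * protein arm (missense only): REVEL `>= cfg$pp3_protein_min` pathogenic,
#'   `<= cfg$bp4_protein_max` benign.
#'
#' PP3 is assigned if either arm supports pathogenicity; BP4 only if every
#' evaluable arm supports benignity. The two are mutually exclusive by
#' construction. With no evaluable predictor both are `not_automated`.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @return List of two [criterion_call()]s (PP3, BP4).
#' @export
evaluate_pp3_bp4 <- function(bundle, cfg) {
  preds <- bundle$predictions
  s <- .spliceai_max(preds)
  revel <- preds$revel
  missense <- bundle$flags$is_missense

  splice_notes <- character()
  splice_vote <- NA_character_  # "pathogenic"/"benign"/"neutral"/NA (unevaluable)
  splice_unconfirmed <- FALSE
  if (!is.null(s)) {
    if (s >= cfg$pp3_splice_min) {
      if (cfg$mmr_splice_combination) {
        prior <- preds$mmr_prior
        if (is.null(prior)) {
          splice_unconfirmed <- TRUE
          splice_notes <- c(splice_notes, sprintf(
            "SpliceAI max delta %.3g >= %.3g but the combined MMR splice prior is missing; pathogenic splice call cannot be confirmed",
            s, cfg$pp3_splice_min))
        } else if (prior >= cfg$mmr_prior_min) {
          splice_vote <- "pathogenic"
          splice_notes <- c(splice_notes, sprintf(
            "SpliceAI max delta %.3g >= %.3g and MMR prior %.3g >= %.3g",
            s, cfg$pp3_splice_min, prior, cfg$mmr_prior_min))
        } else {
          splice_vote <- "neutral"
          splice_notes <- c(splice_notes, sprintf(
            "predictors disagree: SpliceAI max delta %.3g >= %.3g but MMR prior %.3g < %.3g; no splice call",
            s, cfg$pp3_splice_min, prior, cfg$mmr_prior_min))
        }
      } else {
        splice_vote <- "pathogenic"
        splice_notes <- c(splice_notes, sprintf(
          "SpliceAI max delta %.3g >= PP3 cut-off %.3g", s, cfg$pp3_splice_min))
      }
    } else if (s <= cfg$bp4_splice_max) {
      splice_vote <- "benign"
      splice_notes <- c(splice_notes, sprintf(
        "SpliceAI max delta %.3g <= BP4 cut-off %.3g", s, cfg$bp4_splice_max))
    } else {
      splice_vote <- "neutral"
      splice_notes <- c(splice_notes, sprintf(
        "SpliceAI max delta %.3g in the indeterminate gap (%.3g, %.3g)",
        s, cfg$bp4_splice_max, cfg$pp3_splice_min))
    }
  }

  protein_notes <- character()
  protein_vote <- NA_character_
  if (missense && !is.null(revel)) {
    if (revel >= cfg$pp3_protein_min) {
      protein_vote <- "pathogenic"
      protein_notes <- sprintf("REVEL %.3g >= PP3 cut-off %.3g",
                               revel, cfg$pp3_protein_min)
    } else if (revel <= cfg$bp4_protein_max) {
      protein_vote <- "benign"
      protein_notes <- sprintf("REVEL %.3g <= BP4 cut-off %.3g",
                               revel, cfg$bp4_protein_max)
    } else {
      protein_vote <- "neutral"
      protein_notes <- sprintf("REVEL %.3g in the indeterminate gap (%.3g, %.3g)",
                               revel, cfg$bp4_protein_max, cfg$pp3_protein_min)
    }
  }

  votes <- c(splice = splice_vote, protein = protein_vote)
  evaluable <- !is.na(votes)
  notes <- paste(c(splice_notes, protein_notes), collapse = "; ")
  if (!any(evaluable) && !splice_unconfirmed) {
    why <- "no evaluable predictor scores supplied"
    return(list(criterion_call("PP3", "not_automated", explanation = why),
                criterion_call("BP4", "not_automated", explanation = why)))
  }

  pp3_yes <- any(votes[evaluable] == "pathogenic")
  bp4_yes <- !pp3_yes && !splice_unconfirmed && any(evaluable) &&
    all(votes[evaluable] == "benign")

  pp3 <- if (pp3_yes) {
    criterion_call("PP3", "assigned", "supporting", explanation = notes)
  } else if (splice_unconfirmed && !any(votes[evaluable] == "pathogenic")) {
    criterion_call("PP3", "not_automated", explanation = notes)
  } else {
    criterion_call("PP3", "denied", explanation = notes)
  }
  bp4 <- if (bp4_yes) {
    criterion_call("BP4", "assigned", "supporting", explanation = notes)
  } else if (!any(evaluable)) {
    criterion_call("BP4", "not_automated", explanation = notes)
  } else {
    criterion_call("BP4", "denied", explanation = notes)
  }
  list(pp3, bp4)
}

#' Evaluate BP7 (synonymous / deep intronic with no predicted impact)
#'
#' Applicable only to synonymous variants and intronic variants beyond the
#' canonical splice positions. Requires the benign splice prediction (the
#' BP4 splice condition) and, when the gene configuration demands
#' non-conservation, a PhastCons score strictly below
#' `cfg$conservation_max_phastcons` (so a fully conserved nucleotide,
#' PhastCons = 1, blocks BP7 at the default cut-off of 1).
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @param bp4_splice Logical: was the benign splice condition met? (Passed in
#'   by the orchestrator from [evaluate_pp3_bp4()]'s splice arm.)
#' @return A [criterion_call()] for BP7.
#' @export
evaluate_bp7 <- function(bundle, cfg, bp4_splice) {
  cons <- bundle$flags$protein_consequence
  eligible <- (cons %in% c("synonymous", "intronic")) &&
    !bundle$flags$is_canonical_splice
  if (!eligible) {
    return(criterion_call("BP7", "not_applicable",
      explanation = "BP7 applies only to synonymous or non-canonical intronic variants"))
  }
  if (!isTRUE(bp4_splice)) {
    return(criterion_call("BP7", "denied",
      explanation = "benign splice prediction (BP4 splice condition) not met"))
  }
  if (cfg$bp7_requires_nonconserved) {
    ph <- bundle$predictions$phastcons
    if (is.null(ph)) {
      return(criterion_call("BP7", "not_automated",
        explanation = "nucleotide conservation required but PhastCons score missing"))
    }
    if (ph >= cfg$conservation_max_phastcons) {
      return(criterion_call("BP7", "denied",
        explanation = sprintf(
          "nucleotide predicted strongly conserved (PhastCons %.3g >= %.3g)",
          ph, cfg$conservation_max_phastcons)))
    }
  }
  criterion_call("BP7", "assigned", "supporting",
    explanation = "no predicted splice impact and conservation condition satisfied")
}

#' Evaluate PM4 and BP3 (protein-length changes)
#'
#' PM4: in-frame insertion/deletion or stop-loss outside a repeat region.
#' BP3: in-frame insertion/deletion inside a repeat region. Mutually
#' exclusive; both not applicable for other consequences.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @return List of two [criterion_call()]s (PM4, BP3).
#' @export
evaluate_pm4_bp3 <- function(bundle, cfg) {
  cons <- bundle$flags$protein_consequence
  in_repeat <- isTRUE(bundle$flags$in_repeat_region)
  if (!(cons %in% c("inframe_indel", "stoploss"))) {
    why <- sprintf("consequence '%s' does not change protein length in frame",
                   cons)
    return(list(criterion_call("PM4", "not_applicable", explanation = why),
                criterion_call("BP3", "not_applicable", explanation = why)))
  }
  if (cons == "inframe_indel" && in_repeat) {
    list(criterion_call("PM4", "denied",
           explanation = "in-frame indel lies in a repeat region (BP3 applies)"),
         criterion_call("BP3", "assigned", "supporting",
           explanation = "in-frame indel in a repetitive region without known function"))
  } else {
    list(criterion_call("PM4", "assigned", "moderate",
           explanation = sprintf("%s outside repeat regions changes protein length",
                                 cons)),
         criterion_call("BP3", "denied",
           explanation = "not in a repeat region"))
  }
}
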