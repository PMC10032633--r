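# Loss-of-function (PVS1) criterion: a decision tree over variant consequence,
# predicted nonsense-mediated decay, exon relevance and the fraction of
# protein removed, with splice-prediction integration for canonical +-1/+-2
# splice variants. Gene modes: the general tree; a PTEN override forcing very
# strong for truncating variants 5' of the configured boundary; and a CDH1
# site-specific mode consulting a packaged per-site splice strength table.

.nmd_escape_window <- 50L  # nt upstream of the last junction escaping NMD

.predict_nmd_at <- function(ptc_cdna, t) {
  if (t$single_exon) return(FALSE)
  ptc_cdna < (t$last_junction_cdna - .nmd_escape_window)
}

#' Predict nonsense-mediated decay for a premature termination codon
#'
#' Applies the 50-nt rule: a transcript is predicted to undergo NMD when the
#' premature termination codon lies more than 50 nt upstream of the 3'-most
#' exon-exon junction. Single-exon transcripts escape NMD.
#'
#' @param d A `variant_descriptor` introducing a premature termination codon
#'   (nonsense or frameshift); purely intronic descriptors are a domain error.
#' @param t A `transcript_model`.
#' @return Logical: `TRUE` if NMD is predicted.
#' @export
predict_nmd <- function(d, t) {
  stopifnot(inherits(d, "variant_descriptor"), inherits(t, "transcript_model"))
  if (d$intron_offset_start != 0L) {
    stop("cannot locate a termination codon for a purely intronic variant",
         call. = FALSE)
  }
  .predict_nmd_at(d$cdna_start, t)
}

.cdh1_splice_table <- function() {
  path <- system.file("extdata", "cdh1_splice_sites.tsv",
                      package = "hcvarclass", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

.site_key <- function(d) {
  .format_position(d$cdna_start, d$intron_offset_start, d$utr3_start)
}

# Truncating-variant branch of the tree (shared by the direct nonsense/
# frameshift path and the frameshift-inducing splice path).
.truncating_strength <- function(ptc, t, cfg, path) {
  nmd <- .predict_nmd_at(ptc, t)
  rel_end <- t$relevant_region_end
  if (nmd) {
    path <- c(path, "nmd_predicted")
    if (is.null(rel_end) || ptc <= rel_end) {
      return(list(strength = "very_strong",
                  path = c(path, "in_relevant_region"), warnings = character()))
    }
    path <- c(path, "outside_relevant_region")
  } else {
    path <- c(path, "nmd_escape")
  }
  # NMD escape (or PTC beyond the annotated relevant region): strength from
  # removed-region relevance, else from the fraction of protein lost
  if (!is.null(rel_end) && ptc <= rel_end) {
    return(list(strength = "strong", path = c(path, "removed_region_relevant"),
                warnings = character()))
  }
  if (is.na(t$protein_length)) {
    return(list(strength = "moderate",
                path = c(path, "protein_fraction_unknown"),
                warnings = "protein length unknown; conservative moderate strength"))
  }
  aa <- ceiling(ptc / 3)
  frac <- (t$protein_length - aa) / t$protein_length
  if (frac > cfg$protein_loss_fraction) {
    list(strength = "strong",
         path = c(path, sprintf("protein_loss_%.0f%%", 100 * frac)),
         warnings = character())
  } else {
    list(strength = "moderate",
         path = c(path, sprintf("protein_loss_%.0f%%", 100 * frac)),
         warnings = character())
  }
}

# Exon flanking a canonical +-1/+-2 splice position.
.splice_exon <- function(d, t) {
  base <- d$cdna_start
  if (d$intron_offset_start > 0) exon_index_of(t, base)       # donor side
  else if (d$intron_offset_start < 0) exon_index_of(t, base)  # acceptor side
  else exon_index_of(t, base)
}

#' Evaluate the PVS1 loss-of-function criterion
#'
#' Implements the strength-assignment decision tree for loss-of-function
#' variants. Nonsense/frameshift variants predicted to undergo NMD in the
#' biologically relevant region receive very strong strength; NMD-escaping
#' truncations are weighed by removed-region relevance and the fraction of
#' protein lost (> the configured fraction, default 10%, gives strong, else
#' moderate). Canonical splice variants follow the splice arm: a predicted
#' splice-site *gain* is conservatively given supporting strength with a
#' warning suggesting an RNA assay; predicted exon skipping at the first or
#' last exon gives no strength but a warning; otherwise skipping is analysed
#' as in-frame (region relevance / fraction removed) or frameshift (NMD
#' logic). Start-loss variants take the moderate branch.
#'
#' Gene modes (`cfg$pvs1_mode`): `pten_override` forces very strong for
#' truncating variants starting 5' of `cfg$pvs1_override_boundary`
#' (c.1121 for PTEN); `cdh1_site_specific` consults the packaged per-site
#' splice strength table (e.g. c.1137+1 is capped at strong) before falling
#' back to the general tree.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @return A [criterion_call()] for PVS1; its `warnings` field carries the
#'   RNA-assay / first-last-exon messages and an attribute-free `path` of
#'   decision nodes is embedded in the explanation.
#' @export
evaluate_pvs1 <- function(bundle, cfg) {
  d <- bundle$descriptor
  t <- bundle$transcript
  cons <- bundle$flags$protein_consequence
  lof_like <- cons %in% c("nonsense", "frameshift", "startloss") ||
    bundle$flags$is_canonical_splice
  if (!lof_like) {
    return(criterion_call("PVS1", "not_applicable",
      explanation = sprintf("consequence '%s' is not loss-of-function", cons)))
  }

  finish <- function(res, mode_note = NULL) {
    expl <- paste0("decision path: ",
                   paste(c(mode_note, res$path), collapse = " > "))
    if (res$strength == "none") {
      criterion_call("PVS1", "warning", explanation = expl,
                     warnings = res$warnings)
    } else {
      criterion_call("PVS1", "assigned", res$strength, explanation = expl,
                     warnings = res$warnings)
    }
  }

  truncating <- cons %in% c("nonsense", "frameshift")

  # PTEN-style override: truncations 5' of the boundary are very strong
  if (cfg$pvs1_mode == "pten_override" && truncating &&
      !is.na(cfg$pvs1_override_boundary) &&
      d$intron_offset_start == 0L &&
      d$cdna_start < cfg$pvs1_override_boundary) {
    return(finish(list(strength = "very_strong",
                       path = sprintf("truncating_5prime_of_c%d",
                                      as.integer(cfg$pvs1_override_boundary)),
                       warnings = character()),
                  mode_note = "gene_override"))
  }

  # CDH1-style site-specific splice table
  if (cfg$pvs1_mode == "cdh1_site_specific" && bundle$flags$is_canonical_splice) {
    tab <- .cdh1_splice_table()
    hit <- tab[tab$site == .site_key(d), , drop = FALSE]
    if (nrow(hit) == 1) {
      return(finish(list(strength = hit$strength,
                         path = sprintf("site_specific_c%s", hit$site),
                         warnings = character()),
                    mode_note = "splice_site_table"))
    }
  }

  if (truncating) {
    if (d$intron_offset_start != 0L) {
      return(criterion_call("PVS1", "not_automated",
        explanation = "termination codon position not computable (intronic start)"))
    }
    return(finish(.truncating_strength(d$cdna_start, t, cfg,
                                       path = cons)))
  }

  if (cons == "startloss") {
    return(finish(list(strength = "moderate", path = "startloss",
                       warnings = character())))
  }

  # canonical +-1/+-2 splice variant
  deltas <- bundle$predictions[c("spliceai_ag", "spliceai_al",
                                 "spliceai_dg", "spliceai_dl")]
  have <- !vapply(deltas, is.null, TRUE)
  if (!any(have)) {
    return(criterion_call("PVS1", "not_automated",
      explanation = "canonical splice variant but SpliceAI scores missing"))
  }
  vals <- unlist(deltas[have])
  argmax <- names(vals)[which.max(vals)]
  gain <- argmax %in% c("spliceai_ag", "spliceai_dg")
  if (gain) {
    return(finish(list(strength = "supporting",
                       path = c("canonical_splice", "splice_site_gain"),
                       warnings = "splice-site gain predicted: RNA assay suggested before assigning higher strength")))
  }
  exon <- .splice_exon(d, t)
  n_exons <- nrow(t$exons)
  if (!is.na(exon) && (exon == t$exons$index[1] || exon == t$exons$index[n_exons])) {
    return(finish(list(strength = "none",
                       path = c("canonical_splice", "exon_skipping",
                                "first_or_last_exon"),
                       warnings = "predicted skipping of the first or last exon: no PVS1 strength assigned; experimental follow-up required")))
  }
  ex_row <- t$exons[t$exons$index == exon, , drop = FALSE]
  ex_len <- ex_row$cdna_last - ex_row$cdna_first + 1L
  if (ex_len %% 3L == 0L) {
    # in-frame exon skip: removed-region relevance, else fraction removed
    rel_end <- t$relevant_region_end
    path <- c("canonical_splice", "exon_skipping", "in_frame")
    if (!is.null(rel_end) && ex_row$cdna_first <= rel_end) {
      return(finish(list(strength = "strong",
                         path = c(path, "removed_region_relevant"),
                         warnings = character())))
    }
    frac <- (ex_len / 3) / t$protein_length
    strength <- if (!is.na(t$protein_length) &&
                    frac > cfg$protein_loss_fraction) "strong" else "moderate"
    return(finish(list(strength = strength,
                       path = c(path, sprintf("protein_loss_%.0f%%",
                                              100 * frac)),
                       warnings = character())))
  }
  # frameshifting skip: premature stop near the start of the skipped exon
  res <- .truncating_strength(ex_row$cdna_first, t, cfg,
                              path = c("canonical_splice", "exon_skipping",
                                       "frameshift"))
  finish(res)
}
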