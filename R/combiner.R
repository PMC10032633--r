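# Criterion combination: pairwise overlap exclusions (CanVIG-UK style, to
# avoid double counting evidence), the naturally scaled point sum, and the
# five-tier classification bands.

#' Load criterion-overlap exclusion rules
#'
#' The packaged defaults are the pairs that encode the same underlying
#' evidence and must not be combined: PVS1 x PP3, PVS1 x PM1, PM1 x PP3,
#' PVS1 x PM4. Users may supply an extended tab-delimited file with columns
#' `code_a`, `code_b`, `rationale`.
#'
#' @param path Optional path to a rules file; `NULL` loads the packaged
#'   defaults.
#' @return data.frame with columns `code_a`, `code_b`, `rationale`;
#'   pairs are unordered and de-duplicated.
#' @export
load_exclusion_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "exclusion_rules.tsv",
                        package = "hcvarclass", mustWork = TRUE)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("code_a", "code_b") %in% names(df)))
  if (is.null(df$rationale)) df$rationale <- ""
  # canonicalise unordered pairs and drop duplicates
  a <- pmin(df$code_a, df$code_b)
  b <- pmax(df$code_a, df$code_b)
  keep <- !duplicated(paste(a, b))
  data.frame(code_a = a[keep], code_b = b[keep],
             rationale = df$rationale[keep], stringsAsFactors = FALSE)
}

#' Apply criterion-overlap exclusion rules
#'
#' For every rule pair with both codes assigned, the call with the lower
#' absolute point value is dropped; on a points tie the code later in
#' canonical strength-class order (PVS1 < PS < PM < PP < BA < BS < BP) is
#' dropped, keeping the stronger evidence category. Every drop is recorded
#' with the kept code and the rule's rationale. The result is conflict-free
#' and independent of the input ordering.
#'
#' @param calls List of [criterion_call()]s (any states; only assigned calls
#'   participate).
#' @param rules data.frame from [load_exclusion_rules()].
#' @return A list with `active` (assigned calls surviving exclusion) and
#'   `dropped` (data.frame: `code`, `kept_code`, `rationale`).
#' @export
apply_exclusion_rules <- function(calls, rules = load_exclusion_rules()) {
  assigned <- Filter(function(cl) cl$state == "assigned", calls)
  codes <- vapply(assigned, `[[`, "", "code")
  names(assigned) <- codes
  assigned <- assigned[order(.code_order[codes])]
  dropped <- data.frame(code = character(), kept_code = character(),
                        rationale = character(), stringsAsFactors = FALSE)
  rules <- rules[order(rules$code_a, rules$code_b), , drop = FALSE]
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(rules))) {
      a <- rules$code_a[i]; b <- rules$code_b[i]
      if (!is.null(assigned[[a]]) && !is.null(assigned[[b]])) {
        pa <- abs(assigned[[a]]$points); pb <- abs(assigned[[b]]$points)
        drop <- if (pa < pb) a
                else if (pb < pa) b
                else if (.code_order[[a]] > .code_order[[b]]) a else b
        keep <- if (identical(drop, a)) b else a
        dropped <- rbind(dropped, data.frame(
          code = drop, kept_code = keep,
          rationale = if (nzchar(rules$rationale[i])) rules$rationale[i]
                      else "overlapping evidence must not be double-counted",
          stringsAsFactors = FALSE))
        assigned[[drop]] <- NULL
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(active = unname(assigned), dropped = dropped)
}

#' Sum criterion points
#'
#' Signed sum of the points of the active (post-exclusion, assigned) calls:
#' supporting/moderate/strong/very-strong pathogenic criteria contribute
#' +1/+2/+4/+8, benign criteria the negative of the same values.
#'
#' @param active List of assigned [criterion_call()]s.
#' @return Integer total.
#' @export
total_points <- function(active) {
  stopifnot(all(vapply(active, `[[`, "", "state") == "assigned"))
  as.integer(sum(vapply(active, `[[`, 0L, "points")))
}

#' Five-tier classification from a point total
#'
#' Band lookup on the integer total: `>= 10` pathogenic, 6 to 9 likely
#' pathogenic, 0 to 5 of unknown significance, -5 to -1 likely benign,
#' `<= -6` benign. BA1 is a standalone criterion: when present the
#' classification short-circuits to benign regardless of the total.
#'
#' @param points Integer point total.
#' @param ba1_standalone Logical: was BA1 assigned?
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"VUS"`,
#'   `"likely_benign"`, `"benign"`.
#' @examples
#' classify_five_tier(10)   # pathogenic
#' classify_five_tier(9)    # likely_pathogenic
#' classify_five_tier(0)    # VUS
#' classify_five_tier(-1)   # likely_benign
#' classify_five_tier(-6)   # benign
#' @export
classify_five_tier <- function(points, ba1_standalone = FALSE) {
  if (isTRUE(ba1_standalone)) return("benign")
  stopifnot(is.numeric(points), length(points) == 1)
  if (points >= 10) "pathogenic"
  else if (points >= 6) "likely_pathogenic"
  else if (points >= 0) "VUS"
  else if (points >= -5) "likely_benign"
  else "benign"
}

#' Run every criterion module and combine the calls into a classification
#'
#' Orchestrates the full rules engine for one evidence bundle: frequency
#' criteria (BA1/BS1/PM2/BS2), the loss-of-function tree (PVS1), in silico
#' criteria (PP3/BP4/BP7/PM4/BP3), codon-context and functional criteria
#' (PS1/PM5/PS3/BS3/PM1/PP2/BP2), and curator-supplied manual criteria; then
#' applies overlap exclusions, sums points and assigns the five-tier class.
#' BA1, when assigned, short-circuits the classification to benign; the
#' remaining calls are still evaluated and reported (informationally) but
#' contribute no points.
#'
#' A manual criterion colliding with an automated assignment of the same
#' code overrides it, with a logged warning.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config` (defaults to the packaged configuration for
#'   the bundle's gene).
#' @param rules Exclusion rules (see [load_exclusion_rules()]).
#' @param assay_table Optional functional-assay table override.
#' @return An object of class `classification_result`: list with `calls`
#'   (all criterion calls), `active` (post-exclusion assigned calls),
#'   `dropped` (drop ledger), `total_points`, `classification`,
#'   `ba1_standalone`, `warnings`, `gene`, `cdna`, `transcript_id`.
#' @export
combine_criteria <- function(bundle, cfg = NULL,
                             rules = load_exclusion_rules(),
                             assay_table = NULL) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  if (is.null(cfg)) {
    cfg <- gene_config_for(load_gene_config(), bundle$descriptor$gene_symbol)
  }
  calls <- list()
  warnings <- character()

  summary <- filtered_popmax(bundle$population, cfg)
  calls <- c(calls, evaluate_frequency_criteria(summary, bundle$population, cfg))
  calls <- c(calls, list(evaluate_bs2(bundle, cfg)))
  calls <- c(calls, list(evaluate_pvs1(bundle, cfg)))
  pp3_bp4 <- evaluate_pp3_bp4(bundle, cfg)
  calls <- c(calls, pp3_bp4)
  # BP7's splice condition is BP4's splice arm: recompute it directly
  s <- .spliceai_max(bundle$predictions)
  bp4_splice <- !is.null(s) && s <= cfg$bp4_splice_max
  calls <- c(calls, list(evaluate_bp7(bundle, cfg, bp4_splice)))
  calls <- c(calls, evaluate_pm4_bp3(bundle, cfg))
  calls <- c(calls, evaluate_ps1_pm5(bundle, cfg))
  calls <- c(calls, evaluate_functional(bundle, cfg, assay_table))
  calls <- c(calls, evaluate_pm1_pp2(bundle, cfg))
  calls <- c(calls, list(evaluate_bp2(bundle, cfg)))

  manual <- ingest_manual_criteria(bundle$manual_criteria)
  if (length(manual) > 0) {
    auto_codes <- vapply(calls, `[[`, "", "code")
    for (m in manual) {
      clash <- which(auto_codes == m$code)
      if (length(clash) > 0 && calls[[clash]]$state == "assigned") {
        warnings <- c(warnings, sprintf(
          "manual %s (%s) overrides automated assignment (%s)",
          m$code, m$strength, calls[[clash]]$strength))
      }
      if (length(clash) > 0) calls[[clash]] <- m else calls <- c(calls, list(m))
    }
  }

  for (cl in calls) warnings <- c(warnings, cl$warnings)

  excl <- apply_exclusion_rules(calls, rules)
  active <- excl$active
  ba1 <- any(vapply(active, `[[`, "", "code") == "BA1")
  pts <- total_points(active)
  structure(
    list(gene = bundle$descriptor$gene_symbol,
         transcript_id = bundle$descriptor$transcript_id,
         cdna = bundle$descriptor$cdna,
         calls = calls, active = active, dropped = excl$dropped,
         total_points = pts,
         classification = classify_five_tier(pts, ba1_standalone = ba1),
         ba1_standalone = ba1,
         warnings = unique(warnings)),
    class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("%s %s %s\n", x$gene, x$transcript_id, x$cdna))
  cat(sprintf("classification: %s (%+d points%s)\n", x$classification,
              x$total_points,
              if (x$ba1_standalone) "; BA1 standalone" else ""))
  df <- calls_as_data_frame(x$calls)
  df <- df[df$state %in% c("assigned", "warning"), , drop = FALSE]
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-5s %-12s %+d  %s\n", df$code[i], df$strength[i],
                  df$points[i], df$explanation[i]))
    }
  }
  if (nrow(x$dropped) > 0) {
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  dropped %s (kept %s): %s\n", x$dropped$code[i],
                  x$dropped$kept_code[i], x$dropped$rationale[i]))
    }
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
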