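# Frequency-based criteria (BA1, BS1, PM2, BS2) from subpopulation allele
# counts. Comparisons can use the one-sided exact-binomial (Clopper-Pearson)
# lower confidence bound of the allele frequency rather than the point
# estimate, so that sparsely sampled populations do not trigger benign
# criteria on unstable frequencies. Founder (bottleneck) populations are
# excluded from BA1/BS1 popmax when configured, since drift can mask
# negative selection against pathogenic alleles.

#' One-sided Clopper-Pearson lower bound of an allele frequency
#'
#' Exact binomial lower confidence limit for the population allele frequency
#' given `allele_count` successes out of `allele_number` trials. For zero
#' observed alleles the lower bound is 0.
#'
#' @param allele_count Observed allele count (non-negative integer).
#' @param allele_number Total alleles sampled (positive integer).
#' @param confidence One-sided confidence level in (0, 1); default 0.95.
#' @return The lower confidence limit, a frequency in `[0, 1]`, always
#'   `<= allele_count / allele_number`.
#' @examples
#' af_ci_lower(0, 250000)        # 0
#' af_ci_lower(10, 10000)        # a little below 1e-3
#' @export
af_ci_lower <- function(allele_count, allele_number, confidence = 0.95) {
  stopifnot(length(allele_count) == 1, length(allele_number) == 1)
  if (allele_number <= 0) stop("allele_number must be positive", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  if (allele_count < 0 || allele_count > allele_number) {
    stop("allele_count must lie in [0, allele_number]", call. = FALSE)
  }
  if (allele_count == 0) return(0)
  stats::qbeta(1 - confidence, allele_count, allele_number - allele_count + 1)
}

#' Filtered population maximum frequency
#'
#' Among coverage-passing subpopulations (and non-founder ones when the gene
#' configuration excludes founder populations), finds the population
#' maximising the comparison statistic: the Clopper-Pearson lower bound when
#' `cfg$use_ci_lower`, the point allele frequency otherwise.
#'
#' @param records List of [population_record()]s.
#' @param cfg A `gene_config`.
#' @return A list of class `frequency_summary` with `popmax_label`,
#'   `af_point`, `af_ci_lower`, `statistic`, `used_ci`,
#'   `excluded_populations`, plus `global_ac`/`global_an` totals over the
#'   evaluable populations; or `NULL` when no population is evaluable (the
#'   frequency criteria then come back `not_automated`).
#' @export
filtered_popmax <- function(records, cfg) {
  if (is.null(records) || length(records) == 0) return(NULL)
  keep <- vapply(records, function(r) {
    r$coverage_ok && !(cfg$exclude_founder && r$founder)
  }, TRUE)
  excluded <- vapply(records[!keep], `[[`, "", "population_label")
  records <- records[keep]
  if (length(records) == 0) return(NULL)
  stat <- vapply(records, function(r) {
    if (cfg$use_ci_lower) {
      af_ci_lower(r$allele_count, r$allele_number, cfg$ci_confidence)
    } else {
      r$allele_count / r$allele_number
    }
  }, 0)
  best <- which.max(stat)
  r <- records[[best]]
  structure(
    list(popmax_label = r$population_label,
         af_point = r$allele_count / r$allele_number,
         af_ci_lower = af_ci_lower(r$allele_count, r$allele_number,
                                   cfg$ci_confidence),
         statistic = stat[best],
         used_ci = isTRUE(cfg$use_ci_lower),
         excluded_populations = as.character(excluded),
         global_ac = sum(vapply(records, `[[`, 0L, "allele_count")),
         global_an = sum(vapply(records, `[[`, 0L, "allele_number"))),
    class = "frequency_summary")
}

#' Evaluate the frequency criteria BA1, BS1 and PM2
#'
#' BA1 (standalone benign) is assigned when the popmax statistic reaches the
#' gene's `ba1_af` threshold (inclusive); otherwise BS1 when it reaches
#' `bs1_af`. PM2 (rarity) is assigned, at the configured strength, when the
#' variant is absent from every coverage-passing population or the global
#' frequency statistic is at or below `pm2_af`; PM2 is never assigned
#' together with BA1 or BS1. With no evaluable population data all three
#' criteria are `not_automated`.
#'
#' @param summary A `frequency_summary` from [filtered_popmax()] (or `NULL`).
#' @param records The full list of [population_record()]s (used for the PM2
#'   absence rule, which considers founder populations too).
#' @param cfg A `gene_config`.
#' @return List of three [criterion_call()]s (BA1, BS1, PM2).
#' @export
evaluate_frequency_criteria <- function(summary, records, cfg) {
  na <- function(code, why) criterion_call(code, "not_automated",
                                           explanation = why)
  if (is.null(summary)) {
    why <- "no evaluable population (missing data or no coverage-passing, non-excluded population)"
    return(list(na("BA1", why), na("BS1", why), na("PM2", why)))
  }
  stat_desc <- sprintf("%s statistic %.3g (popmax %s, AF %.3g)",
                       if (summary$used_ci) "CI lower-bound" else "point-AF",
                       summary$statistic, summary$popmax_label,
                       summary$af_point)
  ba1 <- summary$statistic >= cfg$ba1_af
  bs1 <- !ba1 && summary$statistic >= cfg$bs1_af

  cov_ok <- Filter(function(r) r$coverage_ok, records)
  absent <- length(cov_ok) > 0 &&
    all(vapply(cov_ok, `[[`, 0L, "allele_count") == 0L)
  global_stat <- if (cfg$use_ci_lower) {
    af_ci_lower(summary$global_ac, summary$global_an, cfg$ci_confidence)
  } else {
    summary$global_ac / summary$global_an
  }
  pm2 <- !ba1 && !bs1 && (absent || global_stat <= cfg$pm2_af)

  list(
    criterion_call("BA1",
                   if (ba1) "assigned" else "denied",
                   if (ba1) "standalone" else "none",
                   sprintf("%s %s BA1 threshold %.3g", stat_desc,
                           if (ba1) ">=" else "<", cfg$ba1_af)),
    criterion_call("BS1",
                   if (bs1) "assigned" else "denied",
                   if (bs1) "strong" else "none",
                   if (ba1) "BA1 standalone assigned; BS1 incompatible with BA1"
                   else sprintf("%s %s BS1 threshold %.3g", stat_desc,
                                if (bs1) ">=" else "<", cfg$bs1_af)),
    criterion_call("PM2",
                   if (pm2) "assigned" else "denied",
                   if (pm2) cfg$pm2_strength else "none",
                   if (ba1 || bs1) {
                     "population frequency supports benignity; PM2 incompatible"
                   } else if (absent) {
                     "variant absent from all coverage-passing populations"
                   } else {
                     sprintf("global AC %d / AN %d, statistic %.3g %s PM2 threshold %.3g",
                             summary$global_ac, summary$global_an, global_stat,
                             if (pm2) "<=" else ">", cfg$pm2_af)
                   }))
}

#' Evaluate BS2 (observed in healthy adults)
#'
#' Depending on the gene mode: not applicable (guideline excludes BS2, e.g.
#' ATM/CHEK2), not automated (no usable public resource, e.g. CDH1 and the
#' mismatch-repair genes), or assigned when the FLOSSIES observation count or
#' the non-cancer homozygote count reaches its configured threshold.
#'
#' @param bundle An `evidence_bundle`.
#' @param cfg A `gene_config`.
#' @return A [criterion_call()] for BS2.
#' @export
evaluate_bs2 <- function(bundle, cfg) {
  switch(cfg$bs2_mode,
    off = criterion_call("BS2", "not_applicable",
      explanation = "BS2 is not applicable under this gene's guidelines"),
    not_automated = criterion_call("BS2", "not_automated",
      explanation = "BS2 is not automated for this gene (no public resource)"),
    flossies_or_homozygote = {
      fl <- bundle$flossies_count
      hz <- bundle$homozygote_count_noncancer
      if (is.null(fl) && is.null(hz)) {
        return(criterion_call("BS2", "not_automated",
          explanation = "no FLOSSIES or non-cancer homozygote data supplied"))
      }
      hit_fl <- !is.null(fl) && fl >= cfg$bs2_flossies_min
      hit_hz <- !is.null(hz) && hz >= cfg$bs2_homozygote_min
      if (hit_fl || hit_hz) {
        criterion_call("BS2", "assigned", "strong",
          explanation = sprintf(
            "observed in healthy controls (FLOSSIES %s, non-cancer homozygotes %s)",
            fl %||% "NA", hz %||% "NA"))
      } else {
        criterion_call("BS2", "denied",
          explanation = sprintf(
            "insufficient healthy-control observations (FLOSSIES %s < %d and homozygotes %s < %d)",
            fl %||% "NA", cfg$bs2_flossies_min, hz %||% "NA",
            cfg$bs2_homozygote_min))
      }
    })
}
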