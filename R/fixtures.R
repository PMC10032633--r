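# Synthetic fixtures: deterministic transcripts, gene-config overrides and
# evidence-bundle scenarios exercising every criterion path, plus brute-force
# oracles for the point-combination table and the binomial CI mathematics.
# All generation is a pure function of (scenario, seed).

#' Generate a synthetic transcript model
#'
#' Splits a CDS of `cds_length` nt into `n_exons` contiguous exons with
#' reproducible pseudo-random boundaries (each exon at least 3 nt).
#'
#' @param n_exons Number of exons (>= 1).
#' @param cds_length CDS length in nt (>= 3 * n_exons).
#' @param seed Integer seed; same arguments give an identical model.
#' @param transcript_id Identifier for the model.
#' @param relevant_region_end Optional relevant-region bound.
#' @return A `transcript_model`.
#' @export
make_transcript_fixture <- function(n_exons, cds_length, seed = 1L,
                                    transcript_id = sprintf("SYNTH_%d.1", seed),
                                    relevant_region_end = NULL) {
  if (n_exons < 1 || cds_length < 3 * n_exons) {
    stop("infeasible transcript geometry: need cds_length >= 3 * n_exons",
         call. = FALSE)
  }
  set.seed(seed)
  if (n_exons == 1) {
    widths <- cds_length
  } else {
    cuts <- sort(sample(seq(3L, cds_length - 3L), n_exons - 1L))
    widths <- diff(c(0L, cuts, cds_length))
    while (any(widths < 3L)) {  # re-draw until every exon has >= 3 nt
      cuts <- sort(sample(seq(3L, cds_length - 3L), n_exons - 1L))
      widths <- diff(c(0L, cuts, cds_length))
    }
  }
  last <- cumsum(widths)
  exons <- data.frame(index = seq_len(n_exons),
                      cdna_first = c(1L, utils::head(last, -1) + 1L),
                      cdna_last = last)
  transcript_model(transcript_id, exons,
                   relevant_region_end = relevant_region_end)
}

# Fixed arithmetic transcripts used by the scenario registry (pure data).
.fx_transcript <- function(gene) {
  mk <- function(id, widths, rel = NULL) {
    last <- cumsum(widths)
    transcript_model(id, data.frame(index = seq_along(widths),
                                    cdna_first = c(1L, utils::head(last, -1) + 1L),
                                    cdna_last = last),
                     relevant_region_end = rel)
  }
  switch(gene,
    PALB2 = mk("NM_SYNTH_PALB2.1", rep(210L, 10)),            # CDS 2100
    PALB2_SHORTFIRST = mk("NM_SYNTH_PALB2b.1", c(300L, 1800L)),
    PTEN = mk("NM_SYNTH_PTEN.1", c(rep(135L, 8), 132L)),      # CDS 1212
    CDH1 = mk("NM_SYNTH_CDH1.1",
              c(rep(200L, 5), 137L, 263L, rep(200L, 5), 249L)),  # CDS 2649
    TP53 = mk("NM_SYNTH_TP53.1", c(rep(118L, 9), 120L)),      # CDS 1182
    MLH1 = mk("NM_SYNTH_MLH1.1", c(rep(227L, 9), 228L)),      # CDS 2271
    ATM = mk("NM_SYNTH_ATM.1", rep(300L, 10)),                # CDS 3000
    stop("no fixture transcript for gene ", gene, call. = FALSE))
}

.fx_pop <- function(nfe_ac = 0L, nfe_an = 100000L, nfe_hom = 0L,
                    asj_ac = 0L) {
  list(population_record("nfe", nfe_ac, nfe_an, homozygote_count = nfe_hom),
       population_record("afr", 0L, 24000L),
       population_record("eas", 0L, 18000L),
       population_record("asj", asj_ac, 10000L, founder = TRUE),
       population_record("fin", 0L, 21000L, founder = TRUE))
}

.fx_preds <- function(revel = NULL, sai_loss = NULL, sai_gain = NULL,
                      phastcons = NULL, mmr_prior = NULL) {
  p <- list(revel = revel, spliceai_ag = NULL, spliceai_al = NULL,
            spliceai_dg = NULL, spliceai_dl = NULL, provean = NULL,
            phastcons = phastcons, phylop = NULL, mmr_prior = mmr_prior)
  if (!is.null(sai_loss)) {
    p$spliceai_al <- 0; p$spliceai_ag <- 0; p$spliceai_dg <- 0
    p$spliceai_dl <- sai_loss
  }
  if (!is.null(sai_gain)) {
    p$spliceai_al <- p$spliceai_al %||% 0
    p$spliceai_dl <- p$spliceai_dl %||% 0
    p$spliceai_ag <- 0
    p$spliceai_dg <- sai_gain
  }
  p
}

.fx_bundle <- function(gene, cdna, consequence, transcript = NULL,
                       population = .fx_pop(), predictions = .fx_preds(),
                       ...) {
  t <- transcript %||% .fx_transcript(gene)
  d <- parse_cdna_description(cdna, gene_symbol = gene,
                              transcript_id = t$transcript_id)
  evidence_bundle(d, t, consequence, population = population,
                  predictions = predictions, ...)
}

.intended <- function(...) {
  pairs <- list(...)
  data.frame(code = vapply(pairs, `[[`, "", 1),
             strength = vapply(pairs, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

# Scenario registry: each entry is function(seed) -> list(gene, bundle,
# config_overrides, intended [post-exclusion active set], expected_class,
# expected_points). Scenario intent is declared, not inferred; the test suite
# validates the generator against the engine so drift is self-detecting.
.scenarios <- list(

  benign_common = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.412G>A", "missense",
                        population = .fx_pop(nfe_ac = 1500L)),
    intended = .intended(c("BA1", "standalone")),
    expected_class = "benign", expected_points = 0L),

  rare_truncating = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.300C>T", "nonsense",
                        population = .fx_pop(),
                        predictions = .fx_preds(sai_loss = 0.6)),
    config_overrides = list(pm2_strength = "supporting"),
    intended = .intended(c("PVS1", "very_strong"), c("PM2", "supporting")),
    expected_class = "likely_pathogenic", expected_points = 9L),

  splice_region_gain = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.420+1G>A", "intronic",
                        predictions = .fx_preds(sai_gain = 0.8),
                        flags = list(is_canonical_splice = TRUE)),
    intended = .intended(c("PVS1", "supporting"), c("PM2", "moderate")),
    expected_class = "VUS", expected_points = 3L),

  first_exon_splice = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.210+1G>A", "intronic",
                        predictions = .fx_preds(sai_loss = 0.9),
                        flags = list(is_canonical_splice = TRUE)),
    intended = .intended(c("PP3", "supporting"), c("PM2", "moderate")),
    expected_class = "VUS", expected_points = 3L),

  splice_inframe_skip = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.841-2A>G", "intronic",
                        predictions = .fx_preds(sai_loss = 0.8),
                        flags = list(is_canonical_splice = TRUE)),
    intended = .intended(c("PVS1", "strong"), c("PM2", "moderate")),
    expected_class = "likely_pathogenic", expected_points = 6L),

  nmd_escape_distal = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.1980G>T", "nonsense",
                        population = .fx_pop(nfe_ac = 30L)),
    intended = .intended(c("PVS1", "moderate")),
    expected_class = "VUS", expected_points = 2L),

  nmd_escape_strong = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.400G>T", "nonsense",
                        transcript = .fx_transcript("PALB2_SHORTFIRST"),
                        population = .fx_pop(nfe_ac = 30L)),
    intended = .intended(c("PVS1", "strong")),
    expected_class = "VUS", expected_points = 4L),

  nmd_escape_relevant = function(seed) {
    t <- .fx_transcript("PALB2")
    t$relevant_region_end <- 2000L
    list(gene = "PALB2",
         bundle = .fx_bundle("PALB2", "c.1980G>T", "nonsense", transcript = t,
                             population = .fx_pop(nfe_ac = 30L)),
         intended = .intended(c("PVS1", "strong")),
         expected_class = "VUS", expected_points = 4L)
  },

  nmd_outside_relevant = function(seed) {
    t <- .fx_transcript("PALB2")
    t$relevant_region_end <- 500L
    list(gene = "PALB2",
         bundle = .fx_bundle("PALB2", "c.600G>T", "nonsense", transcript = t,
                             population = .fx_pop(nfe_ac = 30L)),
         intended = .intended(c("PVS1", "strong")),
         expected_class = "VUS", expected_points = 4L)
  },

  startloss = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.2T>C", "startloss"),
    intended = .intended(c("PVS1", "moderate"), c("PM2", "moderate")),
    expected_class = "VUS", expected_points = 4L),

  pten_truncating = function(seed) list(
    gene = "PTEN",
    bundle = .fx_bundle("PTEN", "c.100C>T", "nonsense"),
    intended = .intended(c("PVS1", "very_strong"), c("PM2", "moderate")),
    expected_class = "pathogenic", expected_points = 10L),

  pten_missense = function(seed) list(
    gene = "PTEN",
    bundle = .fx_bundle("PTEN", "c.389G>A", "missense",
                        predictions = .fx_preds(revel = 0.85, sai_loss = 0.05),
                        flags = list(in_pm1_region = TRUE),
                        protein_change = list(ref_aa = "Arg", codon = 130,
                                              alt_aa = "Gln"),
                        flossies_count = 0L,
                        homozygote_count_noncancer = 0L),
    intended = .intended(c("PM1", "moderate"), c("PM2", "moderate"),
                         c("PP2", "supporting")),
    expected_class = "VUS", expected_points = 5L),

  missense_hotspot = function(seed) list(
    gene = "TP53",
    bundle = .fx_bundle("TP53", "c.524G>A", "missense",
                        predictions = .fx_preds(revel = 0.93, sai_loss = 0.03),
                        flags = list(in_pm1_region = TRUE),
                        protein_change = list(ref_aa = "Arg", codon = 175,
                                              alt_aa = "His"),
                        codon_context = list(),
                        flossies_count = 0L,
                        homozygote_count_noncancer = 0L),
    intended = .intended(c("PM1", "moderate"), c("PM2", "moderate"),
                         c("PS3", "strong")),
    expected_class = "likely_pathogenic", expected_points = 8L),

  functional_normal = function(seed) list(
    gene = "TP53",
    bundle = .fx_bundle("TP53", "c.215C>G", "missense",
                        population = .fx_pop(nfe_ac = 300L),
                        predictions = .fx_preds(revel = 0.1, sai_loss = 0.05),
                        protein_change = list(ref_aa = "Pro", codon = 72,
                                              alt_aa = "Arg"),
                        flossies_count = 5L,
                        homozygote_count_noncancer = 3L),
    intended = .intended(c("BS1", "strong"), c("BS2", "strong"),
                         c("BS3", "strong"), c("BP4", "supporting")),
    expected_class = "benign", expected_points = -13L),

  conflicting_assays = function(seed) list(
    gene = "ATM",
    bundle = .fx_bundle("ATM", "c.301C>T", "missense",
                        predictions = .fx_preds(revel = 0.5, sai_loss = 0.3),
                        functional = list(functional_assay_record(
                          "ATM", "c.301C>T", "SYNTH-ATM-ASSAY-3", "normal",
                          "strong"))),
    intended = .intended(c("PM2", "moderate")),
    expected_class = "VUS", expected_points = 2L),

  synonymous_conserved = function(seed) list(
    gene = "PTEN",
    bundle = .fx_bundle("PTEN", "c.741C>T", "synonymous",
                        population = .fx_pop(nfe_ac = 30L),
                        predictions = .fx_preds(sai_loss = 0.05,
                                                phastcons = 1.0),
                        flossies_count = 0L,
                        homozygote_count_noncancer = 0L),
    intended = .intended(c("BP4", "supporting")),
    expected_class = "likely_benign", expected_points = -1L),

  bp7_nonconserved = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.741C>T", "synonymous",
                        population = .fx_pop(nfe_ac = 30L),
                        predictions = .fx_preds(sai_loss = 0.05,
                                                phastcons = 0.2)),
    intended = .intended(c("BP4", "supporting"), c("BP7", "supporting")),
    expected_class = "likely_benign", expected_points = -2L),

  cdh1_synonymous_conserved = function(seed) list(
    gene = "CDH1",
    bundle = .fx_bundle("CDH1", "c.2076C>T", "synonymous",
                        population = .fx_pop(nfe_ac = 30L),
                        predictions = .fx_preds(sai_loss = 0.05,
                                                phastcons = 1.0)),
    intended = .intended(c("BP4", "supporting"), c("BP7", "supporting")),
    expected_class = "likely_benign", expected_points = -2L),

  cdh1_truncating_pm5 = function(seed) list(
    gene = "CDH1",
    bundle = .fx_bundle("CDH1", "c.283C>T", "nonsense",
                        predictions = .fx_preds(sai_loss = 0.3)),
    intended = .intended(c("PVS1", "very_strong"), c("PM2", "supporting"),
                         c("PM5", "moderate")),
    expected_class = "pathogenic", expected_points = 11L),

  splice_frameshift_skip = function(seed) list(
    gene = "CDH1",
    bundle = .fx_bundle("CDH1", "c.1001-2A>G", "intronic",
                        predictions = .fx_preds(sai_loss = 0.8),
                        flags = list(is_canonical_splice = TRUE)),
    intended = .intended(c("PVS1", "very_strong"), c("PM2", "supporting")),
    expected_class = "likely_pathogenic", expected_points = 9L),

  cdh1_splice_site = function(seed) list(
    gene = "CDH1",
    bundle = .fx_bundle("CDH1", "c.1137+1delG", "intronic",
                        predictions = .fx_preds(sai_loss = 0.9),
                        flags = list(is_canonical_splice = TRUE)),
    intended = .intended(c("PVS1", "strong"), c("PM2", "supporting")),
    expected_class = "VUS", expected_points = 5L),

  bp2_homozygote = function(seed) list(
    gene = "CDH1",
    bundle = .fx_bundle("CDH1", "c.1774G>A", "missense",
                        population = .fx_pop(nfe_ac = 300L, nfe_hom = 2L),
                        predictions = .fx_preds(revel = 0.2, sai_loss = 0.1),
                        homozygote_count_noncancer = 2L),
    intended = .intended(c("BS1", "strong"), c("BP2", "supporting"),
                         c("BP4", "supporting")),
    expected_class = "benign", expected_points = -6L),

  bs2_flossies = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.1010T>C", "missense",
                        population = .fx_pop(nfe_ac = 30L),
                        predictions = .fx_preds(revel = 0.2, sai_loss = 0.1),
                        flossies_count = 3L,
                        homozygote_count_noncancer = 0L),
    intended = .intended(c("BS2", "strong"), c("BP4", "supporting")),
    expected_class = "likely_benign", expected_points = -5L),

  mmr_splice_agree = function(seed) list(
    gene = "MLH1",
    bundle = .fx_bundle("MLH1", "c.350-15C>G", "intronic",
                        predictions = .fx_preds(sai_loss = 0.7,
                                                mmr_prior = 0.9)),
    intended = .intended(c("PP3", "supporting"), c("PM2", "moderate")),
    expected_class = "VUS", expected_points = 3L),

  mmr_splice_conflict = function(seed) list(
    gene = "MLH1",
    bundle = .fx_bundle("MLH1", "c.350-15C>G", "intronic",
                        predictions = .fx_preds(sai_loss = 0.7,
                                                mmr_prior = 0.2)),
    intended = .intended(c("PM2", "moderate")),
    expected_class = "VUS", expected_points = 2L),

  inframe_repeat = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.100_102del", "inframe_indel",
                        population = .fx_pop(nfe_ac = 30L),
                        flags = list(in_repeat_region = TRUE)),
    intended = .intended(c("BP3", "supporting")),
    expected_class = "likely_benign", expected_points = -1L),

  inframe_unique = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.100_102del", "inframe_indel"),
    intended = .intended(c("PM4", "moderate"), c("PM2", "moderate")),
    expected_class = "VUS", expected_points = 4L),

  ps1_codon = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.91A>T", "missense",
                        population = .fx_pop(nfe_ac = 30L),
                        protein_change = list(ref_aa = "Ser", codon = 31,
                                              alt_aa = "Cys"),
                        codon_context = list(list(
                          cdna = "c.91_93delinsTGT",
                          protein_change = list(ref_aa = "Ser", codon = 31,
                                                alt_aa = "Cys"),
                          classification = "P",
                          expert_panel_reviewed = TRUE,
                          nmd_predicted = NULL))),
    intended = .intended(c("PS1", "strong")),
    expected_class = "VUS", expected_points = 4L),

  pm5_codon = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.91A>T", "missense",
                        population = .fx_pop(nfe_ac = 30L),
                        protein_change = list(ref_aa = "Ser", codon = 31,
                                              alt_aa = "Cys"),
                        codon_context = list(list(
                          cdna = "c.92G>C",
                          protein_change = list(ref_aa = "Ser", codon = 31,
                                                alt_aa = "Thr"),
                          classification = "P",
                          expert_panel_reviewed = TRUE,
                          nmd_predicted = NULL))),
    intended = .intended(c("PM5", "moderate")),
    expected_class = "VUS", expected_points = 2L),

  manual_heavy = function(seed) list(
    gene = "PALB2",
    bundle = .fx_bundle("PALB2", "c.1010T>C", "missense",
                        population = .fx_pop(nfe_ac = 30L),
                        predictions = .fx_preds(revel = 0.5, sai_loss = 0.3),
                        manual_criteria = list(
                          list(code = "PP1", strength = "strong"),
                          list(code = "PS4", strength = "moderate"),
                          list(code = "PM3", strength = "supporting"))),
    intended = .intended(c("PP1", "strong"), c("PS4", "moderate"),
                         c("PM3", "supporting")),
    expected_class = "likely_pathogenic", expected_points = 7L),

  manual_full = function(seed) list(
    gene = "ATM",
    bundle = .fx_bundle("ATM", "c.1010T>C", "missense",
                        population = .fx_pop(nfe_ac = 30L),
                        manual_criteria = list(
                          list(code = "PS2", strength = "strong"),
                          list(code = "PM6", strength = "moderate"),
                          list(code = "PP4", strength = "supporting"),
                          list(code = "BP5", strength = "supporting"),
                          list(code = "BP1", strength = "supporting"),
                          list(code = "BS4", strength = "strong"))),
    intended = .intended(c("PS2", "strong"), c("PM6", "moderate"),
                         c("PP4", "supporting"), c("BP5", "supporting"),
                         c("BP1", "supporting"), c("BS4", "strong")),
    expected_class = "VUS", expected_points = 1L)
)

#' Names of the registered evidence scenarios
#' @return Character vector of scenario template names.
#' @export
scenario_names <- function() names(.scenarios)

#' Generate a registered evidence-bundle scenario
#'
#' Each scenario declares its intent: the gene, an evidence bundle, optional
#' gene-config overrides, and the exact post-exclusion criterion set, class
#' and point total the engine is expected to produce. The test suite runs
#' every scenario through the engine and checks the declared intent, so the
#' generator and the engine cannot drift apart silently.
#'
#' @param name A template name from [scenario_names()].
#' @param seed Integer seed (generation is a pure function of name and seed).
#' @return List with `name`, `gene`, `bundle`, `config_overrides`,
#'   `intended` (data.frame code/strength), `expected_class`,
#'   `expected_points`.
#' @export
make_evidence_scenario <- function(name, seed = 1L) {
  fn <- .scenarios[[name]]
  if (is.null(fn)) {
    stop("unknown scenario template: ", name, "; see scenario_names()",
         call. = FALSE)
  }
  out <- fn(as.integer(seed))
  out$name <- name
  out$config_overrides <- out$config_overrides %||% list()
  out
}

#' Gene configuration for a scenario
#'
#' @param scenario Result of [make_evidence_scenario()].
#' @param configs Optional preloaded configuration set.
#' @return The scenario gene's `gene_config` with the scenario's overrides
#'   applied.
#' @export
scenario_config <- function(scenario, configs = load_gene_config()) {
  cfg <- gene_config_for(configs, scenario$gene)
  for (k in names(scenario$config_overrides)) {
    cfg[[k]] <- scenario$config_overrides[[k]]
  }
  cfg
}

#' Brute-force point-combination oracle
#'
#' Independently enumerates every subset of a criterion universe, summing
#' points from its own strength table and classifying with its own band
#' lookup. Used to verify the combiner by exhaustive equivalence.
#'
#' @param universe data.frame with columns `code` and `strength`
#'   (at most 14 rows).
#' @return data.frame with one row per subset: `subset_id` (bitmask),
#'   `points`, `class`.
#' @export
combination_oracle <- function(universe) {
  stopifnot(is.data.frame(universe), nrow(universe) <= 14)
  pts_tab <- c(supporting = 1, moderate = 2, strong = 4, very_strong = 8,
               standalone = 0)
  sign <- ifelse(substr(universe$code, 1, 1) == "P", 1, -1)
  item_pts <- sign * pts_tab[universe$strength]
  band <- function(p) {
    if (p >= 10) return("pathogenic")
    if (p >= 6) return("likely_pathogenic")
    if (p >= 0) return("VUS")
    if (p >= -5) return("likely_benign")
    "benign"
  }
  n <- nrow(universe)
  ids <- 0:(2^n - 1)
  pts <- vapply(ids, function(mask) {
    sum(item_pts[bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) != 0])
  }, 0)
  data.frame(subset_id = ids, points = as.integer(pts),
             class = vapply(as.integer(pts), band, ""),
             stringsAsFactors = FALSE)
}

#' Independent Clopper-Pearson lower-bound oracle
#'
#' Inverts the exact binomial tail by root finding on `pbinom` instead of
#' using the beta quantile, providing an independent check of
#' [af_ci_lower()].
#'
#' @param allele_count,allele_number Counts as in [af_ci_lower()].
#' @param confidence One-sided confidence level.
#' @return The lower confidence limit.
#' @export
ci_lower_bruteforce <- function(allele_count, allele_number,
                                confidence = 0.95) {
  if (allele_count == 0) return(0)
  alpha <- 1 - confidence
  f <- function(p) {
    stats::pbinom(allele_count - 1, allele_number, p, lower.tail = FALSE) - alpha
  }
  stats::uniroot(f, c(1e-15, 1 - 1e-15), tol = 1e-14)$root
}

#' Write a complete fixture dataset to disk
#'
#' Writes every registered scenario's evidence bundle as JSON, a batch table
#' referencing them (cycling the scenarios to reach `n_rows`), and a gene
#' config override file mirroring the scenario overrides.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed forwarded to the scenario generators.
#' @param n_rows Number of batch-table rows (default: one per scenario).
#' @return List with `bundle_paths`, `batch_table`, `config_file`.
#' @export
write_fixture_dataset <- function(dir, seed = 1L, n_rows = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nms <- scenario_names()
  bundle_paths <- character(0)
  rows <- list()
  cfg_lines <- character(0)
  for (nm in nms) {
    sc <- make_evidence_scenario(nm, seed)
    p <- file.path(dir, paste0(nm, ".json"))
    write_evidence_bundle(sc$bundle, p)
    bundle_paths[nm] <- p
    rows[[nm]] <- data.frame(gene = sc$gene,
                             transcript = sc$bundle$descriptor$transcript_id,
                             cdna = sc$bundle$descriptor$cdna,
                             evidence_path = p, stringsAsFactors = FALSE)
    for (k in names(sc$config_overrides)) {
      cfg_lines <- c(cfg_lines, paste(sc$gene, k, sc$config_overrides[[k]],
                                      sep = "\t"))
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(n_rows)) {
    tab <- tab[rep(seq_len(nrow(tab)), length.out = n_rows), , drop = FALSE]
  }
  batch_path <- file.path(dir, "batch_table.tsv")
  utils::write.table(tab, batch_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg_path <- file.path(dir, "config_overrides.tsv")
  writeLines(c("# scenario gene-config overrides", unique(cfg_lines)),
             cfg_path)
  list(bundle_paths = bundle_paths, batch_table = batch_path,
       config_file = cfg_path)
}
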