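# Gene-specific configuration: per-gene cut-offs and rule variants for the
# nine hereditary-cancer genes with ClinGen-style specific guidelines
# (ATM, CDH1, CHEK2, MLH1, MSH2, MSH6, PMS2, PTEN, TP53) plus a GENERAL
# profile inherited by every other gene. Shipped defaults live in
# inst/extdata/gene_config_defaults.tsv; users override them with a
# tab-delimited file of (gene, parameter, value) rows.

.mmr_genes <- c("MLH1", "MSH2", "MSH6", "PMS2")
.specific_genes <- c("ATM", "CDH1", "CHEK2", .mmr_genes, "PTEN", "TP53")

.config_parsers <- list(
  ba1_af = as.numeric, bs1_af = as.numeric, pm2_af = as.numeric,
  pm2_strength = as.character, use_ci_lower = as.logical,
  ci_confidence = as.numeric, exclude_founder = as.logical,
  pp3_protein_min = as.numeric, bp4_protein_max = as.numeric,
  pp3_splice_min = as.numeric, bp4_splice_max = as.numeric,
  bp7_requires_nonconserved = as.logical,
  conservation_max_phastcons = as.numeric,
  pvs1_mode = as.character, pvs1_override_boundary = as.numeric,
  protein_loss_fraction = as.numeric,
  ps1_enabled = as.logical, pm5_mode = as.character,
  bs2_mode = as.character, bs2_flossies_min = as.numeric,
  bs2_homozygote_min = as.numeric,
  bp2_mode = as.character,
  mmr_splice_combination = as.logical, mmr_prior_min = as.numeric,
  pm1_applicable = as.logical, pp2_enabled = as.logical,
  ps3_bs3_covered = as.logical, bs3_covered = as.logical,
  expert_panel_only = as.logical)

.config_enums <- list(
  pm2_strength = c("very_strong", "strong", "moderate", "supporting"),
  pvs1_mode = c("general_tree", "pten_override", "cdh1_site_specific"),
  pm5_mode = c("classic_codon", "cdh1_truncating", "off"),
  bs2_mode = c("off", "flossies_or_homozygote", "not_automated"),
  bp2_mode = c("off", "homozygote_supporting", "not_applicable"))

.validate_gene_config <- function(cfg, gene) {
  bad <- function(...) stop("gene configuration error (", gene, "): ", ...,
                            call. = FALSE)
  if (!(cfg$ba1_af > cfg$bs1_af)) {
    bad("ba1_af (", cfg$ba1_af, ") must exceed bs1_af (", cfg$bs1_af, ")")
  }
  if (!(cfg$bs1_af > cfg$pm2_af)) {
    bad("bs1_af (", cfg$bs1_af, ") must exceed pm2_af (", cfg$pm2_af, ")")
  }
  if (cfg$pm2_af < 0) bad("pm2_af must be non-negative")
  if (!(cfg$pp3_splice_min > cfg$bp4_splice_max)) {
    bad("pp3_splice_min (", cfg$pp3_splice_min,
        ") must exceed bp4_splice_max (", cfg$bp4_splice_max, ")")
  }
  if (!(cfg$pp3_protein_min > cfg$bp4_protein_max)) {
    bad("pp3_protein_min (", cfg$pp3_protein_min,
        ") must exceed bp4_protein_max (", cfg$bp4_protein_max, ")")
  }
  for (p in names(.config_enums)) {
    if (!(cfg[[p]] %in% .config_enums[[p]])) {
      bad(p, " must be one of: ", paste(.config_enums[[p]], collapse = ", "))
    }
  }
  invisible(cfg)
}

.read_config_rows <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(data.frame(gene = character(), parameter = character(),
                      value = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad) > 0) {
    stop("gene configuration file ", path, ": line ", bad[1],
         " does not have 3 tab-separated fields", call. = FALSE)
  }
  df <- data.frame(gene = vapply(parts, `[[`, "", 1),
                   parameter = vapply(parts, `[[`, "", 2),
                   value = vapply(parts, `[[`, "", 3),
                   stringsAsFactors = FALSE)
  if (identical(tolower(df$parameter[1]), "parameter")) df <- df[-1, ]
  df
}

.apply_config_rows <- function(configs, rows) {
  for (i in seq_len(nrow(rows))) {
    gene <- rows$gene[i]
    param <- rows$parameter[i]
    if (!param %in% names(.config_parsers)) {
      stop("unknown gene-config parameter '", param, "' (gene ", gene, ")",
           call. = FALSE)
    }
    if (is.null(configs[[gene]])) {
      configs[[gene]] <- configs[["GENERAL"]]
      configs[[gene]]$gene_symbol <- gene
    }
    val <- suppressWarnings(.config_parsers[[param]](rows$value[i]))
    if (is.na(val) && !identical(rows$value[i], "NA")) {
      stop("gene-config value '", rows$value[i], "' for ", gene, "/", param,
           " could not be parsed", call. = FALSE)
    }
    configs[[gene]][[param]] <- val
  }
  configs
}

#' Load gene-specific configuration
#'
#' Loads the packaged default configuration and optionally applies a user
#' override file. The file dialect is UTF-8 tab-delimited with three columns
#' `gene`, `parameter`, `value` (one parameter per row) and `#` comments; an
#' optional header row is skipped. Genes without any rows inherit the
#' `GENERAL` profile. Overriding is idempotent: applying the same file twice
#' equals applying it once.
#'
#' Numeric frequency thresholds in the shipped defaults (`ba1_af`, `bs1_af`,
#' `pm2_af`) are documented synthetic values, not published guideline
#' numbers; deployments should set them from the applicable gene-specific
#' guidelines.
#'
#' @param path Optional path to an override file; `NULL` loads defaults only.
#' @return A named list of `gene_config` objects (one per configured gene,
#'   plus `GENERAL`), validated against the threshold-ordering invariants
#'   `ba1_af > bs1_af > pm2_af >= 0`, `pp3_splice_min > bp4_splice_max`,
#'   `pp3_protein_min > bp4_protein_max`.
#' @export
load_gene_config <- function(path = NULL) {
  defaults_path <- system.file("extdata", "gene_config_defaults.tsv",
                               package = "hcvarclass", mustWork = TRUE)
  base <- list(gene_symbol = "GENERAL")
  configs <- list(GENERAL = base)
  configs <- .apply_config_rows(configs, .read_config_rows(defaults_path))
  # genes configured in defaults start from the finished GENERAL profile
  general <- configs$GENERAL
  configs <- list(GENERAL = general)
  rows <- .read_config_rows(defaults_path)
  configs <- .apply_config_rows(configs, rows[rows$gene != "GENERAL", ])
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("no such gene-config file: ", path, call. = FALSE)
    }
    configs <- .apply_config_rows(configs, .read_config_rows(path))
  }
  for (g in names(configs)) {
    configs[[g]] <- structure(configs[[g]], class = "gene_config")
    .validate_gene_config(configs[[g]], g)
  }
  configs
}

#' Look up the configuration for one gene
#'
#' @param configs Result of [load_gene_config()].
#' @param gene Gene symbol; genes without a specific profile inherit
#'   `GENERAL`.
#' @return A `gene_config`.
#' @export
gene_config_for <- function(configs, gene) {
  cfg <- configs[[gene]]
  if (is.null(cfg)) {
    cfg <- configs[["GENERAL"]]
    cfg$gene_symbol <- gene
  }
  cfg
}

#' Criterion applicability matrix for a gene
#'
#' Derives, from a gene's configuration, how each criterion with
#' gene-dependent handling is treated: `automated`, `partial`, `manual_only`
#' or `not_applicable`. Purely informational (reports); the evaluators apply
#' the same flags directly.
#'
#' @param cfg A `gene_config`.
#' @return Named character vector keyed by criterion code.
#' @export
criterion_applicability <- function(cfg) {
  c(BA1 = "automated", BS1 = "automated", PM2 = "automated",
    BS2 = switch(cfg$bs2_mode, off = "not_applicable",
                 flossies_or_homozygote = "partial",
                 not_automated = "manual_only"),
    PVS1 = "automated", PP3 = "automated", BP4 = "automated",
    BP7 = "automated", PM4 = "automated", BP3 = "automated",
    PS1 = if (cfg$ps1_enabled) "automated" else "not_applicable",
    PM5 = if (cfg$pm5_mode == "off") "not_applicable" else "automated",
    PS3 = if (cfg$ps3_bs3_covered) "partial" else "manual_only",
    BS3 = if (cfg$ps3_bs3_covered && cfg$bs3_covered) "partial"
          else "manual_only",
    PM1 = if (cfg$pm1_applicable) "automated" else "not_applicable",
    PP2 = if (cfg$pp2_enabled) "automated" else "not_applicable",
    BP2 = switch(cfg$bp2_mode, off = "manual_only",
                 homozygote_supporting = "partial",
                 not_applicable = "not_applicable"),
    PM3 = "manual_only", PS4 = "manual_only", PS2 = "manual_only",
    PM6 = "manual_only", PP1 = "manual_only", BS4 = "manual_only",
    PP4 = "manual_only", BP5 = "manual_only", BP1 = "manual_only")
}
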