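# Evidence bundles: the per-variant evidence container every criterion module
# consumes. Bundles are built in code (fixtures) or loaded from JSON files.
# Missing evidence is tri-state: a field absent from the bundle (NULL) means
# "no evidence", which downstream yields not_automated -- never a denial.

.consequences <- c("missense", "nonsense", "frameshift", "synonymous",
                   "inframe_indel", "stoploss", "startloss", "intronic", "utr")

.default_flags <- list(in_pm1_region = FALSE, in_repeat_region = FALSE,
                       is_canonical_splice = FALSE, nmd_proven = FALSE,
                       cdh1_pm5_splice_eligible = FALSE)

#' Construct a population allele-frequency record
#'
#' One gnomAD-style subpopulation record from a non-cancer dataset.
#' `coverage_ok` marks whether the site mean coverage meets the 20x minimum;
#' `founder` marks bottleneck populations (e.g. Ashkenazi Jewish, Finnish)
#' that are excluded from BA1/BS1 comparisons when the gene configuration
#' requests it.
#'
#' @param population_label Subpopulation label (e.g. `"nfe"`, `"asj"`).
#' @param allele_count,allele_number Observed allele count and total alleles.
#' @param homozygote_count Homozygous individuals observed.
#' @param founder Logical founder-population flag.
#' @param coverage_ok Logical; site coverage passes the 20x minimum.
#' @return A list of class `population_record`.
#' @export
population_record <- function(population_label, allele_count, allele_number,
                              homozygote_count = 0L, founder = FALSE,
                              coverage_ok = TRUE) {
  allele_count <- as.integer(allele_count)
  allele_number <- as.integer(allele_number)
  homozygote_count <- as.integer(homozygote_count)
  if (allele_number <= 0L) stop("allele_number must be positive", call. = FALSE)
  if (allele_count < 0L || homozygote_count < 0L) {
    stop("allele/homozygote counts must be non-negative", call. = FALSE)
  }
  if (allele_count > allele_number) {
    stop("allele_count exceeds allele_number", call. = FALSE)
  }
  if (homozygote_count > allele_count %/% 2L) {
    stop("homozygote_count exceeds allele_count/2", call. = FALSE)
  }
  structure(list(population_label = population_label,
                 allele_count = allele_count, allele_number = allele_number,
                 homozygote_count = homozygote_count,
                 founder = isTRUE(founder), coverage_ok = isTRUE(coverage_ok)),
            class = "population_record")
}

#' Construct an evidence bundle
#'
#' Collects everything the rules engine needs for one variant: its parsed
#' descriptor and transcript model, subpopulation allele counts, in silico
#' predictor scores, expert-panel codon context, functional-assay records,
#' region flags and the molecular consequence, plus optional curator-supplied
#' manual criteria.
#'
#' Any evidence block may be `NULL`, meaning the evidence was not available;
#' the corresponding criteria then return `not_automated` rather than being
#' denied.
#'
#' @param descriptor A `variant_descriptor` (see [parse_cdna_description()]).
#' @param transcript A `transcript_model`.
#' @param protein_consequence One of `r paste(.consequences, collapse=", ")`.
#' @param population List of [population_record()]s, or `NULL`.
#' @param predictions Named list of predictor scores: `revel`, `spliceai_ag`,
#'   `spliceai_al`, `spliceai_dg`, `spliceai_dl`, `provean`, `phastcons`,
#'   `phylop`, `mmr_prior` (each `NULL` when unavailable).
#' @param protein_change Optional `list(ref_aa=, codon=, alt_aa=)` for the
#'   test variant (three-letter amino-acid codes, `"Ter"` for stop).
#' @param codon_context List of codon-context entries
#'   (`list(cdna=, protein_change=, classification=, expert_panel_reviewed=,
#'   nmd_predicted=)`) or `NULL` when not retrieved.
#' @param functional List of functional-assay records (see
#'   [functional_assay_record()]) to merge with the packaged table, or `NULL`.
#' @param flags Named list overriding the defaults `in_pm1_region`,
#'   `in_repeat_region`, `is_canonical_splice`, `nmd_proven`,
#'   `cdh1_pm5_splice_eligible` (all `FALSE`).
#' @param flossies_count Observations in the FLOSSIES cancer-free-women
#'   resource, or `NULL` if not consulted.
#' @param homozygote_count_noncancer Homozygotes in the non-cancer population
#'   dataset, or `NULL` if not consulted.
#' @param manual_criteria List of `list(code=, strength=)` supplied by the
#'   curator for non-automatable criteria.
#' @return An object of class `evidence_bundle`.
#' @export
evidence_bundle <- function(descriptor, transcript, protein_consequence,
                            population = NULL, predictions = list(),
                            protein_change = NULL, codon_context = NULL,
                            functional = NULL, flags = list(),
                            flossies_count = NULL,
                            homozygote_count_noncancer = NULL,
                            manual_criteria = list()) {
  stopifnot(inherits(descriptor, "variant_descriptor"),
            inherits(transcript, "transcript_model"))
  protein_consequence <- match.arg(protein_consequence, .consequences)
  fl <- utils::modifyList(.default_flags, flags)
  fl$protein_consequence <- protein_consequence
  fl$is_missense <- protein_consequence == "missense"
  fl$is_synonymous <- protein_consequence == "synonymous"
  if (!is.null(flossies_count)) flossies_count <- as.integer(flossies_count)
  if (!is.null(homozygote_count_noncancer)) {
    homozygote_count_noncancer <- as.integer(homozygote_count_noncancer)
  }
  if (any(c(flossies_count, homozygote_count_noncancer) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  structure(
    list(descriptor = descriptor, transcript = transcript,
         population = population, predictions = predictions,
         protein_change = protein_change, codon_context = codon_context,
         functional = functional, flags = fl,
         flossies_count = flossies_count,
         homozygote_count_noncancer = homozygote_count_noncancer,
         manual_criteria = manual_criteria),
    class = "evidence_bundle")
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat(sprintf("<evidence bundle: %s %s %s [%s]>\n", x$descriptor$gene_symbol,
              x$descriptor$transcript_id, x$descriptor$cdna,
              x$flags$protein_consequence))
  invisible(x)
}

# ---- JSON (de)serialisation -------------------------------------------------

.bundle_errors <- function() {
  errs <- character()
  list(add = function(path, msg) errs <<- c(errs, paste0(path, ": ", msg)),
       all = function() errs)
}

.chk_num01 <- function(e, x, path) {
  if (!is.null(x) && (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1)) {
    e$add(path, "must be a number in [0,1]")
  }
}
.chk_count <- function(e, x, path) {
  if (!is.null(x) && (!is.numeric(x) || length(x) != 1 || x < 0 ||
                      x != trunc(x))) {
    e$add(path, "must be a non-negative integer")
  }
}

#' Load an evidence bundle from JSON
#'
#' Reads and validates a bundle file against the schema shipped at
#' `system.file("extdata", "evidence-bundle-schema.json", package =
#' "hcvarclass")`. Validation collects every failing field path before
#' erroring, so a malformed file is reported in one pass. Evidence blocks
#' absent from the file stay absent (tri-state missingness), never
#' defaulting to zero.
#'
#' @param path Path to a bundle JSON file.
#' @return An `evidence_bundle`.
#' @seealso [write_evidence_bundle()] for the inverse; `load(write(b))`
#'   reproduces `b` on canonical form.
#' @export
load_evidence_bundle <- function(path) {
  if (!file.exists(path)) stop("no such bundle file: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  e <- .bundle_errors()

  for (f in c("gene", "transcript_id", "cdna")) {
    if (!is.character(j[[f]] %||% NULL) || !nzchar(j[[f]] %||% "")) {
      e$add(f, "required string")
    }
  }
  tj <- j$transcript
  if (is.null(tj) || is.null(tj$exons) || length(tj$exons) == 0) {
    e$add("transcript.exons", "required non-empty exon list")
  }
  fj <- j$flags
  if (is.null(fj$protein_consequence) ||
      !(fj$protein_consequence %in% .consequences)) {
    e$add("flags.protein_consequence",
          paste("must be one of:", paste(.consequences, collapse = ", ")))
  }
  for (i in seq_along(j$population)) {
    p <- j$population[[i]]
    pre <- sprintf("population[%d]", i)
    .chk_count(e, p$allele_count, paste0(pre, ".allele_count"))
    .chk_count(e, p$homozygote_count, paste0(pre, ".homozygote_count"))
    if (is.null(p$allele_number) || !is.numeric(p$allele_number) ||
        p$allele_number <= 0) {
      e$add(paste0(pre, ".allele_number"), "must be a positive integer")
    } else if (!is.null(p$allele_count) && is.numeric(p$allele_count) &&
               p$allele_count > p$allele_number) {
      e$add(paste0(pre, ".allele_count"), "exceeds allele_number")
    }
  }
  pj <- j$predictions
  .chk_num01(e, pj$revel, "predictions.revel")
  for (s in c("ag", "al", "dg", "dl")) {
    .chk_num01(e, pj$spliceai[[s]], paste0("predictions.spliceai.", s))
  }
  .chk_num01(e, pj$phastcons, "predictions.phastcons")
  .chk_num01(e, pj$mmr_prior, "predictions.mmr_prior")
  .chk_count(e, j$flossies_count, "flossies_count")
  .chk_count(e, j$homozygote_count_noncancer, "homozygote_count_noncancer")
  for (i in seq_along(j$codon_context)) {
    cc <- j$codon_context[[i]]
    if (is.null(cc$classification) ||
        !(cc$classification %in% c("P", "LP", "VUS", "LB", "B"))) {
      e$add(sprintf("codon_context[%d].classification", i),
            "must be one of P, LP, VUS, LB, B")
    }
    if (!is.null(cc$protein_change$codon) && cc$protein_change$codon < 1) {
      e$add(sprintf("codon_context[%d].protein_change.codon", i), "must be >= 1")
    }
  }
  if (length(e$all()) > 0) {
    stop("evidence bundle ", path, " failed validation:\n  ",
         paste(e$all(), collapse = "\n  "), call. = FALSE)
  }

  exons <- do.call(rbind, lapply(tj$exons, function(x) {
    data.frame(index = x$index, cdna_first = x$cdna_first,
               cdna_last = x$cdna_last)
  }))
  trans <- transcript_model(
    j$transcript_id, exons,
    protein_length = tj$protein_length %||% NULL,
    relevant_region_end = tj$relevant_region_end %||% NULL,
    strand = tj$strand %||% "+")
  desc <- parse_cdna_description(j$cdna, gene_symbol = j$gene,
                                 transcript_id = j$transcript_id)
  pop <- if (is.null(j$population)) NULL else lapply(j$population, function(p) {
    population_record(p$population %||% p$population_label,
                      p$allele_count, p$allele_number,
                      p$homozygote_count %||% 0L,
                      founder = isTRUE(p$founder),
                      coverage_ok = !isFALSE(p$coverage_ok))
  })
  preds <- list(
    revel = pj$revel %||% NULL,
    spliceai_ag = pj$spliceai$ag %||% NULL,
    spliceai_al = pj$spliceai$al %||% NULL,
    spliceai_dg = pj$spliceai$dg %||% NULL,
    spliceai_dl = pj$spliceai$dl %||% NULL,
    provean = pj$provean %||% NULL,
    phastcons = pj$phastcons %||% NULL,
    phylop = pj$phylop %||% NULL,
    mmr_prior = pj$mmr_prior %||% NULL)
  func <- if (is.null(j$functional)) NULL else lapply(j$functional, function(r) {
    functional_assay_record(r$gene %||% j$gene, r$variant_key, r$source_id,
                            r$result, r$strength %||% "strong",
                            guideline_listed = isTRUE(r$guideline_listed))
  })
  manual <- lapply(j$manual_criteria, function(m) {
    list(code = m$code, strength = m$strength)
  })
  evidence_bundle(
    descriptor = desc, transcript = trans,
    protein_consequence = fj$protein_consequence,
    population = pop, predictions = preds,
    protein_change = j$protein_change %||% NULL,
    codon_context = if (is.null(j$codon_context)) NULL else j$codon_context,
    functional = func,
    flags = fj[setdiff(names(fj), "protein_consequence")],
    flossies_count = j$flossies_count %||% NULL,
    homozygote_count_noncancer = j$homozygote_count_noncancer %||% NULL,
    manual_criteria = manual)
}

#' Write an evidence bundle to JSON (canonical form)
#'
#' @param bundle An `evidence_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  t <- bundle$transcript
  j <- list(
    gene = bundle$descriptor$gene_symbol,
    transcript_id = bundle$descriptor$transcript_id,
    cdna = bundle$descriptor$cdna,
    transcript = list(
      strand = t$strand,
      exons = lapply(seq_len(nrow(t$exons)), function(i) {
        as.list(t$exons[i, c("index", "cdna_first", "cdna_last")])
      }),
      protein_length = t$protein_length,
      relevant_region_end = t$relevant_region_end),
    flags = bundle$flags[c(names(.default_flags), "protein_consequence",
                           "is_missense", "is_synonymous")],
    predictions = list(
      revel = bundle$predictions$revel,
      spliceai = if (any(!vapply(bundle$predictions[
          c("spliceai_ag", "spliceai_al", "spliceai_dg", "spliceai_dl")],
          is.null, TRUE))) {
        list(ag = bundle$predictions$spliceai_ag,
             al = bundle$predictions$spliceai_al,
             dg = bundle$predictions$spliceai_dg,
             dl = bundle$predictions$spliceai_dl)
      } else NULL,
      provean = bundle$predictions$provean,
      phastcons = bundle$predictions$phastcons,
      phylop = bundle$predictions$phylop,
      mmr_prior = bundle$predictions$mmr_prior),
    protein_change = bundle$protein_change,
    population = if (is.null(bundle$population)) NULL else
      lapply(bundle$population, function(p) {
        list(population = p$population_label, allele_count = p$allele_count,
             allele_number = p$allele_number,
             homozygote_count = p$homozygote_count,
             founder = p$founder, coverage_ok = p$coverage_ok)
      }),
    codon_context = bundle$codon_context,
    functional = if (is.null(bundle$functional)) NULL else
      lapply(bundle$functional, unclass),
    flossies_count = bundle$flossies_count,
    homozygote_count_noncancer = bundle$homozygote_count_noncancer,
    manual_criteria = bundle$manual_criteria)
  j <- j[!vapply(j, is.null, TRUE)]
  jsonlite::write_json(j, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
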