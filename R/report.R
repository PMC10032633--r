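# Reporting: literature search-string builder, TSV/xlsx report writer (TSV is
# the canonical, byte-stable format; xlsx is a presentation layer written by a
# minimal single-sheet OOXML writer), and single/batch classification entry
# points with per-run log files.

.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
             Ter = "*")

#' Build a literature search string for a variant
#'
#' OR-joins quoted aliases of the variant name (the coding-DNA description
#' with and without its `c.` prefix and with spaced operators, plus the
#' protein change in three-letter and one-letter forms when available),
#' conjoined with the gene symbol, for use in Internet search engines when
#' manually curating functional, allelic and clinical criteria.
#'
#' @param d A `variant_descriptor`.
#' @param protein_change Optional `list(ref_aa=, codon=, alt_aa=)`
#'   (three-letter codes, `"Ter"` for stop).
#' @return A single search-string.
#' @examples
#' d <- parse_cdna_description("c.892G>T", gene_symbol = "TP53")
#' build_search_string(d, list(ref_aa = "Glu", codon = 298, alt_aa = "Ter"))
#' @export
build_search_string <- function(d, protein_change = NULL) {
  stopifnot(inherits(d, "variant_descriptor"))
  body <- sub("^c\\.", "", d$cdna)
  aliases <- c(d$cdna, body, paste0("c. ", body))
  if (grepl(">", body, fixed = TRUE)) {
    aliases <- c(aliases, gsub(">", " > ", d$cdna, fixed = TRUE))
  }
  if (!is.null(protein_change)) {
    pc <- protein_change
    three <- paste0(pc$ref_aa, pc$codon, pc$alt_aa)
    one <- paste0(.aa3to1[[pc$ref_aa]], pc$codon, .aa3to1[[pc$alt_aa]])
    aliases <- c(aliases, three, paste0("p.(", three, ")"), paste0("p.", three),
                 one)
  }
  aliases <- unique(aliases)
  paste0('"', d$gene_symbol, '" AND (',
         paste0('"', aliases, '"', collapse = " OR "), ")")
}

# ---- report writing ---------------------------------------------------------

.report_table <- function(result) {
  df <- calls_as_data_frame(result$calls)
  df[order(.code_order[df$code]), , drop = FALSE]
}

.report_summary_lines <- function(result, search_string) {
  c(sprintf("# variant\t%s\t%s\t%s", result$gene, result$transcript_id,
            result$cdna),
    sprintf("# classification\t%s", result$classification),
    sprintf("# total_points\t%d", result$total_points),
    sprintf("# ba1_standalone\t%s", result$ba1_standalone),
    sprintf("# search_string\t%s", search_string),
    vapply(seq_len(nrow(result$dropped)), function(i) {
      sprintf("# dropped\t%s\tkept=%s\t%s", result$dropped$code[i],
              result$dropped$kept_code[i], result$dropped$rationale[i])
    }, ""),
    vapply(result$warnings, function(w) sprintf("# warning\t%s", w), ""))
}

#' Export a classification result to TSV or xlsx
#'
#' The report holds one row per criterion (code, state, strength, points,
#' source, explanation, warnings) plus a summary block (total points, class,
#' standalone flag, drop ledger, search string, warnings). TSV is the
#' canonical format: [read_report_tsv()] recovers every call's
#' code/state/strength/points. The xlsx output carries identical cell
#' content in a single sheet.
#'
#' @param result A `classification_result`.
#' @param path Output file path.
#' @param format `"tsv"` or `"xlsx"` (default from the file extension).
#' @param search_string Optional pre-built search string (rebuilt from the
#'   result's descriptor fields if omitted).
#' @return `path`, invisibly.
#' @export
export_report <- function(result, path,
                          format = c("tsv", "xlsx"),
                          search_string = NULL) {
  stopifnot(inherits(result, "classification_result"))
  if (missing(format)) {
    format <- if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx" else "tsv"
  }
  format <- match.arg(format)
  if (is.null(search_string)) {
    d <- parse_cdna_description(result$cdna, gene_symbol = result$gene,
                                transcript_id = result$transcript_id)
    search_string <- build_search_string(d)
  }
  df <- .report_table(result)
  header <- .report_summary_lines(result, search_string)
  if (format == "tsv") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(paste(names(df), collapse = "\t"), con)
    for (i in seq_len(nrow(df))) {
      writeLines(paste(vapply(df[i, ], as.character, ""), collapse = "\t"), con)
    }
  } else {
    rows <- c(lapply(header, function(h) strsplit(h, "\t", fixed = TRUE)[[1]]),
              list(names(df)),
              lapply(seq_len(nrow(df)), function(i) {
                vapply(df[i, ], as.character, "")
              }))
    .write_minimal_xlsx(rows, path)
  }
  invisible(path)
}

#' Read back a TSV report
#'
#' @param path Path written by [export_report()] with `format = "tsv"`.
#' @return List with `summary` (named list: classification, total_points,
#'   ba1_standalone, search_string) and `calls` (data.frame of the
#'   per-criterion rows).
#' @export
read_report_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  get1 <- function(key) {
    hit <- meta[startsWith(meta, paste0("# ", key, "\t"))]
    if (length(hit) == 0) return(NULL)
    strsplit(hit[1], "\t", fixed = TRUE)[[1]][2]
  }
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  df$points <- as.integer(df$points)
  list(summary = list(classification = get1("classification"),
                      total_points = as.integer(get1("total_points")),
                      ba1_standalone = as.logical(get1("ba1_standalone")),
                      search_string = get1("search_string")),
       calls = df)
}

# Minimal single-sheet xlsx writer: inline-string cells only. Enough for a
# human-readable spreadsheet and for readxl to parse; not a general OOXML
# implementation.
.write_minimal_xlsx <- function(rows, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  col_ref <- function(i) {
    ref <- ""
    while (i > 0) {
      ref <- paste0(LETTERS[(i - 1) %% 26 + 1], ref)
      i <- (i - 1) %/% 26
    }
    ref
  }
  sheet_rows <- vapply(seq_along(rows), function(r) {
    cells <- vapply(seq_along(rows[[r]]), function(c) {
      sprintf('<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
              col_ref(c), r, esc(rows[[r]][c]))
    }, "")
    sprintf('<row r="%d">%s</row>', r, paste(cells, collapse = ""))
  }, "")
  dir <- tempfile("xlsx")
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'), file.path(dir, "[Content_Types].xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(dir, "_rels", ".rels"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="classification" sheetId="1" r:id="rId1"/></sheets>',
    '</workbook>'), file.path(dir, "xl", "workbook.xml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'), file.path(dir, "xl", "_rels", "workbook.xml.rels"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', sheet_rows, '</sheetData>', '</worksheet>'),
    file.path(dir, "xl", "worksheets", "sheet1.xml"))
  old <- getwd()
  if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(old, path)
  if (file.exists(path)) unlink(path)
  on.exit(setwd(old), add = TRUE)
  setwd(dir)
  zip::zip(path, files = c("[Content_Types].xml", "_rels/.rels",
                           "xl/workbook.xml", "xl/_rels/workbook.xml.rels",
                           "xl/worksheets/sheet1.xml"),
           include_directories = FALSE)
  invisible(path)
}

# ---- single and batch entry points ------------------------------------------

.log_line <- function(con, variant_key, outcome, message, elapsed) {
  writeLines(sprintf("%s\t%s\t%s\t%.3fs\t%s",
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     variant_key, outcome, elapsed, message), con)
}

#' Classify a single variant from an evidence-bundle file
#'
#' Validates the variant (type and 25-bp length limit), runs every criterion
#' module and the combiner, and optionally writes a report. The `status`
#' field distinguishes `classified` / `rejected` (unsupported variant) /
#' `error` (unreadable or invalid inputs).
#'
#' @param gene Gene symbol.
#' @param transcript Transcript identifier.
#' @param cdna HGVS coding-DNA description.
#' @param evidence_path Path to the bundle JSON (its identity fields must
#'   agree with the arguments).
#' @param config_path Optional gene-config override file.
#' @param report_path Optional report output path (TSV or xlsx by extension).
#' @param rules_path Optional exclusion-rules override file.
#' @return List with `status` (`classified`/`rejected`/`error`), `result`
#'   (a `classification_result`, when classified), `reason`/`message`
#'   otherwise.
#' @export
classify_single <- function(gene, transcript, cdna, evidence_path,
                            config_path = NULL, report_path = NULL,
                            rules_path = NULL) {
  out <- tryCatch({
    d <- parse_cdna_description(cdna, gene_symbol = gene,
                                transcript_id = transcript)
    verdict <- validate_supported_variant(d)
    if (!verdict$accepted) {
      return(list(status = "rejected", reason = verdict$reason,
                  message = verdict$message))
    }
    bundle <- load_evidence_bundle(evidence_path)
    if (!identical(bundle$descriptor$cdna, cdna) ||
        !identical(bundle$descriptor$gene_symbol, gene)) {
      stop("evidence bundle identity (", bundle$descriptor$gene_symbol, " ",
           bundle$descriptor$cdna, ") does not match the requested variant (",
           gene, " ", cdna, ")", call. = FALSE)
    }
    configs <- load_gene_config(config_path)
    cfg <- gene_config_for(configs, gene)
    rules <- load_exclusion_rules(rules_path)
    result <- combine_criteria(bundle, cfg, rules)
    if (!is.null(report_path)) {
      export_report(result, report_path,
                    search_string = build_search_string(
                      bundle$descriptor, bundle$protein_change))
    }
    list(status = "classified", result = result)
  }, error = function(e) {
    list(status = "error", message = conditionMessage(e))
  })
  out
}

#' Classify a batch of variants sequentially
#'
#' Reads a tab-delimited table with columns `gene`, `transcript`, `cdna`,
#' `evidence_path`, classifies each row with [classify_single()] (one row's
#' failure never aborts the batch), writes one report per classified variant
#' into `out_dir`, and creates a fresh timestamped log file with exactly one
#' entry per input row (outcome, message, per-variant wall time).
#'
#' @param table_path Path to the batch table.
#' @param out_dir Output directory (created if needed) for reports and the
#'   log file.
#' @param config_path,rules_path Optional override files.
#' @param report_format `"tsv"` or `"xlsx"`.
#' @return List with `summary` (named counts: classified, rejected, error),
#'   `results` (per-row outcome list), `log_path`.
#' @export
classify_batch <- function(table_path, out_dir, config_path = NULL,
                           rules_path = NULL, report_format = "tsv") {
  if (!file.exists(table_path)) {
    stop("batch table not readable: ", table_path, call. = FALSE)
  }
  tab <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  needed <- c("gene", "transcript", "cdna", "evidence_path")
  if (!all(needed %in% names(tab))) {
    stop("batch table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, format(Sys.time(), "run_%Y%m%d_%H%M%S.log"))
  # one fresh log per invocation; suffix if two runs land in the same second
  while (file.exists(log_path)) log_path <- paste0(log_path, "+")
  con <- file(log_path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))

  results <- vector("list", nrow(tab))
  counts <- c(classified = 0L, rejected = 0L, error = 0L)
  for (i in seq_len(nrow(tab))) {
    key <- sprintf("%s:%s", tab$gene[i], tab$cdna[i])
    t0 <- proc.time()[["elapsed"]]
    res <- classify_single(tab$gene[i], tab$transcript[i], tab$cdna[i],
                           tab$evidence_path[i], config_path = config_path,
                           rules_path = rules_path)
    if (res$status == "classified") {
      report <- file.path(out_dir, sprintf("%03d_%s_%s.%s", i, tab$gene[i],
                                           gsub("[^A-Za-z0-9.+-]", "_",
                                                tab$cdna[i]),
                                           report_format))
      export_report(res$result, report, format = report_format)
      res$report_path <- report
    }
    elapsed <- proc.time()[["elapsed"]] - t0
    counts[[res$status]] <- counts[[res$status]] + 1L
    .log_line(con, key, res$status,
              if (res$status == "classified") {
                sprintf("%s (%+d points)", res$result$classification,
                        res$result$total_points)
              } else {
                res$message %||% res$reason %||% ""
              },
              elapsed)
    results[[i]] <- res
  }
  list(summary = as.list(counts), results = results, log_path = log_path)
}
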