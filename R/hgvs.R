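# Minimal HGVS coding-DNA parser covering the engine's supported subset:
# substitutions, deletions, duplications, insertions and single-anchor
# deletion-insertions up to 25 nt, with intronic offsets (+n/-n) and UTR
# positions (c.-n five-prime, c.*n three-prime). Inversions parse but are
# rejected by validate_supported_variant(). This is not a nomenclature
# corrector: descriptions must already be syntactically normalised.

.pos_regex <- "(\\*)?(-?[0-9]+)([+-][0-9]+)?"

.parse_position <- function(token) {
  m <- regmatches(token, regexec(paste0("^", .pos_regex, "$"), token))[[1]]
  if (length(m) == 0) {
    stop("malformed HGVS position token: '", token, "'", call. = FALSE)
  }
  list(utr3 = m[2] == "*",
       base = as.integer(m[3]),
       offset = if (m[4] == "") 0L else as.integer(m[4]))
}

.format_position <- function(base, offset, utr3) {
  paste0(if (utr3) "*" else "", base,
         if (offset > 0) paste0("+", offset) else if (offset < 0) offset else "")
}

.span_length <- function(d) {
  # nucleotide span between start and end positions; valid for exonic spans
  # and spans within one intron (mixed spans carry an explicit sequence)
  (d$cdna_end - d$cdna_start) + (d$intron_offset_end - d$intron_offset_start) + 1L
}

#' Parse an HGVS coding-DNA variant description
#'
#' Parses `c.` descriptions into a structured [variant descriptor]. Supported
#' forms: substitution (`c.100A>T`), deletion (`c.100del`, `c.100_102delATG`),
#' duplication (`c.100dup`, `c.100_105dup`), insertion (`c.100_101insAT`),
#' deletion-insertion (`c.100delinsTT`, `c.100_102delinsA`) and inversion
#' (`c.100_110inv`, parsed but later rejected as unsupported). Positions may
#' carry intronic offsets (`c.1137+1`) and UTR markers (`c.-15`, `c.*52`).
#'
#' @param cdna HGVS coding-DNA string beginning with `"c."`.
#' @param gene_symbol,transcript_id Optional identity fields carried on the
#'   returned descriptor.
#' @return An object of class `variant_descriptor` with fields `gene_symbol`,
#'   `transcript_id`, `cdna`, `variant_type`, `cdna_start`, `cdna_end`,
#'   `intron_offset_start`, `intron_offset_end`, `utr3_start`, `utr3_end`,
#'   `ref_allele`, `alt_allele`, `indel_length`.
#' @examples
#' parse_cdna_description("c.1137+1delG")  # deletion, offset +1, length 1
#' parse_cdna_description("c.892G>T")      # substitution
#' @export
parse_cdna_description <- function(cdna, gene_symbol = NA_character_,
                                   transcript_id = NA_character_) {
  if (!is.character(cdna) || length(cdna) != 1 || !nzchar(cdna)) {
    stop("variant description must be a single non-empty string",
         call. = FALSE)
  }
  if (grepl("^p\\.", cdna)) {
    stop("protein-level (p.) nomenclature is not supported; supply a ",
         "coding-DNA (c.) description", call. = FALSE)
  }
  if (!grepl("^c\\.", cdna)) {
    stop("malformed HGVS description '", cdna, "': must begin with 'c.'",
         call. = FALSE)
  }
  body <- sub("^c\\.", "", cdna)
  pos1 <- paste0("(", .pos_regex, ")")
  span <- paste0(pos1, "(?:_(", .pos_regex, "))?")

  build <- function(type, p_start, p_end, ref = "", alt = "", indel_len) {
    structure(
      list(gene_symbol = gene_symbol, transcript_id = transcript_id,
           cdna = cdna, variant_type = type,
           cdna_start = p_start$base, cdna_end = p_end$base,
           intron_offset_start = p_start$offset,
           intron_offset_end = p_end$offset,
           utr3_start = p_start$utr3, utr3_end = p_end$utr3,
           ref_allele = ref, alt_allele = alt,
           indel_length = as.integer(indel_len)),
      class = "variant_descriptor")
  }

  # substitution: POS R>A
  m <- regmatches(body, regexec(paste0("^", pos1, "([ACGT])>([ACGT])$"), body))[[1]]
  if (length(m) > 0) {
    p <- .parse_position(m[2])
    return(build("substitution", p, p, ref = m[6], alt = m[7], indel_len = 0L))
  }
  # deletion / duplication with optional trailing sequence
  m <- regmatches(body, regexec(paste0("^", span, "(del|dup)([ACGT]*)$"), body))[[1]]
  if (length(m) > 0 && !grepl("delins", body)) {
    p1 <- .parse_position(m[2])
    p2 <- if (m[6] == "") p1 else .parse_position(m[6])
    type <- if (m[10] == "del") "deletion" else "duplication"
    d <- build(type, p1, p2, ref = if (type == "deletion") m[11] else "",
               alt = if (type == "duplication") m[11] else "", indel_len = 0L)
    d$indel_length <- if (nzchar(m[11])) nchar(m[11]) else .span_length(d)
    if (d$indel_length < 1L) {
      stop("malformed HGVS description '", cdna, "': empty span", call. = FALSE)
    }
    return(d)
  }
  # deletion-insertion
  m <- regmatches(body, regexec(paste0("^", span, "delins([ACGT]+)$"), body))[[1]]
  if (length(m) > 0) {
    p1 <- .parse_position(m[2])
    p2 <- if (m[6] == "") p1 else .parse_position(m[6])
    d <- build("delins", p1, p2, ref = "", alt = m[10], indel_len = 0L)
    d$indel_length <- max(.span_length(d), nchar(m[10]))
    return(d)
  }
  # insertion between two flanking positions
  m <- regmatches(body, regexec(paste0("^", pos1, "_", pos1, "ins([ACGT]+)$"),
                                body))[[1]]
  if (length(m) > 0) {
    p1 <- .parse_position(m[2])
    p2 <- .parse_position(m[6])
    return(build("insertion", p1, p2, alt = m[10], indel_len = nchar(m[10])))
  }
  # inversion (parsed so validation can reject it with a precise reason)
  m <- regmatches(body, regexec(paste0("^", span, "inv$"), body))[[1]]
  if (length(m) > 0) {
    p1 <- .parse_position(m[2])
    p2 <- if (m[6] == "") p1 else .parse_position(m[6])
    d <- build("inversion", p1, p2, indel_len = 0L)
    d$indel_length <- .span_length(d)
    return(d)
  }
  stop("malformed HGVS description '", cdna, "': unrecognised form '",
       body, "'", call. = FALSE)
}

#' Format a variant descriptor back to its HGVS string
#'
#' Inverse of [parse_cdna_description()] on the supported subset:
#' `parse(format(d))` reproduces `d`.
#'
#' @param d A `variant_descriptor`.
#' @return The HGVS coding-DNA string.
#' @export
format_cdna <- function(d) {
  stopifnot(inherits(d, "variant_descriptor"))
  p1 <- .format_position(d$cdna_start, d$intron_offset_start, d$utr3_start)
  p2 <- .format_position(d$cdna_end, d$intron_offset_end, d$utr3_end)
  single <- identical(p1, p2)
  span <- if (single) p1 else paste0(p1, "_", p2)
  body <- switch(d$variant_type,
    substitution = paste0(p1, d$ref_allele, ">", d$alt_allele),
    deletion = paste0(span, "del", d$ref_allele),
    duplication = paste0(span, "dup", d$alt_allele),
    insertion = paste0(p1, "_", p2, "ins", d$alt_allele),
    delins = paste0(span, "delins", d$alt_allele),
    inversion = paste0(span, "inv"))
  paste0("c.", body)
}

#' @export
print.variant_descriptor <- function(x, ...) {
  cat(sprintf("<variant %s %s %s (%s)>\n",
              x$gene_symbol, x$transcript_id, x$cdna, x$variant_type))
  invisible(x)
}

# Maximum supported insertion/deletion length in nucleotides.
.max_indel_nt <- 25L

#' Validate that a variant is of a supported type and size
#'
#' The engine classifies single-nucleotide substitutions and deletions,
#' duplications and insertions up to 25 bp (including intronic and UTR
#' variants). Inversions, deletion-insertions with more than one nucleotide
#' on both sides, and indels longer than 25 nt are rejected.
#'
#' @param d A `variant_descriptor`.
#' @return A list with `accepted` (logical), and when rejected, `reason`
#'   (machine-readable code) and `message`.
#' @examples
#' validate_supported_variant(parse_cdna_description("c.100A>T"))
#' validate_supported_variant(parse_cdna_description("c.100_110inv"))
#' @export
validate_supported_variant <- function(d) {
  stopifnot(inherits(d, "variant_descriptor"))
  reject <- function(reason, message) {
    list(accepted = FALSE, reason = reason, message = message)
  }
  if (d$variant_type == "inversion") {
    return(reject("unsupported_type_inversion",
                  "inversions are not supported"))
  }
  if (d$variant_type == "delins") {
    del_span <- .span_length(d)
    if (del_span > 1L && nchar(d$alt_allele) > 1L) {
      return(reject("delins_both_sides_gt1",
                    "deletion-insertions with >1 nt on both sides are not supported"))
    }
  }
  if (d$indel_length > .max_indel_nt) {
    return(reject("indel_length_exceeds_25",
                  sprintf("indel length %d exceeds the %d-bp limit",
                          d$indel_length, .max_indel_nt)))
  }
  list(accepted = TRUE, reason = NULL, message = NULL)
}
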