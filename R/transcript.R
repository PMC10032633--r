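#' Construct a transcript model in cDNA coordinates
#'
#' Stores the exon geometry needed by the loss-of-function decision tree:
#' exon bounds in cDNA space (genome-build independent), CDS and protein
#' lengths, and the position of the 3'-most exon-exon junction used by the
#' 50-nt nonsense-mediated-decay rule. `relevant_region_end` optionally bounds
#' the biologically relevant region of the protein-coding sequence (for
#' example the PTEN c.1121 boundary used by its specific guidelines).
#'
#' @param transcript_id Transcript identifier (RefSeq-style).
#' @param exons data.frame with columns `index`, `cdna_first`, `cdna_last`;
#'   exons must be contiguous and non-overlapping in cDNA space, starting at 1.
#' @param protein_length Protein length in amino acids; defaults to
#'   `cds_length / 3 - 1` (excluding the stop codon) when the CDS length is a
#'   multiple of 3.
#' @param relevant_region_end Optional cDNA position bounding the biologically
#'   relevant region (`NULL` = whole CDS relevant).
#' @param strand `"+"` or `"-"` (informational; all logic is in cDNA space).
#' @return An object of class `transcript_model` with fields `transcript_id`,
#'   `strand`, `exons`, `cds_length`, `protein_length`, `last_junction_cdna`
#'   (`NA` for single-exon transcripts), `relevant_region_end`, `single_exon`.
#' @export
transcript_model <- function(transcript_id, exons, protein_length = NULL,
                             relevant_region_end = NULL, strand = "+") {
  stopifnot(is.data.frame(exons),
            all(c("index", "cdna_first", "cdna_last") %in% names(exons)))
  exons <- exons[order(exons$cdna_first), , drop = FALSE]
  if (exons$cdna_first[1] != 1L) {
    stop("exon bounds must start at cDNA position 1", call. = FALSE)
  }
  if (any(exons$cdna_last < exons$cdna_first)) {
    stop("exon with cdna_last < cdna_first", call. = FALSE)
  }
  if (nrow(exons) > 1 &&
      any(exons$cdna_first[-1] != exons$cdna_last[-nrow(exons)] + 1L)) {
    stop("exons must be contiguous and non-overlapping in cDNA space",
         call. = FALSE)
  }
  cds_length <- exons$cdna_last[nrow(exons)]
  if (is.null(protein_length)) {
    protein_length <- if (cds_length %% 3 == 0) cds_length %/% 3 - 1L
                      else NA_integer_
  }
  single <- nrow(exons) == 1
  structure(
    list(transcript_id = transcript_id,
         strand = match.arg(strand, c("+", "-")),
         exons = exons,
         cds_length = as.integer(cds_length),
         protein_length = as.integer(protein_length),
         last_junction_cdna = if (single) NA_integer_
                              else as.integer(exons$cdna_last[nrow(exons) - 1]),
         relevant_region_end = if (is.null(relevant_region_end)) NULL
                               else as.integer(relevant_region_end),
         single_exon = single),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s: %d exon(s), CDS %d nt, protein %s aa>\n",
              x$transcript_id, nrow(x$exons), x$cds_length,
              ifelse(is.na(x$protein_length), "?", x$protein_length)))
  invisible(x)
}

# Exon index containing an exonic cDNA position (NA if outside the CDS span).
exon_index_of <- function(t, cdna_pos) {
  hit <- which(t$exons$cdna_first <= cdna_pos & t$exons$cdna_last >= cdna_pos)
  if (length(hit) == 0) NA_integer_ else t$exons$index[hit[1]]
}
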