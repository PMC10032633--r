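# Shared helpers for the test suite: quick access to configs, a plain
# missense bundle builder, and a shorthand assigned-call constructor.

fx_configs <- load_gene_config()

fx_cfg <- function(gene = "GENERAL", ...) {
  cfg <- gene_config_for(fx_configs, gene)
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  cfg
}

fx_missense_bundle <- function(gene = "PALB2", cdna = "c.412G>A", ...) {
  t <- make_transcript_fixture(10, 2100, seed = 42,
                               transcript_id = "NM_SYNTH_T.1")
  d <- parse_cdna_description(cdna, gene_symbol = gene,
                              transcript_id = t$transcript_id)
  evidence_bundle(d, t, "missense", ...)
}

acall <- function(code, strength) {
  criterion_call(code, "assigned", strength, explanation = "test")
}

call_state <- function(calls, code) {
  hit <- Filter(function(cl) cl$code == code, calls)
  if (length(hit) == 0) NA_character_ else hit[[1]]$state
}

# independent five-tier band lookup used by several oracles
band_lookup <- function(p) {
  if (p >= 10) "pathogenic"
  else if (p >= 6) "likely_pathogenic"
  else if (p >= 0) "VUS"
  else if (p >= -5) "likely_benign"
  else "benign"
}

class_rank <- c(benign = 1, likely_benign = 2, VUS = 3,
                likely_pathogenic = 4, pathogenic = 5)
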