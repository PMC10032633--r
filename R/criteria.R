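#' @importFrom stats setNames
NULL

# ACMG/AMP criterion codes recognised by the engine.  PP5 and BP6 were retired
# by ClinGen (reputable-source assertions not tied to primary evidence) and are
# rejected everywhere, including manual intake.
.pathogenic_codes <- c("PVS1",
                       paste0("PS", 1:4),
                       paste0("PM", 1:6),
                       paste0("PP", 1:4))
.benign_codes <- c("BA1",
                   paste0("BS", 1:4),
                   paste0("BP", c(1:5, 7)))
.retired_codes <- c("PP5", "BP6")

#' Recognised ACMG/AMP criterion codes
#'
#' Returns the criterion codes the engine understands, split by evidence
#' direction. Retired codes (PP5, BP6) are listed separately; supplying them
#' anywhere (including as manual criteria) is an error.
#'
#' @return A list with elements `pathogenic`, `benign` and `retired`,
#'   each a character vector of codes.
#' @export
criterion_codes <- function() {
  list(pathogenic = .pathogenic_codes,
       benign     = .benign_codes,
       retired    = .retired_codes)
}

.all_codes <- c(.pathogenic_codes, .benign_codes)

# Canonical code order used for deterministic tie-breaks in exclusion rules:
# strength-class order PVS < PS < PM < PP, then BA < BS < BP.
.code_order <- setNames(seq_along(.all_codes), .all_codes)

.strength_levels <- c("standalone", "very_strong", "strong", "moderate",
                      "supporting", "none")

# Point magnitudes of the naturally scaled point system: supporting/moderate/
# strong/very strong map to 1/2/4/8; benign criteria subtract the same values.
# BA1 (standalone) carries no points; it short-circuits the classification.
.strength_points <- c(standalone = 0, very_strong = 8, strong = 4,
                      moderate = 2, supporting = 1, none = 0)

.call_states <- c("assigned", "denied", "not_automated", "not_applicable",
                  "warning")

criterion_sign <- function(code) {
  if (code %in% .pathogenic_codes) 1L
  else if (code %in% .benign_codes) -1L
  else stop("unknown criterion code: ", code, call. = FALSE)
}

#' Construct a criterion call
#'
#' A criterion call records the outcome of evaluating one ACMG/AMP criterion:
#' its state (assigned, denied, not automated, not applicable, or
#' warning-only), the strength at which it was assigned, the signed points it
#' contributes, a human-readable explanation, and its provenance (automated
#' evaluation vs. curator-supplied).
#'
#' Points are non-zero only for `state = "assigned"`: +1/2/4/8 for pathogenic
#' criteria at supporting/moderate/strong/very-strong strength, and the
#' negative of the same magnitudes for benign criteria. The `standalone`
#' strength is valid only for BA1 and carries 0 points (BA1 short-circuits
#' the five-tier classification instead).
#'
#' @param code Criterion code (e.g. `"PVS1"`, `"BS1"`). PP5/BP6 are rejected.
#' @param state One of `"assigned"`, `"denied"`, `"not_automated"`,
#'   `"not_applicable"`, `"warning"`.
#' @param strength One of `"standalone"`, `"very_strong"`, `"strong"`,
#'   `"moderate"`, `"supporting"`, `"none"`. Must be `"none"` unless assigned.
#' @param explanation Human-readable reason for the state.
#' @param source `"automated"` or `"manual"`.
#' @param warnings Character vector of warnings attached to this call.
#' @return An object of class `criterion_call`: a list with fields `code`,
#'   `state`, `strength`, `points`, `explanation`, `source`, `warnings`.
#' @examples
#' criterion_call("PVS1", "assigned", "very_strong", "nonsense, NMD predicted")
#' criterion_call("BS1", "assigned", "strong", "popmax AF above threshold")
#' @export
criterion_call <- function(code, state, strength = "none",
                           explanation = "", source = "automated",
                           warnings = character()) {
  if (code %in% .retired_codes) {
    stop("criterion ", code, " is retired (ClinGen): reputable-source ",
         "assertions not linked to supporting evidence must not be used",
         call. = FALSE)
  }
  if (!code %in% .all_codes) {
    stop("unknown criterion code: ", code, call. = FALSE)
  }
  state <- match.arg(state, .call_states)
  strength <- match.arg(strength, .strength_levels)
  if (state != "assigned" && strength != "none") {
    stop("strength must be 'none' unless state is 'assigned' (", code, ")",
         call. = FALSE)
  }
  if (state == "assigned" && strength == "none") {
    stop("assigned call requires a strength (", code, ")", call. = FALSE)
  }
  if (strength == "standalone" && code != "BA1") {
    stop("standalone strength is only valid for BA1", call. = FALSE)
  }
  points <- if (state == "assigned") {
    criterion_sign(code) * .strength_points[[strength]]
  } else 0L
  structure(
    list(code = code, state = state, strength = strength,
         points = as.integer(points), explanation = explanation,
         source = source, warnings = warnings),
    class = "criterion_call")
}

#' @export
print.criterion_call <- function(x, ...) {
  cat(sprintf("%-5s %-14s %-12s %+d  %s\n", x$code, x$state, x$strength,
              x$points, x$explanation))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Tabulate a list of criterion calls
#'
#' @param calls List of [criterion_call()] objects.
#' @return A data.frame with one row per call (code, state, strength, points,
#'   source, explanation, warnings collapsed with `"; "`).
#' @export
calls_as_data_frame <- function(calls) {
  if (length(calls) == 0) {
    return(data.frame(code = character(), state = character(),
                      strength = character(), points = integer(),
                      source = character(), explanation = character(),
                      warnings = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    code = vapply(calls, `[[`, "", "code"),
    state = vapply(calls, `[[`, "", "state"),
    strength = vapply(calls, `[[`, "", "strength"),
    points = vapply(calls, `[[`, 0L, "points"),
    source = vapply(calls, `[[`, "", "source"),
    explanation = vapply(calls, `[[`, "", "explanation"),
    warnings = vapply(calls, function(cl) paste(cl$warnings, collapse = "; "),
                      ""),
    stringsAsFactors = FALSE)
}
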