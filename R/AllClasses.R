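#' Primer: a named oligonucleotide, written 5' to 3'
#'
#' The unit of the specificity analysis. The 3' end (last base of the string)
#' is the polymerase extension end; mismatch positions everywhere in this
#' package are indexed from it, position 1 being the 3'-terminal base.
#'
#' @slot name Single string, no whitespace.
#' @slot sequence A [Biostrings::DNAString], 5' to 3', length >= 10. IUPAC
#'   degeneracies are allowed.
#' @export
setClass("Primer", representation(name = "character", sequence = "DNAString"))

setValidity("Primer", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name) ||
      grepl("\\s", object@name)) {
    msg <- c(msg, "'name' must be a single non-empty string without whitespace")
  }
  if (length(object@sequence) < 10L) {
    msg <- c(msg, "primer shorter than 10 nt is rejected as implausible")
  }
  chars <- strsplit(as.character(object@sequence), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% .IUPAC_CODES)) {
    msg <- c(msg, "primer sequence must use IUPAC nucleotide codes only")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Primer
#'
#' @param name Primer name (single string, no whitespace).
#' @param sequence Nucleotide string, 5' to 3'. Lowercase and `U` are
#'   normalized; IUPAC degeneracies allowed.
#' @return A [Primer-class] object.
#' @examples
#' primer("COI-F", "ACACCCTAATCAACTGGC")
#' @export
primer <- function(name, sequence) {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- .normalizeResidues(sequence)
  .validateResidues(sequence, name)
  new("Primer", name = as.character(name),
      sequence = Biostrings::DNAString(sequence))
}

#' @describeIn Primer-class Primer name.
#' @param object,x A `Primer`.
#' @export
primerName <- function(x) x@name

#' @describeIn Primer-class Primer sequence as a [Biostrings::DNAString].
#' @export
primerSeq <- function(x) x@sequence

#' @describeIn Primer-class Primer length in nucleotides.
#' @export
primerLength <- function(x) length(x@sequence)

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer %s: 5'-%s-3' (%d nt)\n", object@name,
              as.character(object@sequence), length(object@sequence)))
})

#' Parameters of the amplifiability rule
#'
#' Defaults encode the screening rule used throughout: a template is called
#' unlikely to amplify when either primer's best binding site carries two or
#' more mismatches within the 3'-terminal five bases, or more than three
#' mismatches over the whole primer; in addition an orientation-valid product
#' within `[minLen, maxLen]` must exist.
#'
#' @slot window 3'-terminal window size in bases (default 5).
#' @slot terminalThreshold Mismatch count within the window at or above which
#'   a primer fails (default 2).
#' @slot totalThreshold Maximum tolerated total mismatches per primer
#'   (default 3; a fourth mismatch fails).
#' @slot maxMismatches Search budget for the binding-site scan (default 7;
#'   the rule saturates well below this, the margin is for reporting).
#' @slot minLen,maxLen Accepted product length bounds in bp (defaults 50 and
#'   2000).
#' @export
setClass("SpecificityParams", representation(
  window = "integer", terminalThreshold = "integer",
  totalThreshold = "integer", maxMismatches = "integer",
  minLen = "integer", maxLen = "integer"))

setValidity("SpecificityParams", function(object) {
  msg <- character()
  one <- function(s) length(slot(object, s)) == 1L && !is.na(slot(object, s))
  for (s in slotNames(object)) {
    if (!one(s)) msg <- c(msg, paste0("'", s, "' must be a single integer"))
  }
  if (!length(msg)) {
    if (object@window < 1L) msg <- c(msg, "window must be >= 1")
    if (object@terminalThreshold < 1L)
      msg <- c(msg, "terminalThreshold must be >= 1")
    if (object@totalThreshold < 0L)
      msg <- c(msg, "totalThreshold must be >= 0")
    if (object@terminalThreshold > object@maxMismatches)
      msg <- c(msg, "terminalThreshold must not exceed maxMismatches")
    if (object@minLen < 1L || object@minLen > object@maxLen)
      msg <- c(msg, "need 0 < minLen <= maxLen")
  }
  if (length(msg)) msg else TRUE
})

#' Construct specificity parameters
#'
#' @param window,terminalThreshold,totalThreshold,maxMismatches,minLen,maxLen
#'   See [SpecificityParams-class]; defaults are the standard rule
#'   (window 5, terminal threshold 2, total threshold 3).
#' @return A [SpecificityParams-class] object.
#' @examples
#' specificityParams()
#' specificityParams(window = 3, terminalThreshold = 1)
#' @export
specificityParams <- function(window = 5L, terminalThreshold = 2L,
                              totalThreshold = 3L, maxMismatches = 7L,
                              minLen = 50L, maxLen = 2000L) {
  new("SpecificityParams",
      window = as.integer(window),
      terminalThreshold = as.integer(terminalThreshold),
      totalThreshold = as.integer(totalThreshold),
      maxMismatches = as.integer(maxMismatches),
      minLen = as.integer(minLen), maxLen = as.integer(maxLen))
}

setMethod("show", "SpecificityParams", function(object) {
  cat(sprintf(paste0(
    "SpecificityParams: 3'-window=%d, terminal>=%d or total>%d blocks;",
    " scan budget %d mm; product %d-%d bp\n"),
    object@window, object@terminalThreshold, object@totalThreshold,
    object@maxMismatches, object@minLen, object@maxLen))
})

#' Per-template amplifiability verdict
#'
#' Produced by [classifyTemplate()]. `amplifiable` is `TRUE` iff `reasons`
#' is exactly `"OK"`; otherwise `reasons` enumerates every failed condition
#' (`NO_FWD_SITE`, `NO_REV_SITE`, `TERMINAL_MM_FWD`, `TERMINAL_MM_REV`,
#' `TOTAL_MM_FWD`, `TOTAL_MM_REV`, `NO_VALID_PAIR`).
#'
#' @slot templateId,species Identifiers of the template and its species
#'   label.
#' @slot amplifiable Logical call.
#' @slot reasons Character vector of reason codes.
#' @slot productLength Primary (shortest) predicted product length in bp, or
#'   `NA` when no valid amplicon exists.
#' @slot fwdTerminalMM,fwdTotalMM,revTerminalMM,revTotalMM Best-site mismatch
#'   summaries per primer (`NA` when no site was found within the budget).
#' @export
setClass("SpecificityVerdict", representation(
  templateId = "character", species = "character",
  amplifiable = "logical", reasons = "character",
  productLength = "integer",
  fwdTerminalMM = "integer", fwdTotalMM = "integer",
  revTerminalMM = "integer", revTotalMM = "integer"))

setValidity("SpecificityVerdict", function(object) {
  msg <- character()
  if (object@amplifiable != identical(object@reasons, "OK")) {
    msg <- c(msg, "amplifiable must hold exactly when reasons == 'OK'")
  }
  if (object@amplifiable && is.na(object@productLength)) {
    msg <- c(msg, "an amplifiable verdict must carry a product length")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SpecificityVerdict-class Logical amplifiability call.
#' @param object,x A `SpecificityVerdict`.
#' @export
isAmplifiable <- function(x) x@amplifiable

#' @describeIn SpecificityVerdict-class Reason codes for the call.
#' @export
verdictReasons <- function(x) x@reasons

#' @describeIn SpecificityVerdict-class Primary product length (bp) or `NA`.
#' @export
productLength <- function(x) x@productLength

setMethod("show", "SpecificityVerdict", function(object) {
  cat(sprintf("SpecificityVerdict for %s (%s): %s [%s]%s\n",
              object@templateId, object@species,
              if (object@amplifiable) "AMPLIFIABLE" else "not amplifiable",
              paste(object@reasons, collapse = ","),
              if (is.na(object@productLength)) "" else
                sprintf(", primary product %d bp", object@productLength)))
})

#' Cross-species panel report
#'
#' One row per template of a panel scan, plus summary counts and, when an
#' expectation table was supplied, a confusion matrix (amplifiable = positive).
#'
#' @slot table A `data.frame`, one row per template, fixed column order
#'   `species, template_id, amplifiable, reasons, product_length,
#'   fwd_terminal_mm, fwd_total_mm, rev_terminal_mm, rev_total_mm`.
#' @slot summary Named integer vector `c(amplifiable=, non_amplifiable=)`.
#' @slot confusion Named integer vector `c(tp=, fp=, tn=, fn=)`, all `NA`
#'   when no expectations were supplied.
#' @export
setClass("PanelReport", representation(
  table = "data.frame", summary = "integer", confusion = "integer"))

setValidity("PanelReport", function(object) {
  msg <- character()
  if (!identical(names(object@summary), c("amplifiable", "non_amplifiable"))) {
    msg <- c(msg, "summary must be named c(amplifiable, non_amplifiable)")
  } else if (sum(object@summary) != nrow(object@table)) {
    msg <- c(msg, "summary counts must sum to the row count")
  }
  if (!identical(names(object@confusion), c("tp", "fp", "tn", "fn"))) {
    msg <- c(msg, "confusion must be named c(tp, fp, tn, fn)")
  } else if (!anyNA(object@confusion) &&
             sum(object@confusion) != nrow(object@table)) {
    msg <- c(msg, "confusion counts must sum to the row count")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PanelReport-class The per-template table as a `data.frame`.
#' @param object,x A `PanelReport`.
#' @export
reportTable <- function(x) x@table

#' @describeIn PanelReport-class Amplifiable / non-amplifiable counts.
#' @export
reportSummary <- function(x) x@summary

#' @describeIn PanelReport-class Confusion counts `c(tp, fp, tn, fn)`
#'   (all `NA` when no expectations were supplied).
#' @export
reportConfusion <- function(x) x@confusion

setMethod("show", "PanelReport", function(object) {
  cat(sprintf("PanelReport: %d templates (%d amplifiable, %d not)\n",
              nrow(object@table), object@summary[["amplifiable"]],
              object@summary[["non_amplifiable"]]))
  if (!anyNA(object@confusion)) {
    cat(sprintf("  confusion vs expectations: TP=%d FP=%d TN=%d FN=%d\n",
                object@confusion[["tp"]], object@confusion[["fp"]],
                object@confusion[["tn"]], object@confusion[["fn"]]))
  }
  if (nrow(object@table)) {
    print(utils::head(object@table[, c("species", "template_id",
                                       "amplifiable", "reasons",
                                       "product_length")], 10L))
    if (nrow(object@table) > 10L) cat("  ...\n")
  }
})
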