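.verdictRow <- function(v) {
  data.frame(species = v@species, template_id = v@templateId,
             amplifiable = v@amplifiable,
             reasons = paste(v@reasons, collapse = ";"),
             product_length = v@productLength,
             fwd_terminal_mm = v@fwdTerminalMM, fwd_total_mm = v@fwdTotalMM,
             rev_terminal_mm = v@revTerminalMM, rev_total_mm = v@revTotalMM,
             stringsAsFactors = FALSE)
}

#' Evaluate a primer pair across a multi-species template panel
#'
#' Applies [classifyTemplate()] to every template and assembles the
#' cross-species specificity report. Species labels come from the
#' templates' `mcols()$species` (first token of the FASTA description,
#' falling back to the id) unless `species` is supplied. When an
#' expectation map is given, a confusion matrix is computed with
#' "amplifiable" as the positive class.
#'
#' @param fwd,rev Forward and reverse [Primer-class] objects.
#' @param templates A [Biostrings::DNAStringSet] (e.g. from
#'   [readTemplates()] or [makeCongenerPanel()]).
#' @param params A [SpecificityParams-class].
#' @param expected Optional expectations: a named logical vector
#'   (species -> expected amplifiable) or a data.frame with columns
#'   `species` and `expected_amplifiable`. Species named here but absent
#'   from the panel raise an error.
#' @param species Optional character vector of labels, one per template.
#' @return A [PanelReport-class]; rows follow the input template order.
#' @examples
#' pr <- sikaCoiPrimers()
#' panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 3, seed = 42)
#' evaluatePanel(pr$fwd, pr$rev, panel$templates)
#' @export
evaluatePanel <- function(fwd, rev, templates,
                          params = specificityParams(), expected = NULL,
                          species = NULL) {
  stopifnot(is(templates, "DNAStringSet"), length(templates) >= 1L)
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("template_", seq_along(templates))
  if (is.null(species)) {
    mc <- mcols(templates)
    species <- if (!is.null(mc) && !is.null(mc$species)) mc$species else ids
  }
  stopifnot(length(species) == length(templates))

  rows <- do.call(rbind, lapply(seq_along(templates), function(i) {
    .verdictRow(classifyTemplate(fwd, rev, templates[[i]], params,
                                 templateId = ids[[i]],
                                 species = species[[i]]))
  }))
  rownames(rows) <- NULL

  summary <- c(amplifiable = sum(rows$amplifiable),
               non_amplifiable = sum(!rows$amplifiable))
  confusion <- c(tp = NA_integer_, fp = NA_integer_,
                 tn = NA_integer_, fn = NA_integer_)
  if (!is.null(expected)) {
    if (is.data.frame(expected)) {
      stopifnot(all(c("species", "expected_amplifiable") %in%
                      names(expected)))
      expected <- stats::setNames(as.logical(expected$expected_amplifiable),
                                  expected$species)
    }
    unknown <- setdiff(names(expected), rows$species)
    if (length(unknown)) {
      stop("expected-label table names unknown species: ",
           paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
    exp <- expected[rows$species]
    keep <- !is.na(exp)
    confusion <- c(tp = sum(rows$amplifiable[keep] & exp[keep]),
                   fp = sum(rows$amplifiable[keep] & !exp[keep]),
                   tn = sum(!rows$amplifiable[keep] & !exp[keep]),
                   fn = sum(!rows$amplifiable[keep] & exp[keep]))
  }
  new("PanelReport", table = rows,
      summary = as.integer(summary) |> stats::setNames(names(summary)),
      confusion = vapply(confusion, as.integer, integer(1)))
}

#' Write a panel report to TSV or JSON
#'
#' TSV carries the per-template table with a fixed column order; JSON
#' mirrors the full report (rows, summary, confusion). Both round-trip
#' through [readReport()].
#'
#' @param report A [PanelReport-class].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("tsv", "json")) {
  stopifnot(is(report, "PanelReport"))
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(report@table, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
  } else {
    payload <- list(
      rows = report@table,
      summary = as.list(report@summary),
      confusion = if (anyNA(report@confusion)) NULL else
        as.list(report@confusion))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null")
  }
  invisible(path)
}

#' Read a panel report written by [writeReport()]
#'
#' @param path Path to a `.tsv` or `.json` report.
#' @param format `"tsv"` or `"json"`; guessed from the extension when
#'   missing.
#' @return A [PanelReport-class]. A TSV report cannot carry the confusion
#'   matrix, which is restored as `NA`.
#' @export
readReport <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "tsv"
  }
  format <- match.arg(format, c("tsv", "json"))
  if (format == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    tab$reasons <- as.character(tab$reasons)
    confusion <- c(tp = NA_integer_, fp = NA_integer_,
                   tn = NA_integer_, fn = NA_integer_)
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- as.data.frame(payload$rows, stringsAsFactors = FALSE)
    confusion <- if (is.null(payload$confusion)) {
      c(tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
        fn = NA_integer_)
    } else {
      vapply(payload$confusion[c("tp", "fp", "tn", "fn")], as.integer,
             integer(1))
    }
  }
  tab$product_length <- as.integer(tab$product_length)
  new("PanelReport", table = tab,
      summary = c(amplifiable = sum(tab$amplifiable),
                  non_amplifiable = sum(!tab$amplifiable)) |>
        vapply(as.integer, integer(1)),
      confusion = confusion)
}
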