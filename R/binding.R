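# Coerce the various template representations (DNAString, length-1
# DNAStringSet, character) to a DNAString plus an id.
.asTemplate <- function(template, templateId = NULL) {
  if (is(template, "DNAStringSet")) {
    stopifnot(length(template) == 1L)
    if (is.null(templateId)) templateId <- names(template)
    template <- template[[1L]]
  } else if (is.character(template)) {
    template <- DNAString(.normalizeResidues(template))
  }
  stopifnot(is(template, "DNAString"))
  if (is.null(templateId) || !length(templateId)) templateId <- "template"
  list(seq = template, id = as.character(templateId))
}

.emptySites <- function() {
  DataFrame(template_id = character(), primer = character(),
            strand = character(), start = integer(), end = integer(),
            total_mm = integer(), terminal_mm = integer(),
            ambiguous = logical(),
            positions = IntegerList())
}

# 3'-anchored mismatch positions of a primer laid over a template window.
# `winChars` are plus-strand template characters of the site span; on the
# minus strand the primer reads against the reverse complement of the window.
.mismatchPositions <- function(primerChars, winChars, strand) {
  if (strand == "-") {
    winChars <- rev(unname(.IUPAC_COMPLEMENT[winChars]))
  }
  compat <- .IUPAC_COMPAT[cbind(primerChars, winChars)]
  i <- which(!compat)                       # 5'-indexed
  sort(length(primerChars) - i + 1L)        # position 1 = 3'-terminal base
}

#' Find approximate binding sites of a primer on a template
#'
#' Scans every ungapped placement of the primer on both strands of the
#' template and reports each placement with at most `maxMismatches`
#' mismatches, where a mismatch is a position whose IUPAC base sets do not
#' intersect ([iupacCompatible()]). Candidate placements are located with
#' [Biostrings::matchPattern()] (`fixed = FALSE`); mismatch profiles are
#' then computed per site, indexed from the primer's 3' end (3'-terminal
#' base = position 1).
#'
#' @param primer A [Primer-class].
#' @param template A [Biostrings::DNAString], a length-1
#'   [Biostrings::DNAStringSet], or a nucleotide string.
#' @param maxMismatches Maximum mismatches per site (default 7).
#' @param window 3'-terminal window size used for the `terminal_mm` column
#'   (default 5).
#' @param templateId Template identifier; taken from `names(template)` when
#'   available.
#' @return A [S4Vectors::DataFrame] with one row per site, columns
#'   `template_id`, `primer`, `strand` (`"+"` when the primer matches the
#'   plus strand 5' to 3', `"-"` otherwise), `start`, `end` (1-based closed,
#'   always on the plus strand), `total_mm`, `terminal_mm`, `ambiguous`
#'   (does the template window contain any non-ACGT code?) and `positions`
#'   (an [IRanges::IntegerList] of 3'-anchored mismatch positions). Rows are
#'   sorted by `(start, strand)` with `"+"` before `"-"`. A template shorter
#'   than the primer yields zero rows.
#' @examples
#' p <- sikaCoiPrimers()$fwd
#' tmpl <- paste0(strrep("T", 10), as.character(primerSeq(p)), strrep("A", 10))
#' findBindingSites(p, tmpl, maxMismatches = 0)
#' @export
findBindingSites <- function(primer, template, maxMismatches = 7L,
                             window = 5L, templateId = NULL) {
  stopifnot(is(primer, "Primer"), maxMismatches >= 0L, window >= 1L)
  tpl <- .asTemplate(template, templateId)
  L <- primerLength(primer)
  if (length(tpl$seq) < L) return(.emptySites())
  tplChars <- strsplit(as.character(tpl$seq), "", fixed = TRUE)[[1L]]
  primerChars <- strsplit(as.character(primerSeq(primer)), "",
                          fixed = TRUE)[[1L]]

  scanStrand <- function(strand) {
    pat <- if (strand == "+") primerSeq(primer) else
      reverseComplement(primerSeq(primer))
    hits <- matchPattern(pat, tpl$seq, max.mismatch = maxMismatches,
                         fixed = FALSE)
    if (!length(hits)) return(NULL)
    s <- start(hits); e <- end(hits)
    # drop placements hanging over the template ends: only fully contained
    # ungapped alignments are in the model
    inb <- s >= 1L & e <= length(tpl$seq)
    if (!any(inb)) return(NULL)
    s <- s[inb]; e <- e[inb]
    pos <- lapply(seq_along(s), function(k) {
      .mismatchPositions(primerChars, tplChars[s[k]:e[k]], strand)
    })
    amb <- vapply(seq_along(s), function(k) {
      any(!tplChars[s[k]:e[k]] %in% c("A", "C", "G", "T"))
    }, logical(1))
    list(strand = rep(strand, length(s)), start = s, end = e, pos = pos,
         amb = amb)
  }

  parts <- Filter(Negate(is.null), list(scanStrand("+"), scanStrand("-")))
  if (!length(parts)) return(.emptySites())
  strand <- unlist(lapply(parts, `[[`, "strand"))
  s <- unlist(lapply(parts, `[[`, "start"))
  e <- unlist(lapply(parts, `[[`, "end"))
  pos <- do.call(c, lapply(parts, `[[`, "pos"))
  amb <- unlist(lapply(parts, `[[`, "amb"))
  keep <- !duplicated(paste0(s, strand))
  ord <- order(s[keep], strand[keep] == "-")
  idx <- which(keep)[ord]
  DataFrame(template_id = tpl$id, primer = primerName(primer),
            strand = strand[idx], start = s[idx], end = e[idx],
            total_mm = lengths(pos)[idx],
            terminal_mm = vapply(pos, function(p) sum(p <= window),
                                 integer(1))[idx],
            ambiguous = amb[idx],
            positions = IntegerList(pos[idx]))
}

#' Count mismatches inside the 3'-terminal window
#'
#' @param x A sites [S4Vectors::DataFrame] from [findBindingSites()], or an
#'   integer vector of 3'-anchored mismatch positions.
#' @param window Window size in bases from the 3' end (>= 1).
#' @return Integer vector: per-site (or per-vector) counts of mismatch
#'   positions `<= window`.
#' @examples
#' terminalMismatchCount(c(1L, 5L, 6L), window = 5)  # 2
#' @export
terminalMismatchCount <- function(x, window = 5L) {
  stopifnot(window >= 1L)
  if (is(x, "DataFrame")) {
    return(vapply(as.list(x$positions), function(p) sum(p <= window),
                  integer(1)))
  }
  sum(as.integer(x) <= window)
}

#' Pick the most plausible binding site of a primer on a template
#'
#' Orders sites by `(terminal_mm, total_mm, start, strand)` with `"+"`
#' before `"-"` and returns the first: the 3'-window count dominates because
#' terminal mismatches are what block polymerase extension.
#'
#' @param sites A sites [S4Vectors::DataFrame] for one (primer, template)
#'   pair.
#' @return A one-row [S4Vectors::DataFrame], or `NULL` when `sites` is
#'   empty.
#' @export
bestSite <- function(sites) {
  if (is.null(sites) || nrow(sites) == 0L) return(NULL)
  ord <- order(sites$terminal_mm, sites$total_mm, sites$start,
               sites$strand == "-")
  sites[ord[1L], , drop = FALSE]
}
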