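.emptyAmplicons <- function() {
  DataFrame(template_id = character(),
            fwd_start = integer(), fwd_end = integer(),
            fwd_strand = character(),
            rev_start = integer(), rev_end = integer(),
            rev_strand = character(),
            start = integer(), end = integer(),
            product_length = integer(),
            fwd_total_mm = integer(), fwd_terminal_mm = integer(),
            rev_total_mm = integer(), rev_terminal_mm = integer())
}

#' Pair binding sites into predicted amplicons
#'
#' Every (forward-site, reverse-site) pair on opposite strands whose 3' ends
#' converge (each primer extends toward the other, footprints not
#' overlapping) and whose product length falls within `[minLen, maxLen]`
#' becomes a predicted amplicon. Product length includes both primer
#' footprints: for a plus-strand forward site and minus-strand reverse site
#' it is `rev_end - fwd_start + 1`. Both role assignments are supported, so
#' templates deposited in either orientation produce the same amplicons.
#'
#' @param fwdSites,revSites Site tables from [findBindingSites()] for the
#'   forward and reverse primer on the same template.
#' @param minLen,maxLen Inclusive product-length bounds in bp.
#' @return A [S4Vectors::DataFrame], one row per amplicon, sorted by
#'   `product_length` ascending (the shortest is the "primary" product);
#'   duplicate spans are removed. Zero rows when no valid pair exists.
#' @examples
#' pr <- sikaCoiPrimers()
#' syn <- plantAmplicon(randomTemplate(700, seed = 1), pr$fwd, pr$rev,
#'                      fwdStart = 11, productLength = 526)
#' f <- findBindingSites(pr$fwd, syn$template)
#' r <- findBindingSites(pr$rev, syn$template)
#' predictAmplicons(f, r)$product_length
#' @export
predictAmplicons <- function(fwdSites, revSites, minLen = 50L,
                             maxLen = 2000L) {
  stopifnot(minLen >= 1L, minLen <= maxLen)
  out <- .emptyAmplicons()
  if (is.null(fwdSites) || is.null(revSites) ||
      nrow(fwdSites) == 0L || nrow(revSites) == 0L) return(out)

  # One orientation at a time: the plus-strand member extends rightwards,
  # the minus-strand member leftwards; they converge when the minus
  # footprint lies strictly downstream of the plus footprint.
  build <- function(f, r) {
    g <- expand.grid(i = seq_len(nrow(f)), j = seq_len(nrow(r)))
    fwdOnPlus <- f$strand[1L] == "+"
    ls <- if (fwdOnPlus) f$start[g$i] else r$start[g$j]
    le <- if (fwdOnPlus) f$end[g$i] else r$end[g$j]
    rs <- if (fwdOnPlus) r$start[g$j] else f$start[g$i]
    re <- if (fwdOnPlus) r$end[g$j] else f$end[g$i]
    len <- re - ls + 1L
    ok <- rs > le & len >= minLen & len <= maxLen
    if (!any(ok)) return(NULL)
    i <- g$i[ok]; j <- g$j[ok]
    DataFrame(
      template_id = f$template_id[i],
      fwd_start = f$start[i], fwd_end = f$end[i], fwd_strand = f$strand[i],
      rev_start = r$start[j], rev_end = r$end[j], rev_strand = r$strand[j],
      start = ls[ok], end = re[ok], product_length = len[ok],
      fwd_total_mm = f$total_mm[i], fwd_terminal_mm = f$terminal_mm[i],
      rev_total_mm = r$total_mm[j], rev_terminal_mm = r$terminal_mm[j])
  }

  fP <- fwdSites[fwdSites$strand == "+", , drop = FALSE]
  rM <- revSites[revSites$strand == "-", , drop = FALSE]
  fM <- fwdSites[fwdSites$strand == "-", , drop = FALSE]
  rP <- revSites[revSites$strand == "+", , drop = FALSE]

  parts <- Filter(Negate(is.null),
                  list(if (nrow(fP) && nrow(rM)) build(fP, rM),
                       if (nrow(fM) && nrow(rP)) build(fM, rP)))
  if (length(parts)) out <- do.call(rbind, parts)
  if (!nrow(out)) return(out)
  out <- out[!duplicated(paste(out$start, out$end, out$fwd_strand)), ,
             drop = FALSE]
  out[order(out$product_length, out$start), , drop = FALSE]
}

#' Extract the predicted product sequence
#'
#' Returns the template residues spanned by the amplicon, oriented so the
#' product begins with the forward primer's footprint (reverse-complemented
#' when the forward primer sits on the minus strand).
#'
#' @param template The template sequence (any form accepted by
#'   [findBindingSites()]).
#' @param amplicon One row of the table returned by [predictAmplicons()].
#' @return A nucleotide string of length `product_length`.
#' @export
extractProduct <- function(template, amplicon) {
  stopifnot(nrow(amplicon) == 1L)
  tpl <- .asTemplate(template)
  if (amplicon$start < 1L || amplicon$end > length(tpl$seq)) {
    stop("amplicon span [", amplicon$start, ",", amplicon$end,
         "] outside template ", tpl$id, " (length ", length(tpl$seq), ")",
         call. = FALSE)
  }
  s <- as.character(tpl$seq[amplicon$start:amplicon$end])
  if (amplicon$fwd_strand == "-") s <- revComp(s)
  s
}
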