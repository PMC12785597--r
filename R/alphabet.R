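# IUPAC machinery shared by every stage. Compatibility is set intersection of
# the base sets denoted by two codes; a primer-template position is a mismatch
# iff the sets are disjoint. Built once at install time from Biostrings'
# canonical code map.
.IUPAC_CODES <- names(Biostrings::IUPAC_CODE_MAP)

.IUPAC_SETS <- lapply(Biostrings::IUPAC_CODE_MAP, function(s) {
  strsplit(s, "", fixed = TRUE)[[1L]]
})

.IUPAC_COMPAT <- local({
  m <- matrix(FALSE, length(.IUPAC_CODES), length(.IUPAC_CODES),
              dimnames = list(.IUPAC_CODES, .IUPAC_CODES))
  for (a in .IUPAC_CODES) for (b in .IUPAC_CODES) {
    m[a, b] <- length(intersect(.IUPAC_SETS[[a]], .IUPAC_SETS[[b]])) > 0L
  }
  m
})

.IUPAC_COMPLEMENT <- local({
  x <- vapply(.IUPAC_CODES, function(code) {
    as.character(Biostrings::complement(Biostrings::DNAString(code)))
  }, character(1))
  names(x) <- .IUPAC_CODES
  x
})

.checkCodes <- function(x, what = "nucleotide code") {
  bad <- setdiff(unique(x), .IUPAC_CODES)
  if (length(bad)) {
    stop("invalid ", what, ": ", paste(sQuote(bad), collapse = ", "),
         " (expected IUPAC codes ", paste(.IUPAC_CODES, collapse = ""), ")",
         call. = FALSE)
  }
  invisible(x)
}

#' Are two IUPAC nucleotide codes compatible?
#'
#' Two codes are compatible when the base sets they denote intersect, e.g.
#' `A` vs `R` (= A/G) is compatible, `A` vs `Y` (= C/T) is not. A
#' primer-template position counts as a mismatch exactly when this returns
#' `FALSE`, so an `N` in a template never contributes a mismatch.
#'
#' @param a,b Character vectors of single IUPAC codes (recycled to a common
#'   length).
#' @return Logical vector.
#' @examples
#' iupacCompatible("A", "R")
#' iupacCompatible(c("A", "R"), c("Y", "Y"))
#' @export
iupacCompatible <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  .checkCodes(c(a, b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  .IUPAC_COMPAT[cbind(a, b)]
}

#' Reverse complement of a nucleotide string
#'
#' Full IUPAC complementation (R<->Y, K<->M, B<->V, D<->H; S, W, N map to
#' themselves), then reversal. Thin validated wrapper around
#' [Biostrings::reverseComplement()] for plain character input.
#'
#' @param x A nucleotide string (character scalar) or a
#'   [Biostrings::DNAString].
#' @return Character scalar, the reverse complement.
#' @examples
#' revComp("ACACCCTAATCAACTGGC")
#' @export
revComp <- function(x) {
  if (is(x, "DNAString")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  x <- .normalizeResidues(x)
  .checkCodes(strsplit(x, "", fixed = TRUE)[[1L]])
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Normalize raw sequence text: uppercase, U -> T. Returns the string; callers
# validate the alphabet afterwards so errors can name the record.
.normalizeResidues <- function(x) {
  chartr("U", "T", toupper(x))
}

.validateResidues <- function(x, id) {
  if (!nzchar(x)) {
    stop("empty sequence for record ", sQuote(id), call. = FALSE)
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (any(chars %in% c("-", "."))) {
    stop("gap characters ('-'/'.') in record ", sQuote(id),
         ": supply unaligned sequences", call. = FALSE)
  }
  bad <- setdiff(unique(chars), .IUPAC_CODES)
  if (length(bad)) {
    stop("non-IUPAC character ", paste(sQuote(bad), collapse = ", "),
         " in record ", sQuote(id), call. = FALSE)
  }
  invisible(x)
}
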