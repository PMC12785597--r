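#' Apply the amplifiability rule to one primer's best binding site
#'
#' A primer fails on a template when no binding site was found within the
#' search budget, when the best site carries `terminalThreshold` or more
#' mismatches inside the 3'-terminal window, or when it carries more than
#' `totalThreshold` mismatches over the whole primer. With the default rule
#' (window 5, terminal 2, total 3): two mismatches in the last five 3' bases
#' block extension, as does a fourth mismatch anywhere; three mismatches
#' outside the window are tolerated.
#'
#' @param site A one-row site table (from [bestSite()]) or `NULL` when the
#'   primer found no site.
#' @param params A [SpecificityParams-class].
#' @return A list with `pass` (logical) and `reasons` (character vector;
#'   `"OK"` on pass, otherwise every triggered code among `NO_SITE`,
#'   `TERMINAL_MM`, `TOTAL_MM`).
#' @export
classifyPrimerSite <- function(site, params = specificityParams()) {
  stopifnot(is(params, "SpecificityParams"))
  if (is.null(site) || nrow(site) == 0L) {
    return(list(pass = FALSE, reasons = "NO_SITE"))
  }
  stopifnot(nrow(site) == 1L)
  terminal <- terminalMismatchCount(site$positions[[1L]], params@window)
  reasons <- character()
  if (terminal >= params@terminalThreshold) reasons <- c(reasons, "TERMINAL_MM")
  if (site$total_mm > params@totalThreshold) reasons <- c(reasons, "TOTAL_MM")
  if (length(reasons)) list(pass = FALSE, reasons = reasons)
  else list(pass = TRUE, reasons = "OK")
}

#' Call amplifiability of a primer pair on one template
#'
#' Runs the full per-template pipeline: binding-site search for both primers
#' on both strands, best-site selection, the per-primer amplifiability rule,
#' and amplicon pairing. The template is called amplifiable only when both
#' primers individually pass and at least one orientation-valid product
#' within the length bounds exists — two passing but diverging or absurdly
#' distant sites do not count as amplification.
#'
#' @param fwd,rev Forward and reverse [Primer-class] objects.
#' @param template A template (any form accepted by [findBindingSites()]).
#' @param params A [SpecificityParams-class].
#' @param templateId,species Identifiers; default to the template's name.
#' @return A [SpecificityVerdict-class].
#' @examples
#' pr <- sikaCoiPrimers()
#' syn <- plantAmplicon(randomTemplate(700, seed = 7), pr$fwd, pr$rev,
#'                      fwdStart = 61, productLength = 526)
#' classifyTemplate(pr$fwd, pr$rev, syn$template)
#' @export
classifyTemplate <- function(fwd, rev, template,
                             params = specificityParams(),
                             templateId = NULL, species = NULL) {
  stopifnot(is(fwd, "Primer"), is(rev, "Primer"),
            is(params, "SpecificityParams"))
  tpl <- .asTemplate(template, templateId)
  if (is.null(species)) {
    mc <- if (is(template, "DNAStringSet")) mcols(template) else NULL
    species <- if (!is.null(mc) && !is.null(mc$species)) mc$species[[1L]]
               else tpl$id
  }
  fwdSites <- findBindingSites(fwd, tpl$seq, params@maxMismatches,
                               params@window, tpl$id)
  revSites <- findBindingSites(rev, tpl$seq, params@maxMismatches,
                               params@window, tpl$id)
  bf <- bestSite(fwdSites)
  br <- bestSite(revSites)
  cf <- classifyPrimerSite(bf, params)
  cr <- classifyPrimerSite(br, params)
  # Only sites that individually satisfy the extension rule can seed a
  # product: pairing the others would report amplicons that no polymerase
  # would make, and could shadow the true product as "primary".
  passes <- function(s) {
    s$terminal_mm < params@terminalThreshold &
      s$total_mm <= params@totalThreshold
  }
  amps <- predictAmplicons(fwdSites[passes(fwdSites), , drop = FALSE],
                           revSites[passes(revSites), , drop = FALSE],
                           params@minLen, params@maxLen)

  tagRole <- function(codes, role) {
    vapply(codes, function(x) switch(x,
      NO_SITE = paste0("NO_", role, "_SITE"),
      paste0(x, "_", role)), character(1), USE.NAMES = FALSE)
  }
  reasons <- character()
  if (!cf$pass) reasons <- c(reasons, tagRole(cf$reasons, "FWD"))
  if (!cr$pass) reasons <- c(reasons, tagRole(cr$reasons, "REV"))
  if (cf$pass && cr$pass && nrow(amps) == 0L) {
    reasons <- c(reasons, "NO_VALID_PAIR")
  }
  amplifiable <- !length(reasons)
  if (amplifiable) reasons <- "OK"

  siteInt <- function(s, col) if (is.null(s)) NA_integer_ else
    as.integer(s[[col]])
  new("SpecificityVerdict",
      templateId = tpl$id, species = as.character(species),
      amplifiable = amplifiable, reasons = reasons,
      productLength = if (nrow(amps)) as.integer(amps$product_length[1L])
                      else NA_integer_,
      fwdTerminalMM = siteInt(bf, "terminal_mm"),
      fwdTotalMM = siteInt(bf, "total_mm"),
      revTerminalMM = siteInt(br, "terminal_mm"),
      revTotalMM = siteInt(br, "total_mm"))
}
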