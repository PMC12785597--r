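#' Random nucleotide template
#'
#' Reproducible i.i.d. A/C/G/T background with a target GC fraction. The
#' default GC of 0.42 is typical of cervid mitochondrial protein-coding
#' regions, the sequence class the generator emulates.
#'
#' @param length Template length in bp (>= 1).
#' @param gc Target GC fraction in `[0, 1]`.
#' @param seed Integer seed; the same seed always yields the same sequence.
#'   `NULL` uses (and advances) the current RNG state.
#' @param id Record id.
#' @return A length-1 named [Biostrings::DNAStringSet] with `mcols()`
#'   (`id`, `description`, `species`).
#' @examples
#' randomTemplate(50, seed = 1)
#' @export
randomTemplate <- function(length, gc = 0.42, seed = NULL,
                           id = "random_template") {
  if (length < 1L) stop("template length must be >= 1", call. = FALSE)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]", call. = FALSE)
  chars <- .withSeed(seed, sample(c("A", "C", "G", "T"), length,
                                  replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2,
                                           gc / 2, (1 - gc) / 2)))
  out <- DNAStringSet(paste(chars, collapse = ""))
  names(out) <- id
  mcols(out) <- DataFrame(id = id, description = "", species = id)
  out
}

#' Specify planted mismatches for one primer
#'
#' @param role `"forward"` or `"reverse"`.
#' @param positions Integer vector of mismatch positions indexed from the
#'   primer's 3' end (3'-terminal base = 1); unique, within the primer.
#' @return A list of class `MismatchSpec`.
#' @examples
#' mismatchSpec("reverse", c(1, 3))  # two 3'-terminal-window mismatches
#' @export
mismatchSpec <- function(role = c("forward", "reverse"), positions) {
  role <- match.arg(role)
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && any(positions < 1L)) {
    stop("mismatch positions must be >= 1 (3'-anchored)", call. = FALSE)
  }
  structure(list(role = role, positions = positions),
            class = "MismatchSpec")
}

# Independent amplifiability predicate used for planted ground truth.
# Deliberately coded as bare arithmetic on position vectors, sharing no code
# with classifyPrimerSite(), so generator truth can serve as an oracle for
# the pipeline.
#' Expected amplifiability of a planted template
#'
#' Ground-truth predicate of the generator: a plant is expected to amplify
#' unless some primer carries `terminalThreshold` or more planted mismatches
#' within the 3'-terminal `window` bases, or more than `totalThreshold`
#' planted mismatches in total. Implemented independently of the pipeline's
#' classifier so the two can be compared as implementation vs oracle.
#'
#' @param specs List of [mismatchSpec()] objects (possibly empty).
#' @param window,terminalThreshold,totalThreshold Rule parameters
#'   (defaults 5, 2, 3).
#' @return Logical scalar.
#' @export
expectedAmplifiable <- function(specs, window = 5L, terminalThreshold = 2L,
                                totalThreshold = 3L) {
  for (sp in specs) {
    p <- sp$positions
    if (sum(p <= window) >= terminalThreshold) return(FALSE)
    if (length(p) > totalThreshold) return(FALSE)
  }
  TRUE
}

# Pick, per position, a concrete base drawn from the set a possibly
# degenerate code denotes (seeded upstream).
.concreteBase <- function(code) {
  set <- .IUPAC_SETS[[code]]
  if (length(set) == 1L) set else sample(set, 1L)
}

# A base whose plus-strand identity breaks IUPAC compatibility with the
# primer base bound at that position. `complemented` = TRUE for minus-strand
# footprints, where the primer reads the complement of the plus strand.
.incompatibleBase <- function(primerBase, complemented) {
  cand <- c("A", "C", "G", "T")
  ok <- vapply(cand, function(b) {
    tplBase <- if (complemented) .IUPAC_COMPLEMENT[[b]] else b
    !.IUPAC_COMPAT[primerBase, tplBase]
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand)) {
    stop("cannot place a mismatch against fully degenerate primer base 'N'",
         call. = FALSE)
  }
  if (length(cand) == 1L) cand else sample(cand, 1L)
}

#' Plant a primer-pair amplicon into a background template
#'
#' Overwrites the background so the forward primer's footprint starts at
#' `fwdStart` (plus strand) and the reverse primer's reverse complement ends
#' at `fwdStart + productLength - 1`, giving a product of exactly
#' `productLength` bp. Each requested mismatch position is then mutated to a
#' base that is NOT IUPAC-compatible with the primer base bound there (never
#' to an ambiguity code), so planted mismatch counts are unambiguous. The
#' returned truth record carries the expected verdict computed by
#' [expectedAmplifiable()].
#'
#' @param background A length-1 [Biostrings::DNAStringSet] (e.g. from
#'   [randomTemplate()]).
#' @param fwd,rev The primer pair ([Primer-class]).
#' @param fwdStart 1-based start of the forward footprint.
#' @param productLength Product length in bp, footprints included; must be
#'   at least the two primer lengths combined.
#' @param specs List of [mismatchSpec()] objects.
#' @param seed Integer seed for the mutation-base choices; `NULL` uses the
#'   current RNG state.
#' @param id Template id for the output record (default: background's id).
#' @param species Species label (default: `id`).
#' @return A list: `template` (length-1 named `DNAStringSet`) and `truth`
#'   (one-row `data.frame`: `template_id`, `species`, `fwd_start`,
#'   `product_length`, `fwd_mm_positions`, `rev_mm_positions`
#'   (comma-separated, 3'-anchored), `expected_amplifiable`, `seed`).
#' @examples
#' pr <- sikaCoiPrimers()
#' syn <- plantAmplicon(randomTemplate(700, seed = 3), pr$fwd, pr$rev,
#'                      fwdStart = 100, productLength = 526,
#'                      specs = list(mismatchSpec("reverse", c(1, 3))),
#'                      seed = 3)
#' syn$truth$expected_amplifiable
#' @export
plantAmplicon <- function(background, fwd, rev, fwdStart, productLength,
                          specs = list(), seed = NULL, id = NULL,
                          species = NULL) {
  stopifnot(is(background, "DNAStringSet"), length(background) == 1L,
            is(fwd, "Primer"), is(rev, "Primer"))
  fwdStart <- as.integer(fwdStart)
  productLength <- as.integer(productLength)
  Lf <- primerLength(fwd)
  Lr <- primerLength(rev)
  n <- width(background)[[1L]]
  if (fwdStart < 1L || fwdStart + productLength - 1L > n) {
    stop("planted amplicon [", fwdStart, ", ",
         fwdStart + productLength - 1L, "] exceeds background length ", n,
         call. = FALSE)
  }
  if (productLength < Lf + Lr) {
    stop("productLength ", productLength,
         " smaller than the two primer footprints (", Lf + Lr,
         " bp): footprints would overlap", call. = FALSE)
  }
  for (sp in specs) {
    stopifnot(inherits(sp, "MismatchSpec"))
    lim <- if (sp$role == "forward") Lf else Lr
    if (length(sp$positions) && max(sp$positions) > lim) {
      stop("mismatch position ", max(sp$positions), " outside the ",
           sp$role, " primer (length ", lim, ")", call. = FALSE)
    }
  }
  if (is.null(id)) id <- names(background)[[1L]]
  if (is.null(species)) species <- id

  fwdChars <- strsplit(as.character(primerSeq(fwd)), "", fixed = TRUE)[[1L]]
  revChars <- strsplit(as.character(primerSeq(rev)), "", fixed = TRUE)[[1L]]
  revSiteStart <- fwdStart + productLength - Lr

  chars <- .withSeed(seed, {
    chars <- strsplit(as.character(background[[1L]]), "", fixed = TRUE)[[1L]]
    # perfect footprints first (degenerate primer bases get a concrete base)
    chars[fwdStart:(fwdStart + Lf - 1L)] <-
      vapply(fwdChars, .concreteBase, character(1), USE.NAMES = FALSE)
    chars[revSiteStart:(revSiteStart + Lr - 1L)] <-
      vapply(rev(unname(.IUPAC_COMPLEMENT[revChars])), .concreteBase,
             character(1), USE.NAMES = FALSE)
    # then the planted mismatches
    for (sp in specs) {
      for (p in sp$positions) {
        if (sp$role == "forward") {
          coord <- fwdStart + Lf - p             # 5'-index Lf - p + 1
          chars[coord] <- .incompatibleBase(fwdChars[Lf - p + 1L],
                                            complemented = FALSE)
        } else {
          coord <- revSiteStart + p - 1L
          chars[coord] <- .incompatibleBase(revChars[Lr - p + 1L],
                                            complemented = TRUE)
        }
      }
    }
    chars
  })

  template <- DNAStringSet(paste(chars, collapse = ""))
  names(template) <- id
  mcols(template) <- DataFrame(id = id, description = species,
                               species = species)
  fmt <- function(role) {
    p <- unlist(lapply(specs, function(sp)
      if (sp$role == role) sp$positions else integer()))
    paste(sort(p), collapse = ",")
  }
  truth <- data.frame(
    template_id = id, species = species, fwd_start = fwdStart,
    product_length = productLength,
    fwd_mm_positions = fmt("forward"), rev_mm_positions = fmt("reverse"),
    expected_amplifiable = expectedAmplifiable(specs),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    stringsAsFactors = FALSE)
  list(template = template, truth = truth)
}

# Generator-local sliding scan, independent of the binding module: every
# offset on both strands whose placement is "extensible" (fewer than
# `terminalLimit` mismatches in the 3'-terminal window and at most
# `totalLimit` in total). Used to verify that a planted template's truth
# holds by construction — low-complexity primers can otherwise bind a
# shifted copy of their own footprint.
.extensiblePlacements <- function(chars, primerChars, window = 5L,
                                  terminalLimit = 2L, totalLimit = 3L) {
  n <- length(chars)
  L <- length(primerChars)
  empty <- data.frame(start = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (n < L) return(empty)
  nOff <- n - L + 1L
  res <- list(empty)
  for (strand in c("+", "-")) {
    pc <- if (strand == "+") primerChars
          else rev(unname(.IUPAC_COMPLEMENT[primerChars]))
    tot <- integer(nOff)
    ter <- integer(nOff)
    for (i in seq_len(L)) {
      mm <- !.IUPAC_COMPAT[cbind(pc[i], chars[i:(nOff + i - 1L)])]
      tot <- tot + mm
      pos3 <- if (strand == "+") L - i + 1L else i
      if (pos3 <= window) ter <- ter + mm
    }
    keep <- which(ter < terminalLimit & tot <= totalLimit)
    if (length(keep)) {
      res[[length(res) + 1L]] <- data.frame(start = keep, strand = strand,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# Does a planted template carry exactly the extensible placements its truth
# record promises? Per primer: the planted footprint alone when the primer's
# planted mismatches let it pass, no placement at all otherwise.
.plantIsClean <- function(template, fwd, rev, truth, window = 5L,
                          terminalLimit = 2L, totalLimit = 3L) {
  chars <- strsplit(as.character(template[[1L]]), "", fixed = TRUE)[[1L]]
  parsePos <- function(s) if (nzchar(s)) as.integer(strsplit(
    s, ",", fixed = TRUE)[[1L]]) else integer()
  check <- function(p, positions, start, strand) {
    pc <- strsplit(as.character(primerSeq(p)), "", fixed = TRUE)[[1L]]
    got <- .extensiblePlacements(chars, pc, window, terminalLimit,
                                 totalLimit)
    passes <- sum(positions <= window) < terminalLimit &&
      length(positions) <= totalLimit
    if (passes) {
      nrow(got) == 1L && got$start == start && got$strand == strand
    } else {
      nrow(got) == 0L
    }
  }
  revStart <- truth$fwd_start + truth$product_length - primerLength(rev)
  check(fwd, parsePos(truth$fwd_mm_positions), truth$fwd_start, "+") &&
    check(rev, parsePos(truth$rev_mm_positions), revStart, "-")
}

# Default decoy mismatch plans: congener-like profiles with mismatches
# concentrated at primer 3' termini, plus some >3-total profiles. All are
# non-amplifiable under the default rule, mirroring a specificity panel
# where only the target amplifies.
.defaultDecoySpecs <- function(n) {
  pool <- list(
    list(mismatchSpec("reverse", c(1, 3))),
    list(mismatchSpec("forward", c(1, 2))),
    list(mismatchSpec("forward", c(2, 5))),
    list(mismatchSpec("forward", c(7, 10, 14, 18))),
    list(mismatchSpec("reverse", c(6, 9, 12, 15))),
    list(mismatchSpec("forward", c(1, 4)), mismatchSpec("reverse", c(2, 8))),
    list(mismatchSpec("reverse", c(1, 2, 3))),
    list(mismatchSpec("forward", c(3, 5)), mismatchSpec("reverse", c(1, 5))),
    list(mismatchSpec("forward", c(6, 8, 11, 13, 17))))
  lapply(seq_len(n), function(i) pool[[(i - 1L) %% length(pool) + 1L]])
}

#' Generate a congener-style specificity panel with planted ground truth
#'
#' Builds one target template whose planted binding sites match both primers
#' perfectly (product length `productLength`, default 526 bp) plus
#' `nDecoys` decoy templates carrying planted mismatches — by default
#' congener-like profiles concentrated at the primer 3' termini, all
#' expected non-amplifiable. Decoys sit on independent random backgrounds
#' (`mode = "independent"`) or on mutated copies of the target template
#' (`mode = "mutant"`, closer to real congeners). Everything is seeded and
#' reproducible.
#'
#' @param fwd,rev The primer pair ([Primer-class]).
#' @param nDecoys Number of decoy templates (>= 0; default 9, giving the
#'   classic 10-lane panel).
#' @param decoySpecs Optional list (length `nDecoys`) of per-decoy lists of
#'   [mismatchSpec()] objects; default profiles as above.
#' @param productLength Planted product length in bp (default 526).
#' @param templateLength Background length in bp (default 1200).
#' @param gc Background GC fraction (default 0.42).
#' @param seed Integer seed governing backgrounds, site placement and
#'   mutation choices.
#' @param mode `"independent"` or `"mutant"` decoy backgrounds.
#' @return A list: `templates` (a named [Biostrings::DNAStringSet]:
#'   `target`, `decoy_1`, ...), `truth` (a `data.frame`, one row per
#'   template, as in [plantAmplicon()]).
#' @examples
#' pr <- sikaCoiPrimers()
#' panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 2, seed = 1)
#' panel$truth[, c("template_id", "expected_amplifiable")]
#' @export
makeCongenerPanel <- function(fwd, rev, nDecoys = 9L, decoySpecs = NULL,
                              productLength = 526L, templateLength = 1200L,
                              gc = 0.42, seed = 1L,
                              mode = c("independent", "mutant")) {
  mode <- match.arg(mode)
  nDecoys <- as.integer(nDecoys)
  stopifnot(nDecoys >= 0L,
            templateLength >= productLength + 2L)
  if (is.null(decoySpecs)) decoySpecs <- .defaultDecoySpecs(nDecoys)
  if (length(decoySpecs) != nDecoys) {
    stop("decoySpecs must have one entry per decoy (", nDecoys,
         "), got ", length(decoySpecs), call. = FALSE)
  }

  .withSeed(seed, {
    ids <- c("target", if (nDecoys) paste0("decoy_", seq_len(nDecoys)))
    allSpecs <- c(list(list()), decoySpecs)
    maxStart <- templateLength - productLength + 1L
    maxAttempts <- 100L

    # Draw, plant, verify: backgrounds (and site placement) are redrawn
    # until every planted template carries exactly the extensible
    # placements its truth promises, so truth holds by construction even
    # for low-complexity primers whose shifted footprints can rebind.
    for (attempt in seq_len(maxAttempts)) {
      starts <- sample.int(maxStart, nDecoys + 1L, replace = TRUE)
      subSeeds <- sample.int(.Machine$integer.max - 1L, nDecoys + 1L)
      targetBg <- randomTemplate(templateLength, gc,
                                 seed = subSeeds[[1L]], id = "target")
      out <- vector("list", nDecoys + 1L)
      clean <- TRUE
      for (i in seq_along(ids)) {
        bg <- if (mode == "mutant" && i > 1L) targetBg
              else randomTemplate(templateLength, gc, seed = subSeeds[[i]],
                                  id = ids[[i]])
        fs <- if (mode == "mutant" && i > 1L) starts[[1L]] else starts[[i]]
        out[[i]] <- plantAmplicon(bg, fwd, rev, fwdStart = fs,
                                  productLength = productLength,
                                  specs = allSpecs[[i]],
                                  seed = subSeeds[[i]], id = ids[[i]],
                                  species = ids[[i]])
        if (!.plantIsClean(out[[i]]$template, fwd, rev, out[[i]]$truth)) {
          clean <- FALSE
          break
        }
      }
      if (clean) break
    }
    if (!clean) {
      stop("could not build a clean panel in ", maxAttempts,
           " attempts; primers may be too low-complexity for ",
           "templateLength = ", templateLength, call. = FALSE)
    }

    templates <- do.call(c, lapply(out, `[[`, "template"))
    mcols(templates) <- do.call(rbind, lapply(out, function(x)
      mcols(x$template)))
    truth <- do.call(rbind, lapply(out, `[[`, "truth"))
    truth$seed <- as.integer(seed)
    rownames(truth) <- NULL
    list(templates = templates, truth = truth)
  })
}

#' Write a generated panel to FASTA plus a truth TSV
#'
#' @param panel A list as returned by [makeCongenerPanel()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"panel"`).
#' @return Named character vector with the two paths (`fasta`, `truth`),
#'   invisibly.
#' @export
writePanel <- function(panel, dir, prefix = "panel") {
  stopifnot(is.list(panel), !is.null(panel$templates), !is.null(panel$truth))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  truth <- file.path(dir, paste0(prefix, "_truth.tsv"))
  writeTemplates(panel$templates, fasta)
  write.table(panel$truth, truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta, truth = truth))
}
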