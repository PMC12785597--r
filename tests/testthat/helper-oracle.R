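# Independent oracles for the binding / specificity machinery. Everything
# here is coded from the IUPAC definitions directly (literal tables, plain
# character vectors) and shares no code with the package internals, so it
# can stand as the reference the implementation is compared against.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N")

oracleCompat <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0L
}

oracleRevComp <- function(x) {
  paste(rev(ORACLE_COMP[strsplit(x, "", fixed = TRUE)[[1L]]]),
        collapse = "")
}

# The amplifiability rule, restated independently: a primer extends iff its
# 3'-terminal window carries fewer than 2 mismatches and it carries at most
# 3 mismatches overall.
oracleRule <- function(terminal, total) terminal < 2L && total <= 3L

# Brute-force all-offsets scan: every fully contained placement on both
# strands, mismatch = disjoint IUPAC sets, no pruning. Mismatch positions
# are 3'-anchored (3'-terminal base = 1).
oracleSites <- function(primerStr, tmplStr, maxMM, window = 5L) {
  pc <- strsplit(primerStr, "", fixed = TRUE)[[1L]]
  tc <- strsplit(tmplStr, "", fixed = TRUE)[[1L]]
  L <- length(pc)
  n <- length(tc)
  empty <- data.frame(strand = character(), start = integer(),
                      end = integer(), total_mm = integer(),
                      terminal_mm = integer(), stringsAsFactors = FALSE)
  empty$positions <- list()
  if (n < L) return(empty)
  nOff <- n - L + 1L
  compatPair <- outer(names(ORACLE_SETS), names(ORACLE_SETS),
                      Vectorize(oracleCompat))
  dimnames(compatPair) <- list(names(ORACLE_SETS), names(ORACLE_SETS))
  res <- list(empty)
  for (strand in c("+", "-")) {
    qc <- if (strand == "+") pc else rev(unname(ORACLE_COMP[pc]))
    mmAt <- matrix(FALSE, nOff, L)
    for (i in seq_len(L)) {
      mmAt[, i] <- !compatPair[cbind(rep(qc[i], nOff),
                                     tc[i:(nOff + i - 1L)])]
    }
    tot <- as.integer(rowSums(mmAt))
    keep <- which(tot <= maxMM)
    if (!length(keep)) next
    pos <- lapply(keep, function(o) {
      i <- which(mmAt[o, ])                 # 5'-index along the placement
      p3 <- if (strand == "+") L - i + 1L else i
      sort(p3)
    })
    df <- data.frame(strand = strand, start = keep, end = keep + L - 1L,
                     total_mm = tot[keep],
                     terminal_mm = vapply(pos, function(p)
                       sum(p <= window), integer(1)),
                     stringsAsFactors = FALSE)
    df$positions <- pos
    res[[length(res) + 1L]] <- df
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$strand == "-"), , drop = FALSE]
}

# Random sequences for property tests (plain base R, seeded by the caller).
randomBases <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Convert a sites DataFrame to a plain comparable data.frame.
sitesAsList <- function(sites) {
  list(strand = as.character(sites$strand), start = as.integer(sites$start),
       end = as.integer(sites$end), total = as.integer(sites$total_mm),
       terminal = as.integer(sites$terminal_mm),
       positions = lapply(as.list(sites$positions), as.integer))
}

# Build a one-row sites DataFrame with a given 3'-anchored mismatch profile,
# for exercising the classifier without a template.
makeSiteRow <- function(positions, window = 5L, primerLen = 18L) {
  S4Vectors::DataFrame(
    template_id = "synthetic", primer = "p", strand = "+",
    start = 1L, end = primerLen,
    total_mm = length(positions),
    terminal_mm = sum(positions <= window),
    ambiguous = FALSE,
    positions = IRanges::IntegerList(list(as.integer(positions))))
}
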