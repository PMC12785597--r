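test_that("defaults encode the 5/2/3 rule", {
  p <- specificityParams()
  expect_identical(p@window, 5L)
  expect_identical(p@terminalThreshold, 2L)
  expect_identical(p@totalThreshold, 3L)
  expect_error(specificityParams(window = 0), "window")
  expect_error(specificityParams(minLen = 0), "minLen")
})

test_that("per-primer rule matches the independent predicate exhaustively", {
  params <- specificityParams()
  for (terminal in 0:5) {
    for (total in terminal:8) {
      positions <- c(seq_len(terminal),
                     if (total > terminal) 5L + seq_len(total - terminal))
      cls <- classifyPrimerSite(makeSiteRow(positions), params)
      expect_identical(cls$pass, oracleRule(terminal, total),
                       info = sprintf("terminal=%d total=%d", terminal,
                                      total))
      if (terminal >= 2) expect_true("TERMINAL_MM" %in% cls$reasons)
      if (total > 3) expect_true("TOTAL_MM" %in% cls$reasons)
      if (cls$pass) expect_identical(cls$reasons, "OK")
    }
  }
  expect_identical(classifyPrimerSite(NULL, params),
                   list(pass = FALSE, reasons = "NO_SITE"))
})

test_that("the printed thresholds sit exactly at the boundaries", {
  params <- specificityParams()
  # two mismatches within the 3'-terminal five bases block amplification
  expect_false(classifyPrimerSite(makeSiteRow(c(2, 4)), params)$pass)
  # a fourth mismatch across the primer blocks; exactly three is tolerated
  expect_false(classifyPrimerSite(makeSiteRow(c(3, 7, 10, 13)),
                                  params)$pass)
  expect_true(classifyPrimerSite(makeSiteRow(c(3, 7, 10)), params)$pass)
  expect_true(classifyPrimerSite(makeSiteRow(integer()), params)$pass)
})

test_that("extra mismatches never rescue a failing site", {
  params <- specificityParams()
  set.seed(71)
  for (rep in 1:50) {
    positions <- sort(sample(1:18, sample(0:6, 1)))
    before <- classifyPrimerSite(makeSiteRow(positions), params)$pass
    free <- setdiff(1:18, positions)
    added <- sort(c(positions, sample(free, 1)))
    after <- classifyPrimerSite(makeSiteRow(added), params)$pass
    expect_false(!before && after,
                 info = paste(paste(positions, collapse = ","), "->",
                              paste(added, collapse = ",")))
  }
})

test_that("a clean planted target is called amplifiable at 526 bp", {
  pr <- sikaCoiPrimers()
  panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 0, seed = 33)
  v <- classifyTemplate(pr$fwd, pr$rev, panel$templates[1])
  expect_true(isAmplifiable(v))
  expect_identical(verdictReasons(v), "OK")
  expect_identical(productLength(v), 526L)
  expect_identical(v@fwdTotalMM, 0L)
  expect_identical(v@revTotalMM, 0L)
  # determinism: identical inputs, identical verdicts
  v2 <- classifyTemplate(pr$fwd, pr$rev, panel$templates[1])
  expect_identical(v, v2)
})

test_that("3'-terminal mismatches in the reverse primer block the call", {
  pr <- sikaCoiPrimers()
  panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 1,
                             decoySpecs = list(list(mismatchSpec(
                               "reverse", c(1, 3)))), seed = 33)
  v <- classifyTemplate(pr$fwd, pr$rev, panel$templates["decoy_1"])
  expect_false(isAmplifiable(v))
  # the panel generator guarantees the planted site is the only candidate
  # within the rule, so the reason is the planted terminal double mismatch
  expect_true("TERMINAL_MM_REV" %in% verdictReasons(v) ||
                "TOTAL_MM_REV" %in% verdictReasons(v))
  expect_false(any(grepl("FWD", verdictReasons(v))))
})

test_that("a template without binding sites reports both absences", {
  pr <- sikaCoiPrimers()
  # short template, no planted sites; seeded so the scan is reproducible
  tmpl <- randomTemplate(120, seed = 101)
  v <- classifyTemplate(pr$fwd, pr$rev, tmpl)
  expect_false(isAmplifiable(v))
  expect_identical(sort(verdictReasons(v)),
                   c("NO_FWD_SITE", "NO_REV_SITE"))
  expect_true(is.na(productLength(v)))
})

test_that("passing primers without a convergent pair are not amplifiable", {
  pr <- sikaCoiPrimers()
  # both footprints planted perfectly but 3 kb apart with maxLen = 2000
  bg <- randomTemplate(3500, seed = 55)
  syn <- plantAmplicon(bg, pr$fwd, pr$rev, fwdStart = 101,
                       productLength = 3200, seed = 55)
  v <- classifyTemplate(pr$fwd, pr$rev, syn$template)
  expect_false(isAmplifiable(v))
  expect_true("NO_VALID_PAIR" %in% verdictReasons(v))
})
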