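test_that("random templates are seeded, composed and bounded as asked", {
  a <- randomTemplate(100, gc = 0.5, seed = 1)
  b <- randomTemplate(100, gc = 0.5, seed = 1)
  expect_identical(as.character(a), as.character(b))
  expect_false(identical(as.character(randomTemplate(100, seed = 2)),
                         as.character(a)))
  at <- as.character(randomTemplate(10000, gc = 0, seed = 3))
  expect_true(all(strsplit(at, "")[[1]] %in% c("A", "T")))
  big <- as.character(randomTemplate(1e5, gc = 0.4, seed = 4))
  gcObs <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcObs - 0.4), 0.01)
  expect_error(randomTemplate(0), "length")
  expect_error(randomTemplate(10, gc = 1.5), "gc")
})

test_that("planted footprints carry exactly the requested mismatches", {
  pr <- sikaCoiPrimers()
  set.seed(81)
  for (rep in 1:25) {
    fwdPos <- sort(sample(1:18, sample(0:4, 1)))
    revPos <- sort(sample(1:18, sample(0:4, 1)))
    specs <- list(mismatchSpec("forward", fwdPos),
                  mismatchSpec("reverse", revPos))
    syn <- plantAmplicon(randomTemplate(700), pr$fwd, pr$rev,
                         fwdStart = 100, productLength = 526,
                         specs = specs)
    chars <- strsplit(as.character(syn$template[[1]]), "")[[1]]
    # independent recount with the oracle tables
    fwdChars <- strsplit("ACACCCTAATCAACTGGC", "")[[1]]
    revChars <- strsplit("AAGAAAGAAGGAGGGAGG", "")[[1]]
    fwdWin <- chars[100:117]
    gotFwd <- unname(which(!mapply(oracleCompat, fwdChars, fwdWin)))
    expect_identical(sort(18L - gotFwd + 1L), as.integer(fwdPos),
                     info = paste("fwd rep", rep))
    revStart <- 100 + 526 - 18
    revWin <- rev(unname(ORACLE_COMP[chars[revStart:(revStart + 17)]]))
    gotRev <- unname(which(!mapply(oracleCompat, revChars, revWin)))
    expect_identical(sort(18L - gotRev + 1L), as.integer(revPos),
                     info = paste("rev rep", rep))
    expect_identical(syn$truth$expected_amplifiable,
                     oracleRule(sum(fwdPos <= 5), length(fwdPos)) &&
                       oracleRule(sum(revPos <= 5), length(revPos)))
  }
})

test_that("plant validation rejects impossible requests", {
  pr <- sikaCoiPrimers()
  bg <- randomTemplate(200, seed = 1)
  expect_error(plantAmplicon(bg, pr$fwd, pr$rev, fwdStart = 100,
                             productLength = 150), "exceeds")
  expect_error(plantAmplicon(bg, pr$fwd, pr$rev, fwdStart = 10,
                             productLength = 30), "overlap")
  expect_error(plantAmplicon(bg, pr$fwd, pr$rev, fwdStart = 10,
                             productLength = 100,
                             specs = list(mismatchSpec("forward", 19))),
               "outside")
  expect_error(mismatchSpec("forward", 0), ">= 1")
})

test_that("the truth predicate encodes the rule independently", {
  expect_true(expectedAmplifiable(list()))
  expect_false(expectedAmplifiable(list(mismatchSpec("reverse", c(1, 3)))))
  expect_false(expectedAmplifiable(list(mismatchSpec("forward",
                                                     c(7, 10, 14, 18)))))
  expect_true(expectedAmplifiable(list(mismatchSpec("forward",
                                                    c(6, 9, 12)))))
  expect_true(expectedAmplifiable(list(mismatchSpec("forward", 1),
                                       mismatchSpec("reverse", 2))))
})

test_that("panels are reproducible byte-for-byte and sized as asked", {
  pr <- sikaCoiPrimers()
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 3, seed = 29)
  p2 <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 3, seed = 29)
  writePanel(p1, d1); writePanel(p2, d2)
  expect_identical(readLines(file.path(d1, "panel.fasta")),
                   readLines(file.path(d2, "panel.fasta")))
  expect_identical(readLines(file.path(d1, "panel_truth.tsv")),
                   readLines(file.path(d2, "panel_truth.tsv")))
  expect_identical(names(p1$templates),
                   c("target", "decoy_1", "decoy_2", "decoy_3"))
  solo <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 0, seed = 29)
  expect_identical(length(solo$templates), 1L)
  expect_error(makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 2,
                                 decoySpecs = list(list()), seed = 1),
               "one entry per decoy")
})

test_that("mutant-mode decoys are single-locus variants of the target", {
  pr <- sikaCoiPrimers()
  panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 2, seed = 37,
                             mode = "mutant")
  tgt <- strsplit(as.character(panel$templates[["target"]]), "")[[1]]
  for (i in 2:3) {
    dec <- strsplit(as.character(panel$templates[[i]]), "")[[1]]
    ndiff <- sum(tgt != dec)
    expect_gt(ndiff, 0)
    expect_lte(ndiff, 8)   # only the planted mismatches differ
  }
})
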