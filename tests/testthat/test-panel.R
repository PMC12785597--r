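truthExpectations <- function(panel) {
  data.frame(species = panel$truth$species,
             expected_amplifiable = panel$truth$expected_amplifiable)
}

test_that("the default 10-template panel gives exclusive amplification", {
  pr <- sikaCoiPrimers()
  panel <- makeCongenerPanel(pr$fwd, pr$rev, seed = 7)
  rep <- evaluatePanel(pr$fwd, pr$rev, panel$templates,
                       expected = truthExpectations(panel))
  expect_identical(nrow(reportTable(rep)), 10L)
  expect_identical(reportSummary(rep),
                   c(amplifiable = 1L, non_amplifiable = 9L))
  expect_identical(reportConfusion(rep),
                   c(tp = 1L, fp = 0L, tn = 9L, fn = 0L))
  tab <- reportTable(rep)
  expect_identical(tab$species[tab$amplifiable], "target")
  expect_identical(tab$product_length[tab$amplifiable], 526L)
})

test_that("degenerate panels: target-only and all-decoy", {
  pr <- sikaCoiPrimers()
  solo <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 0, seed = 2)
  rep1 <- evaluatePanel(pr$fwd, pr$rev, solo$templates)
  expect_identical(reportSummary(rep1),
                   c(amplifiable = 1L, non_amplifiable = 0L))
  expect_true(anyNA(reportConfusion(rep1)))   # no expectations given

  full <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 4, seed = 3)
  decoys <- full$templates[-1]
  expd <- data.frame(species = paste0("decoy_", 1:4),
                     expected_amplifiable = FALSE)
  rep2 <- evaluatePanel(pr$fwd, pr$rev, decoys, expected = expd)
  expect_identical(reportConfusion(rep2),
                   c(tp = 0L, fp = 0L, tn = 4L, fn = 0L))
})

test_that("expectations naming unknown species are a configuration error", {
  pr <- sikaCoiPrimers()
  panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 1, seed = 5)
  expect_error(
    evaluatePanel(pr$fwd, pr$rev, panel$templates,
                  expected = c(target = TRUE, ghost_species = FALSE)),
    "unknown species")
})

test_that("panel evaluation is order-independent", {
  pr <- sikaCoiPrimers()
  panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 5, seed = 13)
  rep <- evaluatePanel(pr$fwd, pr$rev, panel$templates,
                       expected = truthExpectations(panel))
  perm <- c(4, 1, 6, 2, 5, 3)
  repP <- evaluatePanel(pr$fwd, pr$rev, panel$templates[perm],
                        expected = truthExpectations(panel))
  expect_identical(reportTable(repP),
                   {
                     t1 <- reportTable(rep)[perm, ]
                     rownames(t1) <- NULL
                     t1
                   })
  expect_identical(reportSummary(repP), reportSummary(rep))
  expect_identical(reportConfusion(repP), reportConfusion(rep))
})

test_that("TSV report round-trips and keeps the fixed column order", {
  pr <- sikaCoiPrimers()
  panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 3, seed = 17)
  rep <- evaluatePanel(pr$fwd, pr$rev, panel$templates)
  f <- tempfile(fileext = ".tsv")
  writeReport(rep, f, "tsv")
  lines <- readLines(f)
  expect_identical(length(lines), 5L)              # header + 4 rows
  expect_identical(lines[1], paste(
    c("species", "template_id", "amplifiable", "reasons", "product_length",
      "fwd_terminal_mm", "fwd_total_mm", "rev_terminal_mm", "rev_total_mm"),
    collapse = "\t"))
  back <- readReport(f)
  expect_identical(reportTable(back), reportTable(rep))
  expect_identical(reportSummary(back), reportSummary(rep))
})

test_that("an empty report writes a header-only TSV", {
  empty <- new("PanelReport",
               table = reportTable(evaluatePanel(
                 sikaCoiPrimers()$fwd, sikaCoiPrimers()$rev,
                 makeCongenerPanel(sikaCoiPrimers()$fwd,
                                   sikaCoiPrimers()$rev, nDecoys = 0,
                                   seed = 1)$templates))[0, ],
               summary = c(amplifiable = 0L, non_amplifiable = 0L),
               confusion = c(tp = NA_integer_, fp = NA_integer_,
                             tn = NA_integer_, fn = NA_integer_))
  f <- tempfile(fileext = ".tsv")
  writeReport(empty, f, "tsv")
  expect_identical(length(readLines(f)), 1L)
})

test_that("JSON report round-trips field-for-field", {
  pr <- sikaCoiPrimers()
  panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 3, seed = 19)
  rep <- evaluatePanel(pr$fwd, pr$rev, panel$templates,
                       expected = truthExpectations(panel))
  f <- tempfile(fileext = ".json")
  writeReport(rep, f, "json")
  back <- readReport(f)
  expect_identical(reportTable(back), reportTable(rep))
  expect_identical(reportSummary(back), reportSummary(rep))
  expect_identical(reportConfusion(back), reportConfusion(rep))
})
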