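# ampliScreen

Virtual PCR screening of primer specificity for species-authentication
assays.

## What it does

A species-authentication PCR assay stands or falls on its primer pair:
the diagnostic fragment must amplify from the target species and from
nothing else that could plausibly be in the sample. ampliScreen performs
the computational half of that validation. Given a primer pair and a FASTA
of candidate templates (the target plus congeners and adulterant species),
it

* finds every ungapped, approximate binding site of each primer on both
  strands, under IUPAC set-intersection matching (a template `N` is never
  a mismatch),
* profiles mismatches per site, indexed from the primer's 3' end, where
  mismatches block polymerase extension,
* pairs convergent opposite-strand sites into predicted amplicons with
  product length and sequence, and
* calls each template **amplifiable** or **not**, with reason codes, using
  the screening rule

  > a template is unlikely to amplify if either primer's best binding site
  > has **≥ 2 mismatches within the 3'-terminal 5 bases**, or **> 3
  > mismatches across the whole primer** — and a positive call additionally
  > requires a convergent product within the length bounds (50–2000 bp by
  > default).

The built-in example pair (`sikaCoiPrimers()`) targets the mitochondrial
COI gene of sika deer (*Cervus nippon*): forward
`5'-ACACCCTAATCAACTGGC-3'`, reverse `5'-AAGAAAGAAGGAGGGAGG-3'`, with an
expected 526 bp product from the target and mismatch-blocked binding in
congeners.

A seeded synthetic generator (`makeCongenerPanel()`, `plantAmplicon()`)
builds panels with planted binding sites, controlled mismatch placement
and recorded ground truth, so the entire pipeline is testable offline; an
independently coded truth predicate makes the generator usable as an
oracle for the classifier. See `vignettes/virtual-pcr-screening.Rmd` for
the model, its assumptions and its limits.

## Worked example

```r
library(ampliScreen)

pr <- sikaCoiPrimers()
pr$fwd
#> Primer COI-F: 5'-ACACCCTAATCAACTGGC-3' (18 nt)

# a 10-template specificity panel: 1 target + 9 congener-like decoys
panel <- makeCongenerPanel(pr$fwd, pr$rev, nDecoys = 9, seed = 42)
report <- evaluatePanel(pr$fwd, pr$rev, panel$templates,
  expected = data.frame(species = panel$truth$species,
                        expected_amplifiable = panel$truth$expected_amplifiable))
report
#> PanelReport: 10 templates (1 amplifiable, 9 not)
#>   confusion vs expectations: TP=1 FP=0 TN=9 FN=0
#>    species template_id amplifiable                   reasons product_length
#> 1   target      target        TRUE                        OK            526
#> 2  decoy_1     decoy_1       FALSE              TOTAL_MM_REV             NA
#> 3  decoy_2     decoy_2       FALSE           TERMINAL_MM_FWD             NA
#> ...
```

Only the target amplifies, at exactly the planted 526 bp; every decoy is
rejected with the rule clause it violates (`TERMINAL_MM_*`: too many
3'-terminal mismatches; `TOTAL_MM_*`: more than three mismatches over the
primer; `NO_*_SITE`: no binding site within the search budget;
`NO_VALID_PAIR`: passing sites that do not converge within the length
bounds). The confusion row confirms the panel reproduces exclusive target
amplification.

Per-template detail is available at every level:

```r
classifyTemplate(pr$fwd, pr$rev, panel$templates[1])
#> SpecificityVerdict for target (target): AMPLIFIABLE [OK], primary product 526 bp

findBindingSites(pr$fwd, panel$templates[1], maxMismatches = 2)
```

### Command line

Thin wrappers in `inst/scripts/` expose the same pipeline to the shell:

```sh
Rscript inst/scripts/ampliscreen-synth --out panel_dir --n-decoys 9 --seed 42
Rscript inst/scripts/ampliscreen-scan --primers primers.tsv \
    --templates panel_dir/panel.fasta --out panel_dir --format tsv
```

`scan` echoes the active rule (window/terminal/total thresholds) in its log
so the criterion used for any report is auditable; options can also come
from a YAML file via `--config`, with explicit flags taking precedence.

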