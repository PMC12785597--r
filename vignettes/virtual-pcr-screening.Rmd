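---
title: "Virtual PCR screening of primer specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual PCR screening of primer specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliScreen)
```

## The problem

PCR-based species authentication rests on a primer pair that amplifies a
diagnostic fragment from the target species and from nothing else likely to
be present in a sample. The motivating application is meat authentication:
a pair targeting the mitochondrial cytochrome c oxidase subunit I (COI)
gene of sika deer (*Cervus nippon*) must produce its 526 bp amplicon from
sika deer DNA while staying silent on congeners such as *Cervus elaphus*
and on common adulterant species. Before any wet-lab validation, that
specificity claim can be screened computationally: lay each primer over
every candidate template, count primer-template mismatches, and ask whether
the mismatch pattern is compatible with polymerase extension.

ampliScreen implements that screen as a deterministic pipeline:

1. **Binding-site search** — every ungapped placement of a primer on either
   strand of a template with at most `maxMismatches` mismatches.
2. **Mismatch profiling** — per-site mismatch positions indexed from the
   primer's 3' end, because that end is where extension starts.
3. **Amplicon pairing** — convergent, opposite-strand site pairs within a
   product-length window.
4. **Amplifiability verdict** — a per-template call from the rule below,
   aggregated into a cross-species panel report.

## Match semantics

A primer-template position is a *mismatch* when the IUPAC sets of the two
codes are disjoint (`iupacCompatible()`). This is the standard convention
of in-silico PCR tools: a template `N` or a degenerate primer base never
counts as a mismatch. The flip side is that heavily ambiguous templates can
look spuriously amplifiable, so every reported binding site carries an
`ambiguous` flag when its template window contains any non-ACGT code, and
reports can be audited for it.

Matching is strictly ungapped: primer-template indels are outside the
model. For orthologous loci diverging by substitutions — the congener
situation the screen is designed for — an ungapped overlay of the primer on
each template is equivalent to reading mismatch columns off a multiple
sequence alignment of the locus, which is how such screens are usually done
by hand. Loci that differ from the primer by insertions or deletions are
not handled and will generally report no binding site.

## Coordinates

All site and amplicon coordinates are 1-based closed intervals on the
template plus strand, the convention of IRanges and of every Bioconductor
container this package builds on. Mismatch positions are the exception:
they are indexed from the primer's 3' end (3'-terminal base = position 1)
because the decision rule is 3'-anchored; the 5'-indexed view is
`length - p + 1`.

## The amplifiability rule

A template is called **unlikely to amplify** when, at the best binding site
of either primer:

* `terminal_mm >= 2` — two or more mismatches fall within the 3'-terminal
  five bases of the primer, or
* `total_mm > 3` — more than three mismatches are distributed across the
  entire primer.

Both clauses are evaluated **per primer**; the thresholds live in
`specificityParams()` (`window = 5`, `terminalThreshold = 2`,
`totalThreshold = 3`) so that non-default screens remain expressible, and
the defaults are asserted in the test suite. The "more than three total"
clause is read per primer rather than summed over the pair: the rule's
subject is each primer individually, and a joint-sum reading would let one
perfect primer excuse four mismatches on the other, which contradicts how
extension works. A template with no detectable site at all fails with its
own reason codes (`NO_FWD_SITE` / `NO_REV_SITE`) rather than being folded
into the mismatch-threshold failures.

A positive verdict additionally requires an orientation-valid product:
both primers pass, and a convergent opposite-strand site pair yields a
product length within `[minLen, maxLen]` (defaults 50–2000 bp, generous
bounds around the 526 bp target). Two passing sites 50 kb apart are not
amplification. Only sites that individually satisfy the rule are allowed
to form products; placements that cannot extend cannot contribute an
amplicon, and letting them pair would occasionally shadow the real product
as the "primary" (shortest) one.

### Best-site selection

When several sites of one primer survive the search budget, the verdict is
based on the site minimising `(terminal_mm, total_mm, start, strand)`,
plus strand before minus. The 3'-window count dominates deliberately: a
site with one 3'-terminal mismatch and many internal ones is closer to
extensible than a site with two terminal mismatches and none elsewhere.
A consequence worth knowing: when a planted or orthologous site fails on
terminal mismatches, a weaker site elsewhere may be selected as "best" and
the failure then reports `TOTAL_MM_*` rather than `TERMINAL_MM_*`. The
verdict itself is unaffected.

### Search budget

The default `maxMismatches = 7` is a reporting margin, not a sensitivity
knob: the rule already fails any primer above 3 total mismatches, so no
site found beyond that can change a verdict, and deeper search only makes
mismatch profiles of clear negatives visible in reports.

## Numerical and degenerate-input choices

* Product length includes both primer footprints
  (`rev_end - fwd_start + 1`); this is the standard PCR convention and is
  what makes a 526 bp planted product round-trip exactly.
* The length filter is closed on both ends (`minLen = maxLen = 526` keeps
  a 526 bp product).
* Amplicons with identical spans arising from overlapping site sets are
  deduplicated; overlapping binding sites themselves are all reported,
  deduplicated only on identical `(start, strand)`.
* Templates shorter than the primer yield an empty site table, not an
  error; an empty panel FASTA is an error.
* Ties in best-site selection fall back to leftmost start, then plus
  strand — an arbitrary but fixed order that keeps verdicts deterministic.
* Sequences are uppercased and `U` is mapped to `T` on input; gap
  characters are rejected rather than stripped, because the pipeline
  consumes unaligned sequences and a gapped FASTA usually signals an
  alignment exported by mistake.

## The synthetic panel generator

Real screening uses GenBank mitochondrial records; the generator exists so
that every pipeline stage can be validated offline against known ground
truth. `plantAmplicon()` overwrites a random background so that the
forward footprint begins at `fwdStart` and the reverse primer's reverse
complement ends `productLength - 1` later, then mutates requested
positions to bases whose IUPAC sets are disjoint from the primer base
bound there — never to an ambiguity code — so planted mismatch counts are
exact. The planted-truth verdict is computed by `expectedAmplifiable()`, a
deliberately separate restatement of the rule in bare arithmetic that
shares no code with the classifier, so generator truth can stand as an
oracle for the pipeline.

`makeCongenerPanel()` emulates the classic specificity panel: one target
with perfect binding sites 526 bp apart (configurable) and `nDecoys`
decoys whose default mismatch plans mirror congeners — mismatches
concentrated at primer 3' termini, plus some >3-total profiles — all
expected negative. Defaults: 10 templates (1 target + 9 decoys), 1200 bp
backgrounds at GC 0.42 (typical of cervid mitochondrial protein-coding
sequence; real mitogenomes are ~16.4 kb, shortened here only because
binding behaviour is local), decoys on independent backgrounds, with a
`mutant` mode that instead mutates copies of the target locus for congener
realism.

One subtlety the generator owns: with a low-complexity primer (the reverse
COI primer is AG-rich), a copy of its own footprint shifted by a few bases
can still bind with few internal mismatches and a clean 3' end, silently
contradicting the planted truth. After planting, the generator therefore
verifies with its own independent sliding scan that the planted footprints
are the *only* extensible placements on each template, and redraws the
background otherwise (seeded, so output remains reproducible; the draw
count is bounded and an informative error is raised for primers too
repetitive to place cleanly).

What the generator does **not** emulate: sequencing error, indels,
mitochondrial genome structure, codon bias, or intraspecific variation.
Passing the planted-truth tests therefore demonstrates that the pipeline's
arithmetic and rule application are exact, not that the 5/2/3 rule itself
predicts wet-lab amplification for real congeners — the rule is a screening
heuristic whose calibration lives outside this package.

## Validation problem sizes

The shipped tests and the acceptance script validate at these scales,
chosen to exercise every code path while keeping a full run to a couple of
minutes: exhaustive truth-table enumeration (39 terminal/total
configurations); 1,000 random primer/template pairs (templates up to
2 kb, budgets 0–7) against a brute-force all-offsets scan; 50 seeded
panels (4–8 decoys, both background modes) for planted-truth recovery;
200 random plant positions/lengths (60–1500 bp) for product-length
round-tripping.

## Known limitations

* No thermodynamics: neither melting temperature, ΔG, nor
  position-specific mismatch energetics — the rule counts mismatches.
* Ungapped matching only; primer-template indels report as absent sites.
* The rule treats both primers symmetrically and ignores mismatch identity
  (e.g. G:T wobble vs A:G), which real polymerases do not.
* Amplification efficiency, cycle number and yield are out of scope; the
  verdict is binary.
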