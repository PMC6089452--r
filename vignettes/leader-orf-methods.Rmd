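---
title: "Methods: upstream ORF annotation and selection analysis in transcript leaders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: upstream ORF annotation and selection analysis in transcript leaders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaderscan)
```

## The problem

Many mRNAs carry AUG triplets in their transcript leader (TL, the 5'
UTR). An upstream AUG opens a reading frame whose relationship to the
main CDS determines its likely regulatory consequence:

* a **uORF** terminates wholly within the leader (stop third base at
  position -1 or earlier) and encodes a short independent peptide;
* an **oORF** is out of frame with the CDS and its first in-frame stop
  ends at or past the CDS first base, so the upstream reading frame
  overlaps the main start codon — a scanning ribosome that translates it
  is carried past the CDS AUG and terminates downstream of it;
* an in-frame upstream AUG with no leader stop is an **N-terminal
  extension** of the main protein, not a separate upstream peptide;
* an out-of-frame AUG whose stop is not found within the search window
  is reported separately as `no_stop_in_window`.

The telomere-capping gene *STN1* is the motivating example: its leader
carries a uORF and a short oORF terminating just past the CDS start, and
point mutations in the initiation or termination codons of these
elements reorganize the architecture. Genome-wide, comparing how often
native leaders contain uORFs/oORFs with how often randomized leaders do
measures the strength of selection against these elements; oORFs can
occupy only the two out-of-CDS reading frames while uORFs can occupy all
three.

## Coordinates and the scanner

All positions are CDS-relative and 1-based with **no position 0**: the
CDS first base is +1, the last TL base is -1. Stop positions refer to
the third base of the stop codon, so an oORF whose stop's third base is
+1 terminates exactly at the CDS boundary. When an ORF spans the
boundary, the nucleotide span from start to stop third base is
`stop - start + 1 - 1` (one is subtracted because 0 is skipped), and it
always equals `3 * (length_aa + 1)`; `length_aa` counts sense codons
including the initiator Met and excluding the stop.

`scan_transcript()` reports every AUG lying wholly within the TL (start
at -3 or earlier; AUGs straddling the TL/CDS boundary are not upstream
initiation events) and reads codons to the first in-frame TAA/TAG/TGA
within TL + `window` nt of CDS-side sequence. Each AUG is scanned
independently, so nested ORFs and two AUGs sharing a stop are all
reported. Codons containing N match neither AUG nor stop; leaders
containing N are flagged in the per-gene summary. The `window` default
of 300 nt makes unterminated out-of-frame ORFs vanishingly rare at
natural base compositions (the chance that ~100 consecutive codons in a
fixed frame contain no stop is below 1%); such calls are reported as
`no_stop_in_window` and excluded from the cohort fractions, and widening
the window can only reclassify them to oORF, never change a closed
call.

## The permutation null and the exact automaton model

`expected_fractions()` implements the cohort null: each leader is
individually permuted (a uniform Fisher-Yates shuffle, preserving
mononucleotide composition and length per gene) and rescanned against
its **real** downstream sequence, so overlapping ORFs still terminate in
genuine CDS. One randomization per leader is the default, matching the
single-randomization design this analysis is usually run with; for
stable expected fractions we recommend `n_rand >= 10` and report the
replicate spread. Only the mononucleotide composition is preserved — a
dinucleotide-preserving shuffle is deliberately not offered as the
default null, since the reference analyses use plain permutation.

`analytic_presence_prob()` gives the exact iid counterpart: the
probability that a random leader of length L contains each class. It is
a product-automaton dynamic program: per reading frame a four-state
automaton (closed/open x uORF-seen), the three frames advanced jointly
over leader positions sharing a two-base memory (25 memory x 64 status
states). Exactness matters because presence probabilities of the three
frames are dependent (a uAUG in one frame excludes overlapping uAUGs in
others); the automaton accounts for all interactions, and
`enumerate_presence_prob()` — brute-force enumeration of all 4^L
leaders through the scanner — verifies it to < 1e-12 for all L <= 8
under uniform and AT-rich compositions. Useful closed values:
p_uORF(6) = 3/4096 (the leader must be exactly AUG + a stop) and
p_oORF(4) = 1/64 (AUG at -4 stays open) at uniform composition.

The permutation null conditions on each gene's composition; the
analytic model assumes iid draws. Per gene the two differ; in
expectation over iid-generated cohorts they coincide (a permutation of
an iid sequence is another iid draw), which the tests verify within
binomial sampling error.

## Cohort statistics

`observed_fractions()` counts genes with at least one uORF and at least
one oORF (genes with both count in both). `length_stratified_fractions()`
bins genes by TL length (default 25-nt bins; bins under 20 genes are
flagged low-support — both defaults are analysis choices, not biology)
and `oe_curve()` forms per-bin observed/expected ratios, with ratios
below 1 indicating depletion. The oORF-below-uORF flag summarizes the
qualitative selection signature expected beyond ~50 nt leaders.

`abundance_association()` joins per-gene groups with a protein-abundance
table and compares uORF-only against oORF-only genes (genes with both,
or neither, are excluded from this contrast). The default test is the
two-sided pooled-variance Student t-test on the supplied scale — the
plain reading of an "unpaired t-test" — with Welch and log10 options
exposed; abundances span orders of magnitude, so `transform = "log10"`
is the sensible choice in practice and is what the analysis drivers
use. Box statistics follow the Tukey convention: quartiles by linear
interpolation of order statistics (type 7), whiskers to the most
extreme point within 1.5 x IQR of the nearer quartile. (The alternative
literal reading of "the largest data point less than 1.5 x IQR" — a
datum smaller than the scalar 1.5 x IQR — is meaningless for abundance
scales and was rejected.)

## Variant re-annotation

`apply_substitution()` edits one base at a relative position (positions
>= +1 are allowed but flagged, because a natural oORF stop can lie
inside the CDS and its knockout then necessarily edits CDS sequence).
`diff_architecture()` matches calls between reference and mutant scans
by start coordinate — the natural key, since stop mutations preserve
the start and start mutations destroy the call — and tags events
`start_loss`, `stop_loss_extension`, `stop_gain_truncation`, and
`class_change`. Because every AUG is scanned independently, a start
knockout can never create a call, which the tests verify exhaustively
over all length-6 leaders.

## Synthetic cohorts and what they do and do not show

`generate_cohort()` draws TL lengths from a lognormal parameterized by
its median (presets: yeast-like median 49 nt with AT-rich composition
A/C/G/T = 0.31/0.19/0.17/0.33; human-like median 173 nt with
0.22/0.28/0.28/0.22; dispersion sdlog 0.7). Only medians are reported
for the reference cohorts, so the dispersion and compositions are this
package's own realistic choices, fixed once. Downstream sequences start
with ATG, keep the CDS frame open, and carry an in-frame stop at the end
of the window.

Three modes: `iid` (no structure — the calibration case), `planted`
(architectures inserted at controlled positions), and `depleted`
(rejection sampling that keeps oORF-containing leaders with a fixed
probability, creating known negative selection). Planted mode scrubs
background AUGs by resampling the middle base of each accidental ATG —
a replacement that provably cannot create a new AUG — then verifies
every gene by re-scanning and regenerates on any collision, so the
planted truth table is exact by construction, not by trust. The cost is
that planted-mode backgrounds are conditioned on being call-free: use
iid mode, not planted mode, for composition-sensitive calibration.

The `stn1_fixture()` records are deterministic, labeled synthetic, and
fix the *class architecture* (16-sense-codon uORF wholly in the leader;
6-sense-codon oORF whose stop ends past +1; human: 15- and 19-codon
oORFs sharing a stop ending exactly at +1) while treating exact offsets
as generator parameters. The published coordinate set for the yeast
gene is internally inconsistent under every counting convention we
tried (an oAUG 13 nt upstream cannot yield a 6-codon ORF terminating 2
bases past the CDS start), so the fixture places the oAUG at -17, the
closest arrangement that satisfies the stated lengths and boundary
relations; the stop-knockout mutant extends the oORF from 6 to 32
codons exactly as described. Passing fixtures demonstrates the
annotation logic, not the real gene's coordinates — scanning the real
sequences requires the external retrieval described in the README.

Synthetic cohorts emulate length distribution, base composition, and
architecture only. They do not reproduce promoter structure, codon
usage, isoform heterogeneity, or the correlation structure of real
leaders, so agreement on synthetic data validates the machinery, not
any biological claim about a particular transcriptome.

## Numerical and scale choices

Analyses in `analysis/` and the test suite run at sizes chosen to keep
a laptop run comfortable while leaving standard errors well below the
effects tested: calibration cohorts of 2,000 genes with 10
randomization replicates, planted cohorts of 1,000 genes, abundance
power at 200 genes per group (delta = 1 log10, sd = 0.5), and null
calibration of the t-test over 5,000 replicates. Exhaustive
enumerations go to 4^9 leaders and the automaton/brute-force
equivalence to L = 8. Randomness is always taken through explicit seed
arguments; identical seeds give byte-identical cohorts.

## Known limitations

Only AUG starts are considered (no CUG/GUG near-cognates), no start
context (Kozak) scoring, no ribosome-profiling evidence, no isoform
quantification, and no indel support in the variant engine. The
observed/expected framework detects depletion but does not model its
mechanism; interpreting depletion as selection assumes the permutation
null is the right neutral model for leader sequence.
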