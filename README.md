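# leaderscan

Annotation and selection analysis of upstream open reading frames in
transcript leaders.

Many mRNAs carry AUG triplets in the transcript leader (TL, the 5' UTR).
Depending on reading frame and where the first in-frame stop falls, an
upstream AUG gives a **uORF** (stop wholly within the leader), an **oORF**
(out of frame with the CDS, stop at or past the CDS first base, so the
reading frame overlaps the main start codon), or an **N-terminal
extension** (in frame, no leader stop). oORFs are strong repressors of
main-ORF translation — the telomere-capping gene *STN1*, whose leader
carries a uORF and a short oORF terminating just past the CDS start, is
the motivating case — and genome-wide they are depleted relative to
randomized leaders, a signature of negative selection.

`leaderscan` is for researchers in translational regulation who want to:

* scan leaders for AUG-initiated ORFs and classify every call
  (`scan_transcript()`, `scan_cohort()`);
* compare observed cohort frequencies with a per-leader permutation null
  (`expected_fractions()`) and with an exact automaton model of random
  sequence (`analytic_presence_prob()`), overall and stratified by leader
  length (`length_stratified_fractions()`, `oe_curve()`);
* relate ORF classes to protein abundance with Tukey box statistics and
  an unpaired t-test (`abundance_association()`);
* re-annotate leaders after point substitutions and classify the events
  — start loss, stop-loss extension, truncation, class change
  (`apply_substitution()`, `diff_architecture()`);
* generate synthetic cohorts with exact ground truth, including
  deterministic STN1-like fixtures (`generate_cohort()`,
  `stn1_fixture()`).

## Conventions

Coordinates are CDS-relative and 1-based with no position 0: CDS first
base = +1, last TL base = -1. Stop positions are the third base of the
stop codon, so a stop ending at +1 terminates exactly at the CDS
boundary. `length_aa` counts sense codons including the initiator Met.
uORFs can occupy all three reading frames; oORFs only the two
out-of-CDS frames.

## Worked example

The yeast STN1-like fixture carries a 16-amino-acid uORF and a
6-amino-acid oORF whose TGA stop overlaps the CDS start codon:

```r
library(leaderscan)
fx <- stn1_fixture("yeastWT")
scan_transcript(fx$record)
#>                gene_id start stop_third_base length_aa frame_offset orf_class
#> 1 STN1_yeast_synthetic   -78             -28        16            0      uORF
#> 2 STN1_yeast_synthetic   -17               4         6            2      oORF
```

The uORF starts 78 nt upstream and terminates inside the leader (third
stop base at -28); the oORF starts 17 nt upstream in frame offset 2 and
its stop ends at +4, past the CDS first base. Disrupting the oORF stop
(`s111`, substitution `+4A>C`) extends the oORF to the next in-frame
stop:

```r
d <- diff_architecture(scan_transcript(fx$record),
                       scan_transcript(stn1_fixture("s111")$record))
d
#> <architecture_diff> destroyed: 0  created: 0  altered: 1  unchanged: 1
#>   start stop_third_base_before stop_third_base_after length_aa_before
#> 1   -17                      4                    82                6
#>   length_aa_after                tags
#> 1              32 stop_loss_extension
```

The oORF grows from 6 to 32 amino acids, tagged as a stop-loss
extension; the uORF is untouched. At cohort scale, an iid yeast-like
cohort (2,000 genes, TL median 49 nt) shows observed fractions matching
the permutation-expected ones, as they must without selection:

```r
g  <- generate_cohort(2000, preset = "yeast", mode = "iid", seed = 1001)
sc <- scan_cohort(g$cohort)
ex <- expected_fractions(g$cohort, n_rand = 10, seed = 2001)
cohort_fractions(observed_fractions(sc$summaries), ex)
#> <cohort_fractions> n = 2000 genes
#>   uORF: observed 33.3%  expected 32.2%
#>   oORF: observed 28.0%  expected 28.1%
```

On real transcriptomes the observed fractions fall far below expected —
that gap, and its length dependence, is the selection readout this
package computes.

## Analysis workflow

The `analysis/` directory is a numbered, self-contained workflow over
the package functions; each script prints what it found and writes
tables under `results/`:

1. `01_simulate_cohorts.R` — build the synthetic study cohorts.
2. `02_observed_vs_expected.R` — observed vs randomization-expected
   fractions.
3. `03_length_stratification.R` — length-binned fractions, O/E curves,
   and the exact analytic curve.
4. `04_abundance.R` — protein abundance by ORF class (planted 1-log10
   decrement, unpaired t-test).
5. `05_stn1_variants.R` — fixture architectures and variant
   re-annotation.
6. `06_real_data.R` — genome-scale fractions on downloaded annotation
   (see below).

## Real data

Genome-scale comparisons and the real *STN1* checks need externally
retrieved inputs that are not distributed here. Place under
`data-raw/real/`, per species: `<species>_regions.fasta` (per-gene
upstream+CDS regions with `cds_start=` headers; build them with
`extract_records_from_genome()` from a genome FASTA + GFF3/BED, e.g.
YeastMine or Ensembl Biomart exports, then `write_transcript_fasta()`)
and `<species>_tl_lengths.tsv` (gene id and TL length, longest isoform
per gene). `load_real_cohort()` reads them back.

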