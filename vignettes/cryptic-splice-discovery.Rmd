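---
title: "Detecting splice-site-creating mutations: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting splice-site-creating mutations: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptsplice)
```

## The problem

A somatic point mutation in an intron, UTR or intergenic region can create
or strengthen a splice donor or acceptor. The spliceosome then produces a
transcript isoform absent from the annotation: an exon extended into its
intron, an exon shortened, a brand-new exon spliced in between two
annotated ones, or — across gene boundaries — a fusion transcript. Such
events are invisible to coding-centric annotation but leave a crisp
signature in RNA-Seq: reads whose alignments skip a novel intron, i.e.
junction-supporting reads near the mutation.

`cryptsplice` turns that signature into calls. Each non-coding mutation
anchors a local junction search; candidate (mutation, junction) pairs then
pass a cascade of filters designed to remove annotation artifacts,
low-level noise and germline/recurrent splicing that is not
mutation-associated.

## The discovery model and its assumptions

The discovery stage assumes spliced alignments with CIGAR `N` operations
that faithfully mark introns, and that a mutation-induced splice site lies
within `window` bp of the novel junction boundary. The default window of
20 bp covers the positions that materially contribute to donor/acceptor
strength (the classical splice region); mutations acting at longer range
(e.g. by disrupting a distant canonical site) are out of reach by design.

Junctions are keyed by their first and last intronic base, 1-based
inclusive, matching GTF exon arithmetic exactly; BAM's 0-based positions
are converted at the read boundary so a single convention holds everywhere.
Reads flagged secondary, supplementary, duplicate or QC-fail are excluded
throughout, as are reads below the mapping-quality floor.

Two definitional choices deserve explanation because the quantities they
control are thresholds:

* **The assessed site for depth and JAF.** The junction allele fraction is
  supporting reads over "total reads at that genomic location". We take
  that location to be the exonic base immediately flanking the junction
  boundary nearest the mutation: it is the only base present in both the
  novel and the canonical isoform, so junction-supporting reads (which have
  an aligned base there) and exon-only reads both count toward the
  denominator. Positions inside the novel intron would be blind to the
  spliced isoform; positions deeper in the exon drift away from the event.
* **Mutation-to-junction distance** is the minimum distance to any of the
  four boundary bases (first/last intronic base and the two adjacent exonic
  bases). This makes the 20-bp rule symmetric around both edges of the
  junction and insensitive to which side of a boundary the mutation sits
  on.

Strand of a novel junction is inferred from the intronic dinucleotides
(`GT..AG` forward, `CT..AC` reverse) and reported as `unknown` otherwise;
scoring then falls back to the forward orientation.

## The filter cascade

1. **Known junctions and polymorphic loci.** Only junctions matching a
   canonical intron on *both* boundaries are removed. Removing
   single-boundary matches would delete exactly the extension and shrinkage
   events the pipeline exists to find, since those always share one
   boundary with the canonical intron. Polymorphic regions (e.g. the HLA
   locus) arrive as a BED blacklist and remove any overlapping candidate.
2. **Coverage/JAF.** The default heuristic removes candidates with
   JAF strictly below 5% (a JAF equal to the threshold passes). The
   alternative proportion-test mode computes the exact binomial upper tail
   at the site's depth under a null JAF of 5% and keeps candidates whose
   Benjamini–Hochberg q-value is at most `alpha`. The heuristic is the
   default because it is the mode used for cohort-scale runs; the test mode
   is preferable when depths vary widely across candidates.
3. **Case/control.** A candidate passes when strictly fewer than `k` = 5%
   of control samples show supporting-read counts at or above the case
   count — ties count against the case, a deliberately conservative reading
   of "top 5%". The comparison is against the control distribution alone
   (the case is not pooled in). At least one control is mandatory.
4. **Spliced-in review.** When the mutation lies in the transcribed segment
   retained by the junction, the reads that both support the junction and
   cover the mutated base must carry the alternate allele at ≥ 30%. We use
   the covering subset of junction reads, not all junction reads: reads
   that do not reach the mutated base carry no evidence either way. Indel
   alleles are flagged indeterminate rather than guessed (substitutions
   only).

All thresholds sit in a single `splice_config()` object; the cascade is
monotone (relaxing any threshold can only grow the surviving set), a
property the test suite checks directly.

## Splice-site scoring

Donor sites are scored over 9-mers (3 exonic + 6 intronic bases), acceptors
over 23-mers (20 intronic + 3 exonic), the standard windows for maximum-
entropy-style scorers. The default model is a first-order position
log-odds model trained on the canonical junctions of the supplied
annotation: per position, log2 of the observed base frequency (pseudocount
1 per base) over a uniform 0.25 background, with a sequence scored as the
sum of per-position terms. The model is deterministic given its training
set and *additive* — a single-base mutation changes the score by exactly
the log-odds difference at that position — which makes the mutant-minus-
reference delta directly interpretable. An external scorer can be swapped
in through the model argument of the scoring functions when parity with a
specific published scorer is wanted; the first-order model deliberately
omits the pairwise dependencies a maximum-entropy model captures, which is
the main accuracy gap to expect.

Training needs at least 50 canonical junctions; below that the pipeline
reports `NA` scores rather than a poorly determined model.

## Event classification

The classifier assigns exactly one category per candidate by boundary
context:

| signature | category |
|---|---|
| one canonical boundary, novel boundary in the intron, mate found | new exon (first/middle/last) |
| one canonical boundary, novel boundary in the intron, no mate | exon extension |
| one canonical boundary, novel boundary in an exon | exon shrinkage |
| both boundaries inside one exon | exon splitting |
| boundaries in two different genes | fusion |
| no annotated transcript at either boundary | new transcript |
| anything mixing elementary signatures | complex |

A new exon requires an *activated mate site*: a partner junction sharing
the host intron's other canonical edge, with its own novel boundary inside
the same intron (the search space is restricted to that intron), at least
`M` supporting reads, and an enclosed interval of 15–600 bp — the same
plausible exon-size range the simulator uses, chosen to avoid inventing a
second arbitrary bound. Competing mates are ranked by supporting reads,
then splice-site score (when a model is available), then genomic position,
so the choice is always deterministic. First/middle/last placement is
relative to the host gene's coding span: a new exon upstream of the first
CDS base is "first", downstream of the last is "last", otherwise "middle";
without CDS annotation "middle" is reported.

Frame impact is defined for insertions bracketed by annotated CDS: a
frameshift when the inserted length is not a multiple of 3, and a premature
stop when the inserted sequence read in the CDS frame at the insertion
point contains a stop codon. Codons spanning the insertion boundary are not
scanned; only codons fully inside the insert can fire the stop call.

## The statistical framework

* `required_depth()` evaluates the Gaussian-approximated one-sided binomial
  power bound; defaults Z₁₋α = 1.645 and Z₁₋β = 0.84 encode a 5% type-I
  rate at 80% power. With a 5% null and 10% alternative JAF the bound is
  150×. A note on discreteness: the bound describes the approximate
  Gaussian test. Monte-Carlo power of that test at exactly R = 150 is
  ~82–83% (the discrete rejection threshold rounds up), while the exact
  binomial test, being conservative, attains ~74–75%. The test suite
  therefore checks that the Gaussian test attains at least nominal − 2pp
  at R, rather than a two-sided band no discrete test can hit.
* `expected_artifact_reads()` and `poisson_tail()` justify the
  supporting-read floor: at 200× and mean quality Q20 two artifact reads
  are expected, and P(X ≥ 5 | λ = 2) ≈ 5.3%, so M = 5 caps chance
  artifact calls near the conventional 5%.
* `new_exon_probability()` treats a new exon as a joint 32-nt donor +
  acceptor motif with per-placement probability 4⁻³² (~10⁻¹⁹) and
  L − E − 31 placements in an intron of length L. Because 1 − 4⁻³²
  rounds to 1 in double precision, the exact form is computed as
  `-expm1(n * log1p(-p))`; the linearised form `n · 4⁻³²` is available as a
  flag and agrees to better than 1e-6 relative error for any realistic
  intron. The ratio `(L_L − E − 31)/(L_S − E − 31)` quantifies the
  long-intron bias (≈10-fold for 30 kb vs 3 kb; ≈40-fold once a 200 bp
  exon must fit a 1 kb intron).
* `tukey_outlier()` uses type-7 (linearly interpolated) quartiles — worth
  stating because Tukey fences are sensitive to the quartile convention —
  and flags |score| > 1.5. The score-to-p conversion is an explicit
  reconstruction: a normal model centred at the cohort median with
  σ = IQR/1.349, one-sided by tail, BH-corrected across genes. It should
  be read as a calibrated ranking, not an exact sampling distribution.
* `fisher_enrichment()` reports the conventional two-sided Fisher p (sum of
  equally-or-less-probable tables) and the direct odds ratio
  `(n2/n1)/(t2/t1)` rather than the conditional-MLE estimate, so the
  printed ratio matches the hand calculation from the 2×2 table.

## The simulator and what the benchmark does (and does not) show

`simulate_gene_locus()` draws an i.i.d. genome (10⁶ bp, GC 0.40 by
default) and one plus-strand gene of 100 exons with exon lengths uniform in
15–600 bp and introns in 100–1000 bp; the transcript adds 200 bp UTRs
(absorbed into the terminal exon blocks so they stay genomically
contiguous) and a 50 bp poly(A) tail — the UTR and poly(A) lengths are the
package's own choices where no standard value exists.
`inject_exon_extension()` extends an exon 5′ or 3′ by 5–50 bp and plants an
anchoring point mutation on the extension base adjacent to the novel
boundary, carried by the altered transcript. `simulate_read_mixture()`
draws 75-bp reads uniformly, substitutes bases at rate 0.001 (no indels —
they are not characteristic of the error process being emulated), mixes
altered-origin reads at the requested fraction, and emits gold-standard
spliced alignments derived from each read's origin rather than from a
spliced aligner. This makes the benchmark measure the pipeline's detection
logic independently of any aligner's idiosyncrasies.

For the sensitivity benchmark, reads are simulated over a window (±450 bp
by default) around each assessed junction rather than the whole transcript:
junction detection depends only on junction-spanning reads, and windowed
simulation keeps a 20-event benchmark at 200× coverage to roughly half a
million read bases per seed. The problem sizes used by the acceptance
script are one 10⁶ bp locus, 20 injected extensions, 200× coverage and
five seeds.

What a high benchmark sensitivity shows: the discovery, filtering,
spliced-in and classification logic recover exactly the injected junctions
at realistic support levels, and do so stably across mixture fractions.
What it does not show: robustness to alignment error (gold alignments have
none), to indels and complex error profiles, to polymorphic or repetitive
real genomes, or to annotation incompleteness. Sensitivity on real tumours
is bounded above by what the spliced aligner surfaces.

## Degenerate inputs and tie-breaks

* Zero depth yields JAF 0, never a division error; supporting reads never
  exceed the assessed depth by construction.
* An empty mutation list, an empty candidate set after any stage, or a
  mutation with no nearby junction all produce empty, successful results.
* Equal-probability tables in the Fisher test and ties in the case/control
  comparison resolve against the candidate (conservative).
* The mate-site search breaks ties by read count, then score, then
  position, and is therefore a pure function of its inputs.
* All simulator randomness flows from a single integer seed; the pipeline
  proper is deterministic.

## Known limitations

* Substitution mutations only in the spliced-in check; indels are flagged
  indeterminate rather than evaluated inside reads.
* The first-order splice model ignores positional dependencies; deltas for
  mutations outside the 9/23-mer windows are zero by construction.
* Branch-point and exonic splicing enhancer/silencer effects are not
  modelled.
* The classifier assigns fusion/new-transcript categories from annotation
  context only; it does not assemble transcripts or predict
  nonsense-mediated decay.
* Cohort-scale quantities (counts of events by category across a tumour
  cohort, mean score shifts, outlier lists) depend on controlled-access
  data and are outside what the simulator can reproduce; the package's
  claims there are limited to the property checks the test suite runs.
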