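---
title: "Splice-signal models behind spliceselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-signal models behind spliceselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceselect)
```

`spliceselect` analyses why an internal ("cassette") exon is included or
skipped, using only cis-acting splice signals: the strengths of the donor
(5′) splice sites flanking the exon, the presence and placement of
branchpoint motifs in the flanking introns, and the architecture
(lengths, conservation) of the surrounding exons and introns. This vignette
explains each model, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer should know about.

## The splicing problem

A cassette exon E sits between two constitutive exons. Splicing can pair the
upstream donor with E's acceptor (inclusion) or splice straight across to
the downstream acceptor (skipping, which removes E together with both
flanking introns). Two cis-level asymmetries favour skipping: a markedly
stronger upstream donor than the exon's own donor, and a weak branchpoint in
the upstream intron combined with a strong one in the downstream intron. The
package quantifies both.

Intron numbering follows the convention that intron *i* lies between exons
*i* and *i+1*; for a cassette exon 7, "5′SS_6" is the donor of the upstream
intron and "5′SS_7" the exon's own donor.

## Donor-site position weight matrices

`build_pwm()` counts bases per position over a set of equal-length junction
strings (by default 5 exonic + up to 12 intronic nucleotides, extracted by
`extract_donor_site()`) and scores

$$\mathrm{score}(b, j) \;=\; \log_2
  \frac{(n_{bj} + s\,q_b)/(n + s)}{q_b}$$

with training-set size $n$, pseudocount $s$ (default 1) and background $q$
(default uniform 0.25, optionally estimated from supplied sequences). A
sequence's PWMS is the sum of its per-position lookups; ambiguity symbols
score 0 and never enter counts. Choices worth stating:

- **Log base 2** throughout, so scores and information content are in bits.
- **Background-scaled Laplace pseudocount.** Published splice-site matrices
  rarely state their exact smoothing; the package therefore treats matrix
  *properties* (normalization, additivity, consensus optimality, recovery of
  a planted probability matrix within ±0.02 per entry at n = 5000) as the
  test surface rather than bit-for-bit reproduction of any published matrix.
- **Score floor −30** replaces $-\infty$ for zero-probability cells at
  pseudocount 0, preserving ordering while keeping arithmetic finite.
- **Width 13 by default** (5 exonic + 8 intronic), matching the bundled
  chromosome-22 donor matrix; extraction supports the wider 5 + 12 window.
  The bundled matrix ships as published log-odds scores without counts
  (`pwm_from_scores()`), and the published per-species PWMS values carried in
  `usp4_donor_panel()` were computed with a wider window than the 13
  published columns — identical 13-mers carry different published scores —
  so those values are treated as data, not as recomputation targets. What
  *is* recomputable from the published columns is frozen into tests: the
  human upstream donor sums to 9.0273 and the column-max sum is 14.3656.
- **Acceptor sites** can be scored with the same machinery under mirrored
  labels; the package exposes but does not privilege this path, since
  flanking acceptor strengths showed no comparable asymmetry.

`paired_pwms_test()` compares paired site-strength samples (upstream vs
downstream donor per species) with a classical two-sided paired t-test,
reporting a degenerate flag instead of failing when the differences have
zero variance.

## Branchpoint model

Branchpoints are modelled as YURAY motifs — `[CT]T[AG]A[CT]` on the DNA
alphabet — scanned with all overlaps reported (`scan_yuray()`). Two
filters turn motif hits into candidates:

1. **Intervening AG exclusion** (`classify_hits()`): a motif is disqualified
   when a non-3′SS `AG` starts at any offset from the motif end up to the
   position before the terminal 3′SS AG, because the first AG after the
   branchpoint is normally committed as the acceptor. The motif itself can
   never contain `AG` (the R–A pair is followed by a pyrimidine), so no
   overlap special-case exists; a test asserts this.
2. **Distance optimality**: `D_to3′` is measured from the *first base* of
   the motif to the intron's 3′ end (`d = L − start`, so a motif occupying
   the final five nucleotides has d = 5 — stated explicitly so histograms
   are comparable across tools). `estimate_opt_window()` finds the smallest
   contiguous window covering at least `coverage_target` of observed
   distances (default 0.75, bracketed by published estimates of 83% within
   21–34 nt for housekeeping introns and a 20–40 nt window genome-wide;
   ties resolve toward the smaller lower bound). `call_strong_bps()` then
   declares a strong branchpoint when a clean candidate falls inside the
   window, choosing the candidate nearest the window midpoint (ties to the
   smaller distance).

Introns that do not end in `AG` are processed with a warning rather than
rejected, tolerating annotation noise. A short-intron filter (default
200 nt) is available for genome-wide distance distributions, where short
introns would bias the histogram; per-intron calls apply no length filter by
default. The whole scan → classify → call path is verified against a
brute-force enumeration oracle on 10⁴ seeded random introns.

## Conservation and length architecture

`column_entropy()` implements $H = -\sum_i p_i \log_2 p_i$ over the observed
residues of an alignment column; gaps are excluded and frequencies
renormalized over residues, because the frequencies are defined over amino
acids. All-gap columns report `NA`, never 0 (a constant column and an empty
column mean opposite things). Columns with non-gap coverage below
`min_coverage` (default 0.5) are masked. `entropy_profile()` smooths with a
centred moving average (default window 9 columns, odd by construction);
both the window and the gap policy are configuration, since profile *shape*
is the scientifically meaningful output and no downstream decision in the
package depends on their exact values. The entropy ceiling is
$\log_2 N$ with $N = 20$ for protein.

`length_summaries()` reduces per-species exon/intron lengths to mode
(smallest value on ties), mode fraction, and range per (clade, unit, index)
cell — the representation used to compare, e.g., a bimodal upstream-intron
length distribution across clades.

## The +6 skipping rule

The discriminant signal for skipping propensity is the sixth intronic
nucleotide of the donor site. Its strengths rank **T > C ≥ A > G**
(`plus6_strength()`): +6T optimal, +6C neutral, +6A/+6G weak. The
prediction rule (`predict_from_plus6()`) is *class-based*:

> skip ⇔ upstream +6 ∈ {T, C} (strong/neutral) **and** downstream +6 ∈
> {A, G} (weak).

A strict ordinal comparison ("upstream stronger than downstream") would be
wrong: the zebrafish configuration +6T upstream / +6C downstream retains the
exon even though T outranks C. The class rule is the minimal rule consistent
with every directly observed configuration (mammalian T;A skipping,
platypus G;A retention, chicken A;A retention, turtle C;A skipping,
zebrafish T;C retention), and those five configurations are pinned in tests.
Two further notes:

- The text ranking places C ≥ A although the bundled matrix's +6 column
  orders G slightly above A; the ordinal map follows the ranking, and
  nothing in the class rule depends on the A/G order (both are weak).
- Exon loss is taken from annotation only (`exon_present = FALSE` →
  `exon_lost`); it is never inferred from sequence divergence.

The secondary rule (`predict_from_pwms()`) calls skipping when
`PWMS_upstream − PWMS_downstream > delta_threshold`. The default threshold 2
is a package calibration chosen between the smallest published mammalian gap
(≈ 2.77) and the largest non-skipping gap (≈ 2.09, frog); it is exposed in
the configuration and documented as such, not as a published constant.

On the bundled 14-species panel the +6 rule calls 9 species alternatively
skipped (8 therians plus the turtle). The shrew classifies as retention
because its published downstream donor carries +6C — the one therian row
whose printed sequence departs from the T;A configuration; the package
classifies the sequences as given.

## Isoform evidence and PSI

`build_probes()` forms three junction probes of length `2 * flank` (default
flank 20): retained E6–E7 and E7–E8, and skipped E6–E8. A read supports a
junction when it contains the probe's central window with at least
`min_overhang` nucleotides on each side of the junction point (default 8,
large enough to rule out single-exon matches at desk scale); matching is
exact by default, with an optional sliding Hamming comparison for up to a
configurable number of substitutions, and reverse complements are checked.
Reads supporting both isoform classes are `ambiguous`; counts conserve
(`retained + skipped + ambiguous + unmatched = total`).

PSI is the fraction of junction evidence supporting inclusion. Two facts
make the naive read-count ratio `retained / (retained + skipped)` a biased
estimator of the underlying inclusion fraction: a retained transcript offers
*two* inclusion junctions, and the retained and skipped transcripts have
different effective lengths. `count_support()` therefore computes inclusion
evidence as the per-junction mean `(c_E6E7 + c_E7E8) / 2` and, when spliced
transcript lengths are supplied, weights junction counts by effective length
(transcript length − read length + 1), which makes the estimator unbiased
even for short transcripts. The raw read-level counts and the long-to-short
ratio `retained / skipped` are reported unchanged alongside. The 95%
interval is a Wilson score interval on the junction-read scale; with
effective-length weighting it is mildly conservative, and seeded simulations
(100 replicates of 2000 reads) show interval coverage at or above nominal.

## Peptide properties

`translate_segment()` translates an exon's coding nucleotides under an
explicit phase (nucleotides carried over from the previous exon), drops the
trailing partial codon, and truncates with a warning at an internal stop.
`profile_peptide()` counts composition, serines, charged residues and net
charge. Histidine counts as positive by default — the published tally of
five positive residues in the human cassette-exon peptide (R, R, K, H, R)
requires it — and the charge convention is a visible parameter. The bundled
peptide string is taken as given (48 letters, though usually described as
47 residues); only its internally consistent properties (16 serines, 5
positive and 1 negative residue, net charge +4) are asserted anywhere.

## What the synthetic generator emulates

`synth_gene_model()` builds a gene as random uniform-composition sequence
with planted landmarks: canonical `GT..AG` introns, requested donor +6
identities, and optional clean YURAY branchpoints at chosen distances. The
defaults are the mammal-like cassette configuration: three exons (cassette
exon 144 nt, matching the 48-codon human cassette peptide; flanking exons
150 nt), upstream intron 500 nt and downstream 300 nt, +6T upstream / +6A
downstream, one clean branchpoint 30 nt from the downstream intron's 3′
end and none in the upstream intron. Within a 3′-terminal purge window
(default 50 nt) accidental clean YURAYs and non-3′SS AGs are removed by
deterministic single-base fix-ups (mutations chosen so they cannot create
new AG dinucleotides), with an iteration cap; this keeps planted truth
exact, which is what makes sensitivity/specificity assertions of 1.0
meaningful. `synth_reads()` draws each read from the retained transcript
with probability `psi` (default 0.7, 2000 reads of 80 nt), uniform start,
substitution errors only.

What this does **not** emulate: biased base composition (available as an
option but off), indels and alignment artefacts, fragmentation and coverage
bias of real RNA-seq libraries, paralogy, or evolutionary sequence
divergence between species. Passing tests on synthetic data therefore
demonstrate correctness of the *computations* — extraction arithmetic,
motif logic, estimator calibration — not robustness to the full messiness
of real transcriptome data.

## Numerical and engineering choices

- Coordinates are 0-based half-open internally; GenBank/GFF3 1-based
  inclusive coordinates are converted at the parsing boundary. Minus-strand
  records are reverse-complemented and remapped on read so exon order is
  always transcription order.
- RNA input (`U`) is normalized to DNA (`T`) everywhere; display may render
  either. Lowercase is uppercased; non-ACGT symbols are retained but score
  as background and never match motifs.
- When a record annotates several transcripts, the longest (largest summed
  exon length) is the default selection, overridable per call — published
  analyses rarely state their per-species transcript choice, so this is an
  explicit package decision.
- A single-exon gene yields an empty intron table (not an error); adjacent
  exons (a zero-length intron) are a validation error.
- Consensus ties break alphabetically and are flagged rather than silently
  resolved.
- `run_pipeline()` is deterministic given config + seed; every tabular
  output carries a config-hash provenance comment, and stage functions can
  be run individually with identical results.

Test problem sizes — 10⁴ random introns for the brute-force branchpoint
oracle, 5000 junctions for matrix recovery, 100 × 2000 reads for interval
coverage — were chosen as the smallest sizes at which the corresponding
statistical claims are sharp (recovery within ±0.02, coverage at the
nominal 95%).

## Known limitations

- The donor model is positionally independent (a PWM); dinucleotide or
  maximum-entropy dependencies are out of scope.
- Branchpoint detection is motif-based; no energetic or learned model, and
  no polypyrimidine-tract scoring.
- The skipping predictor covers the cis-signal model only — trans-acting
  factors, exonic splice enhancers/silencers, and quantitative PSI
  prediction are outside the model by design.
- The junction matcher counts evidence; it is not a spliced aligner, and
  EST/SRA database counts are inherently database-version-dependent, so the
  package reproduces the counting procedure rather than any specific count.
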