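---
title: "Junction-library splicing quantification: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-library splicing quantification: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coenosplice)
```

# The quantification model

`coenosplice` quantifies alternative splicing exclusively from junction
reads. For every annotated transcript it builds a library of reference
sequences:

* **EEJ** — one exon–exon junction per (donor, downstream acceptor)
  pair in transcriptional order, so a gene with exons 1..n contributes
  `choose(n, 2)` forward junctions (constitutive and skipping forms
  alike). Each side of the junction carries an exonic flank of
  `readLen - minOverhang` nucleotides (42 nt at the 50/8 defaults),
  truncated when the exon is shorter.
* **EIJ5 / EIJ3** — the two exon–intron junctions of every intron.
* **intron body** — the whole intron when it is at most 200 nt,
  otherwise a centred 200-nt mid-intron segment (for an even-length
  placement the segment start is `floor(len/2 - 100) + 1`, i.e. the
  left of the two centre candidates).

Reads are first split into 50-nt *read groups* with a 25-nt sliding
step (a 100-nt read gives 3 windows, a 125-nt read 4), pooled across
mates, and mapped against the genome plus the EEJ references. A window
is *placed* only when it has exactly one location in the whole
reference set within the mismatch allowance — the contract of unique
mapping with at most two mismatches. To avoid counting one sequenced
molecule twice, exactly one window per read group — chosen uniformly at
random *before* looking at the placements — is eligible to be counted.
Choosing among placed windows instead would silently over-weight reads
whose other windows fail to map (junction reads with sub-minimum
overhangs), which biases inclusion ratios; the pre-mapping choice keeps
every (read, window) combination equally likely.

EIJ and intron-body references are contiguous genome substrings. Had
they been added to the mapping index alongside the genome, every read
supporting them would match two locations (the reference and its source
locus) and be discarded as multi-mapping. They are therefore counted
from unique *genome* placements by coordinate overlap: a window
supports EIJ5/EIJ3 when it covers the exon–intron boundary with at
least `minOverhang` nucleotides on each side (mirroring the EEJ window
definition), and the intron body when it falls entirely inside the body
segment. Only EEJ-type references (annotated, de novo, microexon) enter
the mapping index.

## Mappability correction

Repetitive flanks make some junction windows ambiguous. For each EEJ
and EIJ the package counts the junction-spanning start positions whose
window occurs nowhere else in the combined reference set (both genome
strands plus all EEJ references):

```
corrected = raw * max_mappability / mappability
max_mappability = readLen - 2 * minOverhang + 1   # 35 at 50/8
```

A raw count of zero stays zero; zero mappable positions make the
junction unquantifiable (`NA`) rather than dividing by zero. The
minimum overhang of 8 nt is the value consistent with a 35-position
maximum for 50-nt reads; it is configurable.

## PIR and PSI

Retention and inclusion are estimated from corrected counts:

```
PIR = 100 * R / (R + EEJ),   R = (EIJ5 + EIJ3) / 2
PSI = 100 * I / (I + S),     I = (up + down) / 2
```

These closed forms average the two flanking junctions; summing them
instead would double-weight retention/inclusion relative to the single
EEJ and is not used. Supporting flags:

* `coverage_ok` — mean raw flanking-junction count plus the raw
  EEJ/skip count reaches `minCoverage` (default 20 reads per splice
  junction).
* `balance_ok` (IR only) — a two-sided exact binomial test of raw EIJ5
  versus EIJ3 (null p = 0.5) does not reject at `balanceAlpha = 0.05`,
  and the intron body has nonzero support whenever retention support is
  nonzero. The body acts as a presence check only; it is not part of
  the test statistic, and introns shorter than the read window (no
  possible body window) skip the check.

Event-level thresholds: an intron is a positive retention event at
PIR ≥ 20 in at least one sample and constitutive below 2 in all; an
exon is alternative at PSI ≤ 90 in at least one sample. Differential
calls require a stage-mean difference above 15 points, every stage's
replicate standard deviation (n−1 denominator) below 10, and adequate
coverage in all samples. Stage means are arithmetic means of replicate
values; Δ uses stage means rather than replicate-pair extremes.

## De novo splice sites and microexons

For each annotated donor the two downstream introns are scanned for AG
acceptor candidates (and symmetrically, upstream introns for GT
donors); "two downstream/upstream introns" is read as the two introns
adjacent in transcriptional order. A candidate's novel EEJ joins the
annotated exonic flank to the contiguous genomic sequence beyond the
motif. Acceptance needs at least 5 supporting read groups over at
least 2 distinct start positions — the support threshold follows the
pipeline's published constant; the two-position minimum operationalises
"multiple positions", which is otherwise unquantified, and is
configurable. Microexon scanning looks for internal AG...GT segments of
3–15 nt inside annotated introns, each yielding the two EEJs that join
it to its flanking exons.

# The synthetic-data generator

The generator is first-class, tested code; it emulates the study
conditions the pipeline targets: a compact genome, two cell stages with
three stranded 100-nt replicates each, and known truth for every
downstream quantity. Defaults: 20 genes of 3–7 exons (150–350 nt) with
80–300 nt GT–AG introns, 8 single-exon lincRNA loci of 400–900 nt in
intergenic gaps of 1200–2500 nt, 50% GC, and 70% of lincRNA loci placed
head-to-head with their nearest gene — the over-representation the
orientation statistics are designed to detect. Coding mRNAs carry one
full-length ORF with uniformly drawn sense codons; noncoding loci are
stop-scrubbed so no forward-frame ORF reaches 60 codons, keeping the
two classes separable by construction.

Reads are simulated by (i) allocating the library size across features
multinomially with weights expression × mature length, (ii) drawing
each read's isoform by independent Bernoulli trials against the PIR /
PSI truth (introns flanking a skipped exon are always spliced), with
the pattern frequencies tilted by isoform length — fragments come from
molecules in proportion to molarity × length, and omitting the tilt
demonstrably biases PIR downward by several points — and (iii) taking a
uniform start position. Reads report the transcript strand (a stranded
dUTP-style protocol) and carry no sequencing errors, no GC bias and no
positional bias; single-end only, since counting pools mates anyway.

Because simulated reads are error-free, the default mapping path uses
exact hash matching of fixed-width windows, which keeps the end-to-end
tests fast. The mismatch-tolerant path (three disjoint trusted bands;
any two-mismatch location is exact in at least one band, so the search
is exhaustive) exists for data with errors and is exercised on small
fixtures. What passing tests show is therefore parameter recovery and
rule fidelity under clean reads — not robustness to sequencing error,
bias or misannotation, which real data add on top.

Decoy loci (one per cascade failure mode: too short, known ncRNA
family, repeat overlap, low expression, UTR-proximal head-to-tail) can
be planted so that every cascade filter rejects exactly one known
candidate.

# The lincRNA cascade

Filters run in a fixed order — length > 200 nt; no homology hit below
e-value 1e-3; no ncRNA-family hit; coding-potential score < −0.5;
no overlap with gene+UTR annotation; UTR-proximity screen; no repeat
overlap; collapse into loci; expression — and the audit records each
candidate's first rejecting step, so rejections plus survivors always
equal the input. Steps 1–7 are independent per-candidate predicates;
the survivor set is unchanged under their reordering, only the audit
labels move.

Design choices where the procedure was genuinely open:

* **UTR-proximity (step 6).** Head-to-tail candidates closer than
  1000 nt to the adjacent gene are flagged as likely mis-annotated UTRs
  and dropped by default; `keepFlagged = TRUE` retains them, replacing
  a manual-review step that cannot live in a pipeline.
* **Orientation.** The class is decided against the *nearest*
  protein-coding gene: head-to-head iff the strands differ (divergent
  pairs may share a bidirectional promoter), head-to-tail otherwise.
  This binary split covers every classified pair and is symmetric under
  reverse-complementing the whole fixture. The generator places each
  lincRNA nearer the flanking gene that defines its intended class.
* **Expression (step 9).** At least 5 FPKM in one sample *and* more
  than 1 FPKM in all remaining samples. The all-remaining reading is
  the stricter of the two plausible readings of "any other sample" and
  is configurable (`exprRule = "any"`).
* **Coding potential.** The built-in scorer is intentionally simple:
  `2.0 * min(L, 150)/100 + bias − 2.8`, with `L` the longest
  forward-frame ORF in codons and `bias` the codon-usage entropy
  deficit inside that ORF. Any sequence without an ORF of ≥ 100 codons
  scores below −0.5 unless its codon usage is extremely skewed; a
  sequence with no ORF at all gets the floor −2.8. The cascade equally
  accepts externally computed scores through the evidence table, which
  is the intended route for real data.

The orientation χ² is a one-degree-of-freedom goodness-of-fit test
against 50/50 without continuity correction (two categories, large n);
the printed significance bound is treated as an upper bound since the
exact test variant used upstream is unstated. Neighbour enrichment uses
a two-sided Fisher exact test on the 2×2 table.

# Cross-species clustering

Ortholog expression matrices are transformed `log2(x + 1)` and quantile
normalized (rank means across columns, ties sharing their mean — after
the step all columns have identical sorted values, asserted exactly in
the tests). Sample distances are `1 − ρ` with Spearman's ρ and
average-rank ties; the plain `1 − ρ` form (rather than `(1 − ρ)/2`) is
used since only relative distances matter to the trees, and one shared
distance matrix feeds both the complete-linkage dendrogram and the
neighbor-joining tree. Bootstrap support resamples genes (rows) with
replacement, 100 replicates by default, and reports the percentage of
replicates containing each internal bipartition. PCA runs on centred,
unscaled normalized values (the quantile step already equalizes the
column distributions); component signs are fixed so the
largest-magnitude loading is positive, making "loading > threshold"
gene selections reproducible. Module co-regulation is the mean
off-diagonal Pearson correlation of the module's genes, compared
against resampled size-matched random gene sets.

# Secretome triage

The cascade is conjunctive: require signal-peptide D-score ≥ 0.450
(boundary inclusive, the usual predictor convention for a cutoff);
reject a transmembrane helix *starting* after residue 60 (a TM segment
within the signal region is tolerated); reject mitochondrial targeting;
reject a C-terminal KDEL/HDEL/HDEF tetrapeptide; reject GPI anchors.
The final secreted set is invariant to the order of the rejection
steps — only the recorded `rejecting_step` labels depend on it — and
every input protein appears in exactly one result row. External
predictors are consumed as tables, never reimplemented.

# Differential expression stand-in

The package's differential-expression caller exists to exercise
downstream plumbing on synthetic data. The statistic is the log2 ratio
of stage means with a pseudocount of 1; its null pools the statistics
of all genes over balanced replicate relabelings, excluding the
observed labeling and its mirror (which carry the signal itself), with
BH adjustment at q ≤ 0.05. Pooling is what makes 3-versus-3 designs
workable: pure label permutation cannot produce p below 0.1 at that
size. It is a deliberately simple caller, not a replacement for a
count-model package on real data.

# Numerical and scale choices

* All generator and analysis randomness is seeded; identical spec +
  seed reproduce fixtures byte for byte.
* Internal coordinates are 0/1-based R conventions with GTF emitted
  1-based inclusive; a single chromosome per fixture.
* The end-to-end recovery checks use a 10-gene genome, two stages with
  three replicates of 60,000 100-nt reads each, giving ≥ 100×
  corrected junction coverage; at that depth mean absolute PIR/PSI
  recovery error is ~1 point against truth levels {0, 25, 50, 75,
  100}, well inside the 5-point acceptance band, and planted Δ ≥ 30
  differential events are recovered with no calls in a same-truth null
  comparison.
* Mappability uniqueness uses exact matching by default; a mismatch
  allowance is available and is quadratic in fixture size, intended
  for references of at most ~100 kb.

# Known limitations

* Only intron retention and cassette-exon skipping are modelled — no
  alternative 5'/3' splice sites, no mutually exclusive exons, no
  non-canonical (GC–AG, AT–AC) introns.
* The simulator omits sequencing error, GC and positional bias, and
  paired-end fragment-length structure; conclusions from synthetic
  recovery transfer to real data only insofar as those factors are
  secondary to junction sampling noise.
* The coding-potential scorer is a calibrated stand-in: adequate for
  fixtures whose classes are separable by ORF content, not a trained
  classifier.
* lincRNA loci are single-exon in the generator; the cascade itself
  accepts multi-exon candidates.
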