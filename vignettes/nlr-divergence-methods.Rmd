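---
title: "Methods: NLR classification, mapping, CNV detection and pseudogene scanning"
author: "nlrpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NLR classification, mapping, CNV detection and pseudogene scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, rules and numerical choices behind
`nlrpan`, in the order the pipeline applies them, and states what the
synthetic-data generator does and does not emulate.

## 1. NLR classification

NLRs are defined through the conserved NB-ARC domain, scanned here as four
short motifs.  The defaults are curated consensus regular expressions:

| motif    | pattern               |
|----------|-----------------------|
| P-loop   | `G....GK[ST]`         |
| Kinase-2 | `[LIVMF][LIVMF][LIVMF]DD` |
| GLPL     | `GLPL[AST]`           |
| MHDV     | `MHD[VLIA]`           |

Any protein with at least one motif hit is a candidate.  The intact rule:
pick the best-scoring (tie: leftmost) hit per motif; a candidate is
*intact* iff at least 3 distinct motifs are present, their starts strictly
increase in the canonical architecture order P-loop < Kinase-2 < GLPL <
MHDV (restricted to the motifs present), and the span from the first
selected hit's start to the last selected hit's end is at least 160 aa.
Everything else is *partial*.

Design notes.  Published NLR scanners use MEME-derived probabilistic motif
models whose matrices are not generally redistributable; the regular
expressions above are deterministic stand-ins, and `scan_motifs()` accepts
user position-weight matrices (`list(pwm=, cutoff=)`) where a calibrated
profile with a score cutoff is preferred.  The NB-ARC boundary needed for
the 160-aa length test is not uniquely defined in the literature; we use
first-hit-start to last-hit-end, which is deterministic and reproducible.
Overlapping hits of one motif collapse to the best-scoring, leftmost one.

## 2. Subgroup assignment

Intact NB-ARC domains are aligned with an in-house deterministic
progressive aligner: a 3-mer-composition guide tree (average linkage)
orders profile–profile merges, each merge a global affine-gap alignment
(BLOSUM62; gap open −10, extension −1) of amino-acid frequency profiles.
Columns with gap fraction strictly above 0.92 are removed (a column at
exactly 0.92 is kept).  Identity distances (1 − identities/comparable
columns; pairs with no comparable columns get distance 1 with a warning)
feed Saitou–Nei neighbor joining (via `ape`), and supports come from a
standard nonparametric column-resampling bootstrap.

The assignment rule is the same whether the tree comes from the in-house
NJ stage or is imported as Newick with supports in internal node labels
(`read_support_tree()`): each unlabelled leaf takes the group of the
*smallest* clade — either side of an internal edge with support at least
90 — whose labelled references are unanimous; no such clade leaves the
query unassigned.  A full maximum-likelihood + ultrafast-bootstrap stack
can therefore be substituted wholesale without touching the rule, which is
the part of the procedure this package commits to.

Partial NLRs are assigned by vote: local alignment (Smith–Waterman,
BLOSUM62) against every labelled intact NB-ARC; a *match* requires
similarity ≥ 0.5 and reference coverage ≥ 0.3, where similarity is the
fraction of alignment columns with a positive substitution score (the
"positives" convention) and coverage is the aligned fraction of the
reference NB-ARC length.  Whether published thresholds of this kind refer
to identities or positives, query or subject coverage, is ambiguous;
both definitions are configurable and the defaults are the positives /
subject-coverage reading.  Vote ties resolve to the group of the single
highest-similarity match, then lexicographically — determinism over
cleverness.

## 3. The NLR map

Anchors are maximal runs of k-mers (k = 21 by default, refusing k < 12)
unique in both sequences, merged along diagonals, on both strands — a
desk-scale stand-in for a maximal-unique-match aligner.  Chaining keeps,
per strand, the collinear chain of maximum total matched bp
(longest-increasing-subsequence dynamic programming), which is the 1-to-1
filtering contract of production whole-genome aligners; a PAF
import/export (`read_paf()`, `write_paf()`) lets one substitute a real
aligner.  Anchors may extend a few bases across a variant junction when
flanking bases coincide, so the chain DP tolerates overlaps up to 30 bp
and trims them off the later block afterwards; without this, an anchor
block flanked by two insertions can be evicted wholesale and a spurious
chain gap appears.

Projection uses the gene midpoint, which is robust to genes that straddle
chain gaps: a midpoint inside a block maps by exact offset; between two
chain blocks at most 100 kb apart (the same flanking scale used for
target-region extraction) the interval is interpolated between block
edges, and a zero-length reference gap is flagged `inserted` — the
signature of an accession-specific insertion.  Everything else is
unmapped and reported.  Reference genes map to themselves.

## 4. Physical clusters and the ortholog catalog

Mapped NLRs merge into physical clusters when consecutive genes are
separated by strictly less than 50 kb (bedtools-merge distance semantics;
a gap of exactly 50,000 bp separates clusters).  Orthology is inferred
*within* clusters only — synteny-constrained by construction — as
reciprocal best hits on global-alignment similarity (thresholds as in the
partial vote), with connected components split greedily (weakest edge
first) until no group has more than one member per accession.  That
≤1-per-accession composition is what makes "core" arithmetic exact: a
core group in an n-accession panel has exactly n genes.

Categories: *specific* = exactly one accession (checked first, so a
single-accession panel is all-specific), *core* = all accessions,
*dispensable* otherwise.  Percentages are taken against the total NLR
candidate count (mapped or not) and rounded half-up to one decimal, so
printed category percentages reproduce published-style accounting tables
exactly.  Pan/core accumulation curves enumerate all accession orderings
up to 6 accessions (k! ≤ 720) and sample orderings with a seed beyond.

## 5. CNV statistics

Only one margin exists in a cluster-count table (assembly completeness
differs by accession but is ignored, as in the source procedure), so the
test is a goodness-of-fit of per-accession counts against their own mean:
chi2 = Σ(o − e)²/e with e = row mean and df = n − 1, upper tail.  Rows
first pass a sample standard deviation filter (n − 1 denominator; a panel
of 5 accessions is a sample) with threshold SD > 2.  Benjamini–Hochberg
adjustment runs across the tested rows only, and significance means
q < 0.05.  Expected counts below 5 are flagged (`expected_ok`) rather
than blocked — small-count chi-square is knowingly kept, as in the
procedure this mirrors.

Window enrichment tiles each reference sequence with non-overlapping 1 Mb
windows and tests each (window, subgroup) pair with at least one member by
the exact hypergeometric upper tail (binomial available by option), BH
over all emitted tests.

Calibration is tested at the counts level (`simulate_cluster_counts()`):
under a shared per-member retention probability the per-cluster counts
differ only by chance, and the acceptance suite checks the significant
fraction stays within 3σ of the nominal level over 200 such panels, while
planted 16/15/1/9/12-style effects are recovered in ≥95 % of 100
replicates.  Running 200 full genome simulations would test the same
statistics at ~100× the cost; the genome-level path is exercised once,
end to end, in the pipeline tests.

## 6. Frameshift-aware pseudogene scanning

`frameshift_align()` is an exact dynamic program in codon space over
states: codon aligned to a residue (BLOSUM62 on the translation; stop
codons read through at −20 so stops downstream of the first are still
counted), protein gap (affine, −11/−1), DNA codon gap (affine per codon,
−11/−1), ±1/±2 frameshift codons (−30 per shift), and a long-DNA-gap
state (flat −40 to open, free extension) that models multi-kilobase
insertions — without it, an ~8 kb insertion is cheaper to explain by
truncating the alignment than by jumping, and large insertions would be
invisible.  The DP is glocal by default (free DNA flanks, whole protein
consumed), with `ends_free = FALSE` forcing full-region alignment for
exact-region analyses.  Tie-breaks prefer codon alignment over gaps over
frameshifts, then leftmost paths.  The implementation is Rcpp; a 250-aa
protein against a 25-kb region runs in well under a second.

Event calling: stop-codon read-throughs → premature stops (with protein
codon index and genomic position); frameshift ops → frameshift
insertions/deletions; DNA-gap runs ≥ 1,000 bp → large insertions.  A
frameshift is localized to its op span (one codon plus the shift): when
the inserted or deleted bases coincide with their neighbours the finer
placement is mathematically ambiguous, and the leftmost optimal path is
reported.  Stop counts are taken along the single optimal path, not per
frame.

`compare_region()` projects a reference gene into another accession
through the inverted anchor chain, pads by 10 kb, aligns on both strands
and keeps the better.  The verdict uses the *exact codon match* fraction
of the protein: below 0.5 the region is called `absent` (random DNA still
"aligns" residues at slightly negative score under affine gap costs, so a
substitution-level fraction would not separate deleted loci); otherwise
any event makes it `pseudogenized`, else `conserved`.

## 7. The synthetic panel: what it does and does not emulate

`simulate_reference()` builds chromosomes carrying clustered, intronless
NLR genes on random backbone sequence.  Each simulated protein is
leader + P-loop + spacer1 + Kinase-2 + spacer2 + GLPL + spacer3 + MHDV +
tail, with the NB-ARC span (motifs plus spacers) 164 aa ≥ the 160-aa
intact threshold by construction.  Subgroup identity is realized as
subgroup-specific random "barcode" spacers with small per-gene noise
(default 2 % per position), so within-subgroup distance (~4 %) is far
below between-subgroup distance (~80 %), and both the tree route and the
vote route can be validated against planted labels.  Random filler is
drawn from an amino-acid alphabet excluding M, D, K and P, which makes the
four motif patterns unable to arise by chance in filler — motif order is
then deterministic by construction, not probabilistically so.

`derive_accession()` plants, per gene, at most one of deletion /
duplication / large insertion / targeted stop-gain (in that precedence
order), then genome-wide SNVs and 1–10 bp InDels; background InDels never
overlap a gene boundary or a gene-targeted edit, keeping annotation
liftover exact.  Stop-gains are planted between Kinase-2 and GLPL so the
truncated protein demotes to partial (two motifs lost).  Large insertions
are drawn at 7,500–8,500 bp, the magnitude at which real intra-species
insertions have been observed to break NLR orthology.  Duplications copy
the reference allele to 0.5–1.5 kb downstream (inside the cluster).  A
master seed expands into fixed-arithmetic child seeds per accession; the
determinism contract — identical config and seed give byte-identical
FASTA/GFF3 — is tested.

Default mutation rates (SNV 10⁻³/bp, InDel 10⁻⁴/bp, a few percent of
genes hit by structural or stop-gain events) were chosen once as
plausible for an inbred crop panel and are not tuned: tests that need
exactness switch individual rates to zero, tests of degradation raise
them.

Not emulated: repeat content and transposons, heterozygosity, assembly
gaps, realistic base composition, intron-containing genes (v1 is
intronless, so spliced alignment is out of scope), inversions and
translocations.  A green test on this panel therefore establishes the
correctness of the *rules and algorithms* under planted truth, not
performance on repeat-rich real assemblies — anchoring in particular is
much harder in genuinely repetitive NLR clusters than on random backbone.

## 8. Degenerate inputs and other fixed conventions

* Coordinates are 0-based half-open everywhere internally; GFF3/BED/PAF
  conversions happen only at I/O boundaries.
* One representative mRNA per gene (longest CDS, ties by identifier):
  alternative-isoform handling is not specified in the procedures this
  package mirrors, so the deterministic rule is ours.
* FASTA ambiguity codes other than N are rejected at parse time.
* `sample()`-style range parameters are validated (cluster gap ranges
  must bracket the 50 kb threshold from the correct sides), and requesting
  more planted CNV clusters than clusters, a reference count below the
  planted row maximum, or a chromosome too short for its clusters all fail
  fast with config errors.
* Empty inputs (empty FASTA, empty cluster list, zero-NLR windows,
  `n_reps = 0` bootstraps) return empty results of the right shape rather
  than erroring.

## 9. Known limitations

Anchor seeding is k-mer-uniqueness based and will fragment in long
perfect repeats; the PAF import exists for exactly that case.  The
chi-square test is asymptotic and knowingly applied at small counts
(flagged, optionally replaceable by Monte-Carlo in a future version).
Partial-NLR votes scale as queries × references local alignments — fine
for hundreds, slow for tens of thousands.  Frameshift positions are
codon-resolution by the nature of the DP.  The in-house progressive
aligner is adequate for the ~165-aa NB-ARC domain family; for full-length
divergent proteins a production MSA tool should be imported instead.
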