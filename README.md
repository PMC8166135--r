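# nlrpan

Intra-species divergence analysis of plant NLR immune receptor genes across
a panel of genome-assembled accessions.

## The problem

Plant disease resistance is largely carried by NLR genes
(nucleotide-binding, leucine-rich-repeat receptors).  Within a single
species, NLR repertoires diverge fast: clusters of tandem NLRs expand and
contract, genes are lost to premature stop codons and frameshift InDels,
and multi-kilobase insertions break ortholog relationships.  Comparing NLR
repertoires across several accessions of one species therefore needs more
than per-genome annotation: the genes of every accession must be placed on
a common coordinate system before copy numbers can be compared locus by
locus.

`nlrpan` implements that comparison end to end, for anyone with a few
annotated genome assemblies of one species (or with the built-in
simulator):

1. **NLR classification** (`scan_motifs()`, `classify_intact()`,
   `select_candidates()`).  Proteins are scanned for the four major NB-ARC
   motifs.  A candidate is *intact* when at least 3 of the 4 motifs occur
   in the canonical order P-loop < Kinase-2 < GLPL < MHDV over a span of at
   least 160 aa; any other motif-bearing protein is *partial*.
2. **Subgroup assignment** (`progressive_align()`, `trim_columns()`,
   `nj_tree()`, `bootstrap_support()`, `assign_intact_groups()`,
   `assign_partial_groups()`).  Intact NB-ARC domains are aligned, columns
   with > 92 % gaps removed, a neighbor-joining tree built with
   column-resampling bootstrap, and each query inherits the subgroup of the
   smallest clade with support >= 90 whose labelled references agree.
   Partial NLRs are assigned by a similarity vote (most reference matches
   at >= 50 % similarity and >= 30 % coverage).
3. **NLR map** (`find_mums()`, `chain_blocks()`, `project_interval()`,
   `build_map()`).  Unique exact matches seed 1-to-1 collinear anchor
   chains; every accession's NLRs are projected onto the reference
   coordinate system through them.
4. **Ortholog catalog** (`merge_physical_clusters()`, `ortho_catalog()`,
   `categorize()`, `pan_core_curve()`).  Mapped NLRs within 50 kb of each
   other form physical clusters; reciprocal-best-hit orthology inside each
   cluster yields groups classified *core* (all accessions),
   *dispensable* (2+, not all) or *specific* (one accession), plus pan/core
   accumulation curves.
5. **CNV statistics** (`detect_cnv_regions()`,
   `window_subgroup_enrichment()`).  Clusters whose per-accession counts
   have sample SD > 2 are tested by a chi-square goodness-of-fit against
   equal copy number, with Benjamini-Hochberg FDR across tested clusters
   (significant at q < 0.05); 1 Mb windows are tested for subgroup
   enrichment with an exact hypergeometric tail.
6. **Pseudogene mechanics** (`frameshift_align()`, `detect_events()`,
   `compare_region()`).  A frameshift-aware protein-to-DNA dynamic
   programming alignment (codon substitutions, +-1/+-2 frameshifts,
   stop-codon read-through, long-gap state) explains *why* a copy is
   missing: premature stops, frameshift InDels, or large (~8 kb)
   insertions.

A genome simulator (`simulate_panel()` and friends) generates
multi-accession panels with planted SNVs, InDels, insertions, deletions,
duplications and stop-gains — with a full ground-truth event table — so
every stage is testable against known answers.

## Worked example

```r
library(nlrpan)

cfg <- pipeline_config(
  panel_cfg = panel_config(n_accessions = 5, n_chromosomes = 1,
                           chromosome_length = 1.1e6, n_clusters = 4,
                           genes_per_cluster = c(2, 3)),
  mut_cfg = mutation_config(0, 0, 0, 0, 0, 0),
  planted_counts = rbind(c(16, 15, 1, 9, 12)),
  seed = 12, boot_reps = 0)
res <- suppressWarnings(run_pipeline(cfg))
res$cnv[res$cnv$significant,
        c("cluster_id", "ACC01", "ACC03", "sd", "chi2", "p", "q")]
#>        cluster_id ACC01 ACC03       sd     chi2           p           q
#> CL0001     CL0001    16     1 6.024948 13.69811 0.008323576 0.008323576
```

One cluster was planted with per-accession copy numbers 16, 15, 1, 9 and
12.  The pipeline re-detects exactly that cluster: the counts recovered
from the full classify-map-cluster chain match the planted ones, their
sample standard deviation 6.02 passes the SD > 2 filter, and the
chi-square test against equal copy number (chi2 = 13.70, df = 4,
p = 0.0083) stays significant after FDR adjustment.  The
`res$pseudogenes` table then reports, per reference gene and accession,
whether the missing copies are truly absent or pseudogenized, and by which
mechanism.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates a five-accession panel (background SNVs, InDels, structural
events, plus one planted strong-effect CNV cluster), runs the whole
pipeline on it — classification, subgroup assignment, NLR map, ortholog
catalog, CNV tests, pseudogene scan — prints the catalog and CNV summary,
writes all stage outputs under `results/pipeline_run/`, and writes the
acceptance JSON to `--out`.
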