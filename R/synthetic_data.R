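# Multi-accession genome simulator with planted ground truth.
#
# The simulator emulates a small panel of inbred accessions of one species:
# accession 1 is the reference; every other accession is derived from it by
# planted sequence variation (SNVs, small InDels, ~8 kb insertions, gene
# deletions/duplications, targeted premature stop codons).  NLR genes are
# intronless, carry the four NB-ARC motifs in canonical order, sit in
# physical clusters whose within-cluster gaps are < 50 kb and between-cluster
# gaps > 50 kb, and encode their subgroup identity as subgroup-specific
# "barcode" spacer segments between the conserved motifs, so that sequence
# distance within a subgroup is far smaller than between subgroups.
#
# Random protein filler is drawn from an alphabet excluding M, D, K and P:
# none of the four default motif patterns can then arise by chance in filler
# (P-loop needs K, Kinase2 needs DD, GLPL needs P, MHDV needs D), which keeps
# motif order deterministic by construction.

FILLER_AA <- setdiff(AMINO_ACIDS, c("M", "D", "K", "P"))

# amino-acid segment lengths of the simulated NLR template
NLR_LAYOUT <- list(leader = 45L, s1 = 60L, s2 = 50L, s3 = 30L, tail = 40L)
MOTIF_AA <- list("P-loop" = "GMGGVGKT", "Kinase2" = "LLVLDDV",
                 "GLPL" = "GLPLA", "MHDV" = "MHDV")

# codon choices per amino acid (standard code), fixed order for determinism
CODONS_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

#' Panel configuration for the genome simulator
#'
#' @param n_accessions number of accessions (reference included), >= 1.
#' @param n_chromosomes chromosomes per accession.
#' @param chromosome_length chromosome length in bp.
#' @param n_clusters total number of NLR physical clusters (distributed
#'   round-robin over chromosomes).
#' @param genes_per_cluster length-2 range of genes per cluster.
#' @param intra_cluster_gap length-2 bp range of gaps between genes inside a
#'   cluster; must stay below 50 kb.
#' @param inter_cluster_gap length-2 bp range of gaps between clusters; must
#'   stay above 50 kb.
#' @param subgroup_labels subgroup labels to plant.
#' @param barcode_noise per-position substitution probability applied to the
#'   subgroup barcode spacers of each gene (within-subgroup variation).
#' @return validated config list of class `nlr_panel_config`.
#' @export
panel_config <- function(n_accessions = 5L, n_chromosomes = 2L,
                         chromosome_length = 1e6, n_clusters = 8L,
                         genes_per_cluster = c(2L, 6L),
                         intra_cluster_gap = c(2000L, 20000L),
                         inter_cluster_gap = c(60000L, 150000L),
                         subgroup_labels = c("G1", "G2", "G8", "G10",
                                             "GT", "GR"),
                         barcode_noise = 0.02) {
  stopifnot(n_accessions >= 1L, n_chromosomes >= 1L, n_clusters >= 1L,
            chromosome_length >= 1L,
            length(genes_per_cluster) == 2L, all(genes_per_cluster >= 1L),
            diff(genes_per_cluster) >= 0,
            all(intra_cluster_gap > 0), all(inter_cluster_gap > 0),
            barcode_noise >= 0, barcode_noise < 1,
            length(subgroup_labels) >= 1L)
  if (intra_cluster_gap[2L] >= 50000L) {
    stop("intra_cluster_gap must stay below the 50 kb clustering threshold")
  }
  if (inter_cluster_gap[1L] <= 50000L) {
    stop("inter_cluster_gap must stay above the 50 kb clustering threshold")
  }
  structure(list(
    n_accessions = as.integer(n_accessions),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.numeric(chromosome_length),
    n_clusters = as.integer(n_clusters),
    genes_per_cluster = as.integer(genes_per_cluster),
    intra_cluster_gap = as.integer(intra_cluster_gap),
    inter_cluster_gap = as.integer(inter_cluster_gap),
    subgroup_labels = as.character(subgroup_labels),
    barcode_noise = barcode_noise,
    accession_ids = sprintf("ACC%02d", seq_len(n_accessions))
  ), class = "nlr_panel_config")
}

#' Mutation configuration for derived accessions
#'
#' Defaults reflect a realistic inbred intra-species panel: ~1 SNV per kb,
#' one small InDel per 10 kb, and a few percent of genes hit by structural or
#' stop-gain events.
#'
#' @param snv_rate substitutions per bp.
#' @param small_indel_rate InDel events per bp (lengths 1-10 bp).
#' @param large_insertion_prob per-gene probability of a ~8 kb insertion into
#'   the CDS.
#' @param gene_deletion_prob per-gene probability of whole-gene deletion.
#' @param gene_duplication_prob per-gene probability of a tandem duplication
#'   placed < 50 kb away.
#' @param premature_stop_prob per-gene probability of a targeted stop-gain
#'   codon change.
#' @param large_insertion_length length-2 bp range of large insertions.
#' @return validated config of class `nlr_mutation_config`.
#' @export
mutation_config <- function(snv_rate = 0.001, small_indel_rate = 1e-4,
                            large_insertion_prob = 0.02,
                            gene_deletion_prob = 0.05,
                            gene_duplication_prob = 0.05,
                            premature_stop_prob = 0.05,
                            large_insertion_length = c(7500L, 8500L)) {
  probs <- c(large_insertion_prob, gene_deletion_prob,
             gene_duplication_prob, premature_stop_prob)
  stopifnot(snv_rate >= 0, small_indel_rate >= 0,
            all(probs >= 0), all(probs <= 1),
            length(large_insertion_length) == 2L,
            all(large_insertion_length > 0))
  structure(list(snv_rate = snv_rate, small_indel_rate = small_indel_rate,
                 large_insertion_prob = large_insertion_prob,
                 gene_deletion_prob = gene_deletion_prob,
                 gene_duplication_prob = gene_duplication_prob,
                 premature_stop_prob = premature_stop_prob,
                 large_insertion_length = as.integer(large_insertion_length)),
            class = "nlr_mutation_config")
}

random_filler <- function(n) {
  paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")
}

noisy_barcode <- function(s, p) {
  if (p <= 0) return(s)
  aa <- strsplit(s, "")[[1L]]
  hit <- runif(length(aa)) < p
  if (any(hit)) aa[hit] <- sample(FILLER_AA, sum(hit), replace = TRUE)
  paste(aa, collapse = "")
}

make_subgroup_barcodes <- function(subgroups) {
  setNames(lapply(subgroups, function(g) {
    list(s1 = random_filler(NLR_LAYOUT$s1),
         s2 = random_filler(NLR_LAYOUT$s2),
         s3 = random_filler(NLR_LAYOUT$s3))
  }), subgroups)
}

simulate_nlr_protein <- function(subgroup, barcodes, noise) {
  bc <- barcodes[[subgroup]]
  paste0("M", random_filler(NLR_LAYOUT$leader - 1L),
         MOTIF_AA[["P-loop"]], noisy_barcode(bc$s1, noise),
         MOTIF_AA[["Kinase2"]], noisy_barcode(bc$s2, noise),
         MOTIF_AA[["GLPL"]], noisy_barcode(bc$s3, noise),
         MOTIF_AA[["MHDV"]], random_filler(NLR_LAYOUT$tail))
}

# protein-coordinate interval (0-based aa) of the second barcode spacer,
# i.e. between Kinase2 and GLPL: where targeted stop codons are planted so
# truncation removes >= 2 motifs
S2_AA_RANGE <- local({
  off <- NLR_LAYOUT$leader + nchar(MOTIF_AA[["P-loop"]]) + NLR_LAYOUT$s1 +
    nchar(MOTIF_AA[["Kinase2"]])
  c(off + 5L, off + NLR_LAYOUT$s2 - 5L)
})

backtranslate <- function(protein, add_stop = TRUE) {
  aa <- strsplit(protein, "")[[1L]]
  codons <- vapply(aa, function(a) {
    cs <- CODONS_OF[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""), if (add_stop) "TAA" else "")
}

#' Simulate the reference accession
#'
#' Builds chromosomes with clustered, intronless NLR genes.  Every simulated
#' protein contains the four NB-ARC motifs in canonical order over a >= 160
#' aa span, so the whole reference panel is classified intact by
#' [select_candidates()] by construction.
#'
#' @param cfg a [panel_config()].
#' @param seed integer seed (determinism contract: same `(cfg, seed)` gives
#'   byte-identical output).
#' @param cluster_sizes optional integer vector overriding the per-cluster
#'   gene count (length `n_clusters`).
#' @return object of class `nlr_reference`: list with `genome`, `genes`
#'   (gene table with truth columns `subgroup` and `cluster_id`),
#'   `clusters` (truth intervals), `barcodes`, `cfg`, `seed`.
#' @export
simulate_reference <- function(cfg, seed = 1L, cluster_sizes = NULL) {
  stopifnot(inherits(cfg, "nlr_panel_config"))
  set.seed(seed)
  barcodes <- make_subgroup_barcodes(cfg$subgroup_labels)
  n_chr <- cfg$n_chromosomes
  chrom_of_cluster <- ((seq_len(cfg$n_clusters) - 1L) %% n_chr) + 1L
  if (is.null(cluster_sizes)) {
    cluster_sizes <- sample_range(cfg$genes_per_cluster[1L], cfg$genes_per_cluster[2L],
                                  cfg$n_clusters)
  }
  stopifnot(length(cluster_sizes) == cfg$n_clusters)

  seqs <- character(n_chr)
  names(seqs) <- sprintf("chr%02d", seq_len(n_chr))
  gene_rows <- list()
  cluster_rows <- list()
  gene_counter <- 0L
  n_lab <- length(cfg$subgroup_labels)

  for (ci in seq_len(n_chr)) {
    segs <- character(0)
    cursor <- 0L
    lead <- sample(10000:30000, 1L)
    segs <- c(segs, random_dna(lead)); cursor <- cursor + lead
    for (cl in which(chrom_of_cluster == ci)) {
      cl_start <- cursor
      for (gi in seq_len(cluster_sizes[cl])) {
        if (gi > 1L) {
          gap <- sample_range(cfg$intra_cluster_gap[1L], cfg$intra_cluster_gap[2L])
          segs <- c(segs, random_dna(gap)); cursor <- cursor + gap
        }
        gene_counter <- gene_counter + 1L
        subgroup <- if (gene_counter <= n_lab) {
          cfg$subgroup_labels[gene_counter]
        } else {
          sample(cfg$subgroup_labels, 1L)
        }
        protein <- simulate_nlr_protein(subgroup, barcodes, cfg$barcode_noise)
        strand <- sample(c("+", "-"), 1L)
        cds <- backtranslate(protein)
        dna <- if (strand == "-") revcomp(cds) else cds
        glen <- nchar(dna)
        gene_rows[[gene_counter]] <- data.frame(
          gene_id = sprintf("NLR%04d", gene_counter),
          accession = cfg$accession_ids[1L],
          seq_id = names(seqs)[ci],
          start = cursor, end = cursor + glen,
          strand = strand, phase = 0L,
          protein = protein, premature_stop = FALSE,
          subgroup = subgroup, cluster_id = sprintf("CL%03d", cl),
          lineage_id = sprintf("NLR%04d", gene_counter),
          stringsAsFactors = FALSE
        )
        segs <- c(segs, dna); cursor <- cursor + glen
      }
      cluster_rows[[cl]] <- data.frame(
        cluster_id = sprintf("CL%03d", cl), seq_id = names(seqs)[ci],
        start = cl_start, end = cursor, n_genes = cluster_sizes[cl],
        stringsAsFactors = FALSE
      )
      gap <- sample_range(cfg$inter_cluster_gap[1L], cfg$inter_cluster_gap[2L])
      segs <- c(segs, random_dna(gap)); cursor <- cursor + gap
    }
    if (cursor > cfg$chromosome_length) {
      stop("chromosome_length ", cfg$chromosome_length, " too short for the ",
           "requested clusters (need >= ", cursor, " bp)")
    }
    segs <- c(segs, random_dna(cfg$chromosome_length - cursor))
    seqs[ci] <- paste(segs, collapse = "")
  }
  genes <- do.call(rbind, gene_rows)
  genes$exons <- lapply(seq_len(nrow(genes)), function(i)
    cbind(start = genes$start[i], end = genes$end[i]))
  genes <- genes[order(genes$seq_id, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome = genome(cfg$accession_ids[1L], seqs),
                 genes = genes,
                 clusters = do.call(rbind, cluster_rows),
                 barcodes = barcodes, cfg = cfg, seed = seed),
            class = "nlr_reference")
}

# ---- edit machinery -------------------------------------------------------

# edits: data.frame(pos, ref_len, alt) on reference coordinates; an edit
# replaces ref [pos, pos+ref_len) with alt (ref_len 0 inserts before pos)
apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0L) return(list(seq = seq, out_pos = integer(0)))
  edits <- edits[order(edits$pos, edits$ref_len), , drop = FALSE]
  n <- nchar(seq)
  pieces <- character(2L * nrow(edits) + 1L)
  out_pos <- numeric(nrow(edits))
  cursor <- 0L; shift <- 0L
  for (i in seq_len(nrow(edits))) {
    e_pos <- edits$pos[i]
    pieces[2L * i - 1L] <- substr(seq, cursor + 1L, e_pos)
    out_pos[i] <- e_pos + shift
    pieces[2L * i] <- edits$alt[i]
    shift <- shift + nchar(edits$alt[i]) - edits$ref_len[i]
    cursor <- e_pos + edits$ref_len[i]
  }
  pieces[2L * nrow(edits) + 1L] <- substr(seq, cursor + 1L, n)
  list(seq = paste(pieces, collapse = ""), out_pos = out_pos,
       edits = edits)
}

# map reference positions to derived positions through a sorted edit set
make_liftover <- function(edits) {
  if (nrow(edits) == 0L) return(function(p) p)
  edits <- edits[order(edits$pos, edits$ref_len), , drop = FALSE]
  delta <- nchar(edits$alt) - edits$ref_len
  cum <- cumsum(delta)
  ref_end <- edits$pos + edits$ref_len
  function(p) {
    # shift from all edits whose ref span ends at or before p
    idx <- findInterval(p, ref_end)
    shift <- c(0, cum)[idx + 1L]
    # positions inside a deleted span collapse to the deletion point
    inside <- findInterval(p, edits$pos)
    collapse <- inside > idx & inside > 0L
    out <- p + shift
    if (any(collapse)) {
      j <- inside[collapse]
      out[collapse] <- edits$pos[j] + ifelse(j > 1L, cum[j - 1L], 0)
    }
    out
  }
}

# drop edits overlapping an earlier-accepted edit (input order = priority)
drop_conflicts <- function(edits) {
  if (nrow(edits) <= 1L) return(edits)
  keep <- rep(TRUE, nrow(edits))
  taken_start <- numeric(0); taken_end <- numeric(0)
  for (i in seq_len(nrow(edits))) {
    s <- edits$pos[i]; e <- edits$pos[i] + max(edits$ref_len[i], 1L)
    if (any(s < taken_end & e > taken_start)) {
      keep[i] <- FALSE
    } else {
      taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
    }
  }
  edits[keep, , drop = FALSE]
}

new_truth <- function() {
  data.frame(accession = character(0), gene_id = character(0),
             event_type = character(0), seq_id = character(0),
             ref_pos = numeric(0), detail = character(0),
             stringsAsFactors = FALSE)
}

truth_row <- function(accession, gene_id, event_type, seq_id, ref_pos,
                      detail = "") {
  data.frame(accession = accession, gene_id = gene_id,
             event_type = event_type, seq_id = seq_id, ref_pos = ref_pos,
             detail = detail, stringsAsFactors = FALSE)
}

#' Derive an accession from the reference by planted mutation
#'
#' Gene-targeted events are drawn first (at most one of deletion,
#' duplication, large insertion, premature stop per gene, in that precedence
#' order), then genome-wide SNVs and small InDels.  Background events never
#' overlap a gene-targeted edit or a gene boundary, so annotation liftover
#' through the planted variation is exact.  Every event is logged as a truth
#' record.
#'
#' @param reference an `nlr_reference` from [simulate_reference()].
#' @param mcfg a [mutation_config()].
#' @param accession_id identifier for the derived accession.
#' @param seed integer seed.
#' @param forced_deletions reference gene ids deleted unconditionally (used
#'   for planting copy-number effects).
#' @return object of class `nlr_accession`: list with `genome`, `genes`
#'   (lifted annotation, re-translated proteins), `truth` (event table).
#' @export
derive_accession <- function(reference, mcfg, accession_id, seed,
                             forced_deletions = character(0)) {
  stopifnot(inherits(reference, "nlr_reference"),
            inherits(mcfg, "nlr_mutation_config"))
  set.seed(seed)
  ref_genes <- reference$genes
  truth <- new_truth()
  seqs_out <- reference$genome$seqs
  genes_out <- list()

  for (chr in names(reference$genome$seqs)) {
    seq <- reference$genome$seqs[[chr]]
    chr_len <- nchar(seq)
    g <- ref_genes[ref_genes$seq_id == chr, , drop = FALSE]
    edits <- data.frame(pos = numeric(0), ref_len = numeric(0),
                        alt = character(0), stringsAsFactors = FALSE)
    deleted <- character(0)
    dup_edit_of <- character(0)   # gene_id by edit row (for duplications)

    # --- gene-targeted events (priority order) ---
    for (i in seq_len(nrow(g))) {
      gid <- g$gene_id[i]; gs <- g$start[i]; ge <- g$end[i]
      ev <- if (gid %in% forced_deletions) {
        "gene_deletion"
      } else {
        draws <- runif(4L)
        types <- c("gene_deletion", "gene_duplication", "large_insertion",
                   "premature_stop")
        probs <- c(mcfg$gene_deletion_prob, mcfg$gene_duplication_prob,
                   mcfg$large_insertion_prob, mcfg$premature_stop_prob)
        hit <- which(draws < probs)
        if (length(hit)) types[hit[1L]] else NA_character_
      }
      if (is.na(ev)) next
      if (ev == "gene_deletion") {
        edits <- rbind(edits, data.frame(pos = gs, ref_len = ge - gs,
                                         alt = "", stringsAsFactors = FALSE))
        dup_edit_of <- c(dup_edit_of, NA_character_)
        deleted <- c(deleted, gid)
        truth <- rbind(truth, truth_row(accession_id, gid, "gene_deletion",
                                        chr, gs, sprintf("len=%d", ge - gs)))
      } else if (ev == "gene_duplication") {
        ins_at <- ge + sample(500:1500, 1L)
        if (ins_at >= chr_len) next
        alt <- substr(seq, gs + 1L, ge)   # reference allele copy
        edits <- rbind(edits, data.frame(pos = ins_at, ref_len = 0,
                                         alt = alt, stringsAsFactors = FALSE))
        dup_edit_of <- c(dup_edit_of, gid)
        truth <- rbind(truth, truth_row(accession_id, gid, "gene_duplication",
                                        chr, ins_at,
                                        sprintf("len=%d", ge - gs)))
      } else if (ev == "large_insertion") {
        len <- sample_range(mcfg$large_insertion_length[1L],
                            mcfg$large_insertion_length[2L])
        n_codons <- (ge - gs) %/% 3L
        at <- gs + 3L * (n_codons %/% 2L)
        edits <- rbind(edits, data.frame(pos = at, ref_len = 0,
                                         alt = random_dna(len),
                                         stringsAsFactors = FALSE))
        dup_edit_of <- c(dup_edit_of, NA_character_)
        truth <- rbind(truth, truth_row(accession_id, gid, "large_insertion",
                                        chr, at, sprintf("len=%d", len)))
      } else if (ev == "premature_stop") {
        cdx <- sample_range(S2_AA_RANGE[1L], S2_AA_RANGE[2L])
        if (g$strand[i] == "+") {
          at <- gs + 3L * cdx
          alt <- "TAA"
        } else {
          at <- ge - 3L * (cdx + 1L)
          alt <- "TTA"   # revcomp(TAA) on the genome strand
        }
        edits <- rbind(edits, data.frame(pos = at, ref_len = 3,
                                         alt = alt, stringsAsFactors = FALSE))
        dup_edit_of <- c(dup_edit_of, NA_character_)
        truth <- rbind(truth, truth_row(accession_id, gid, "premature_stop",
                                        chr, at, sprintf("codon=%d", cdx)))
      }
    }

    # --- background SNVs ---
    n_snv <- rbinom(1L, chr_len, mcfg$snv_rate)
    if (n_snv > 0L) {
      pos <- sort(sample.int(chr_len, n_snv)) - 1L
      ref_base <- substring(seq, pos + 1L, pos + 1L)
      alt_base <- vapply(ref_base, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      snv_edits <- data.frame(pos = pos, ref_len = 1, alt = alt_base,
                              stringsAsFactors = FALSE)
    } else {
      snv_edits <- edits[0L, ]
    }

    # --- background small InDels (never across a gene boundary) ---
    n_ind <- rbinom(1L, chr_len, mcfg$small_indel_rate)
    ind_edits <- edits[0L, ]
    if (n_ind > 0L) {
      pos <- sort(sample.int(chr_len, n_ind)) - 1L
      len <- sample(1:10, n_ind, replace = TRUE)
      is_del <- runif(n_ind) < 0.5
      bounds <- sort(c(g$start, g$end))
      for (i in seq_len(n_ind)) {
        if (is_del[i]) {
          if (pos[i] + len[i] > chr_len) next
          span <- c(pos[i], pos[i] + len[i])
          if (any(bounds > span[1L] & bounds < span[2L])) next
          ind_edits <- rbind(ind_edits, data.frame(
            pos = pos[i], ref_len = len[i], alt = "",
            stringsAsFactors = FALSE))
        } else {
          ind_edits <- rbind(ind_edits, data.frame(
            pos = pos[i], ref_len = 0, alt = random_dna(len[i]),
            stringsAsFactors = FALSE))
        }
      }
    }

    n_gene_edits <- nrow(edits)
    all_edits <- rbind(edits, snv_edits, ind_edits)
    all_edits$priority <- seq_len(nrow(all_edits))
    all_edits$is_dup <- c(dup_edit_of,
                          rep(NA_character_, nrow(all_edits) - n_gene_edits))
    kept <- drop_conflicts(all_edits)

    # log surviving background events
    if (nrow(kept) > n_gene_edits || nrow(all_edits) > n_gene_edits) {
      bg <- kept[kept$priority > n_gene_edits, , drop = FALSE]
      if (nrow(bg)) {
        in_gene <- vapply(bg$pos, function(p) {
          j <- which(g$start <= p & p < g$end)
          if (length(j)) g$gene_id[j[1L]] else NA_character_
        }, character(1))
        type <- ifelse(bg$ref_len == 1 & nchar(bg$alt) == 1, "snv",
                       "small_indel")
        detail <- ifelse(type == "snv", paste0("alt=", bg$alt),
                         ifelse(bg$ref_len > 0,
                                paste0("del_len=", bg$ref_len),
                                paste0("ins_len=", nchar(bg$alt))))
        truth <- rbind(truth, data.frame(
          accession = accession_id, gene_id = in_gene, event_type = type,
          seq_id = chr, ref_pos = bg$pos, detail = detail,
          stringsAsFactors = FALSE))
      }
    }

    kept <- kept[order(kept$pos, kept$ref_len), , drop = FALSE]
    applied <- apply_edits(seq, kept[, c("pos", "ref_len", "alt")])
    seqs_out[[chr]] <- applied$seq
    lift <- make_liftover(kept[, c("pos", "ref_len", "alt")])

    # lifted annotation for surviving genes
    keep_g <- g[!(g$gene_id %in% deleted), , drop = FALSE]
    if (nrow(keep_g)) {
      ins_in_gene <- function(gs, ge) {
        ins <- kept$ref_len == 0 & kept$pos > gs & kept$pos < ge
        del <- kept$ref_len > 0 & kept$pos >= gs & kept$pos + kept$ref_len <= ge
        sum(nchar(kept$alt[ins])) +
          sum(nchar(kept$alt[del]) - kept$ref_len[del])
      }
      new_start <- lift(keep_g$start)
      new_end <- new_start + (keep_g$end - keep_g$start) +
        vapply(seq_len(nrow(keep_g)), function(i)
          ins_in_gene(keep_g$start[i], keep_g$end[i]), numeric(1))
      keep_g$start <- new_start
      keep_g$end <- new_end
      keep_g$accession <- accession_id
    }
    # duplicated copies become new annotations
    dup_rows <- which(!is.na(kept$is_dup))
    dup_g <- NULL
    if (length(dup_rows)) {
      ord <- order(kept$pos, kept$ref_len)
      out_pos_of <- setNames(applied$out_pos, rownames(kept)[ord])
      dup_g <- do.call(rbind, lapply(dup_rows, function(r) {
        src <- g[g$gene_id == kept$is_dup[r], , drop = FALSE]
        src$lineage_id <- src$gene_id
        src$gene_id <- paste0(src$gene_id, "_dup")
        src$start <- out_pos_of[[rownames(kept)[r]]]
        src$end <- src$start + nchar(kept$alt[r])
        src$accession <- accession_id
        src
      }))
    }
    chr_genes <- rbind(keep_g, dup_g)
    if (!is.null(chr_genes) && nrow(chr_genes)) {
      genes_out[[chr]] <- chr_genes
    }
  }

  genes <- if (length(genes_out)) do.call(rbind, genes_out) else
    ref_genes[0L, ]
  if (nrow(genes)) {
    genes <- genes[order(genes$seq_id, genes$start), , drop = FALSE]
    genes$exons <- lapply(seq_len(nrow(genes)), function(i)
      cbind(start = genes$start[i], end = genes$end[i]))
    gnm <- genome(accession_id, seqs_out)
    prot <- lapply(seq_len(nrow(genes)), function(i)
      extract_protein(genes[i, ], gnm))
    genes$protein <- vapply(prot, as.character, character(1))
    genes$premature_stop <- vapply(prot, attr, logical(1), "premature_stop")
    rownames(genes) <- NULL
  } else {
    gnm <- genome(accession_id, seqs_out)
  }
  structure(list(genome = gnm, genes = genes, truth = truth),
            class = "nlr_accession")
}

#' Simulate a whole accession panel with optional planted CNV clusters
#'
#' Accession 1 is the reference.  Clusters flagged as planted CNVs receive
#' accession-specific forced gene deletions so that the per-accession gene
#' counts of those clusters follow `planted_counts`; the reference must hold
#' the row maximum (it is never mutated).
#'
#' @param cfg a [panel_config()].
#' @param mcfg a [mutation_config()] applied to every non-reference
#'   accession.
#' @param seed integer master seed; per-accession child seeds are derived
#'   arithmetically.
#' @param planted_counts optional integer matrix (planted clusters x
#'   accessions) of target NLR counts, e.g. `rbind(c(16,15,1,9,12))`.
#' @return object of class `nlr_panel`: list with `cfg`, `reference`,
#'   `accessions` (named list of `nlr_accession`), `truth` (merged),
#'   `planted_cnv` (planted-CNV table or NULL).
#' @export
simulate_panel <- function(cfg, mcfg = mutation_config(), seed = 1L,
                           planted_counts = NULL) {
  stopifnot(inherits(cfg, "nlr_panel_config"), cfg$n_accessions >= 2L)
  cluster_sizes <- NULL
  planted_ids <- integer(0)
  if (!is.null(planted_counts)) {
    planted_counts <- as.matrix(planted_counts)
    if (nrow(planted_counts) > cfg$n_clusters) {
      stop("more planted CNV clusters requested (", nrow(planted_counts),
           ") than clusters (", cfg$n_clusters, ")")
    }
    if (ncol(planted_counts) != cfg$n_accessions) {
      stop("planted_counts needs one column per accession")
    }
    row_max <- apply(planted_counts, 1L, max)
    if (any(planted_counts[, 1L] != row_max)) {
      stop("the reference (column 1) must carry the row maximum of every ",
           "planted cluster; it is never mutated")
    }
    set.seed(child_seed(seed, 777L))
    planted_ids <- sort(sample.int(cfg$n_clusters, nrow(planted_counts)))
    cluster_sizes <- sample_range(cfg$genes_per_cluster[1L], cfg$genes_per_cluster[2L],
                                  cfg$n_clusters)
    cluster_sizes[planted_ids] <- row_max
  }
  reference <- simulate_reference(cfg, seed, cluster_sizes = cluster_sizes)

  accs <- vector("list", cfg$n_accessions)
  names(accs) <- cfg$accession_ids
  accs[[1L]] <- structure(list(genome = reference$genome,
                               genes = reference$genes,
                               truth = new_truth()),
                          class = "nlr_accession")
  for (k in 2:cfg$n_accessions) {
    forced <- character(0)
    if (length(planted_ids)) {
      set.seed(child_seed(seed, 500L + k))
      for (j in seq_along(planted_ids)) {
        cl_id <- sprintf("CL%03d", planted_ids[j])
        members <- reference$genes$gene_id[
          reference$genes$cluster_id == cl_id]
        n_del <- length(members) - planted_counts[j, k]
        if (n_del > 0L) {
          forced <- c(forced, sample(members, n_del))
        }
      }
    }
    accs[[k]] <- derive_accession(reference, mcfg, cfg$accession_ids[k],
                                  child_seed(seed, k),
                                  forced_deletions = forced)
  }
  planted_tbl <- NULL
  if (length(planted_ids)) {
    planted_tbl <- cbind(
      reference$clusters[planted_ids, , drop = FALSE],
      setNames(as.data.frame(planted_counts), cfg$accession_ids)
    )
    rownames(planted_tbl) <- NULL
  }
  truth <- do.call(rbind, lapply(accs, `[[`, "truth"))
  rownames(truth) <- NULL
  structure(list(cfg = cfg, reference = reference, accessions = accs,
                 truth = truth, planted_cnv = planted_tbl, seed = seed),
            class = "nlr_panel")
}

#' @export
print.nlr_panel <- function(x, ...) {
  cat("<nlr_panel>", x$cfg$n_accessions, "accessions,",
      nrow(x$reference$genes), "reference NLR genes in",
      x$cfg$n_clusters, "clusters;", nrow(x$truth), "planted events\n")
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' Per-accession FASTA + GFF3, the merged truth table and (when present) the
#' planted-CNV table, all as plain text.
#'
#' @param panel an `nlr_panel`.
#' @param dir output directory (created if needed).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (acc in names(panel$accessions)) {
    a <- panel$accessions[[acc]]
    write_fasta(a$genome$seqs, file.path(dir, paste0(acc, ".fasta")))
    write_gff3(a$genes, file.path(dir, paste0(acc, ".gff3")))
  }
  write_table(panel$truth, file.path(dir, "truth_events.tsv"))
  if (!is.null(panel$planted_cnv)) {
    write_table(panel$planted_cnv, file.path(dir, "planted_cnv.tsv"))
  }
  invisible(dir)
}

#' Simulate cluster count matrices for statistical calibration
#'
#' A counts-level stand-in for full genome panels, used to calibrate the CNV
#' test: under the null every accession retains each cluster member with the
#' same probability, so per-cluster counts differ only by chance.  Planted
#' rows are appended verbatim.
#'
#' @param n_clusters number of null clusters.
#' @param n_accessions accessions.
#' @param size_range range of true cluster sizes.
#' @param retention_prob shared per-member retention probability.
#' @param planted_counts optional matrix of planted rows.
#' @param seed integer seed.
#' @return list with `counts` (matrix, rows = clusters) and `planted`
#'   (logical row flags).
#' @export
simulate_cluster_counts <- function(n_clusters, n_accessions = 5L,
                                    size_range = c(4L, 16L),
                                    retention_prob = 0.9,
                                    planted_counts = NULL, seed = 1L) {
  set.seed(seed)
  sizes <- sample_range(size_range[1L], size_range[2L], n_clusters)
  counts <- t(vapply(sizes, function(s)
    rbinom(n_accessions, s, retention_prob), numeric(n_accessions)))
  planted <- rep(FALSE, n_clusters)
  if (!is.null(planted_counts)) {
    planted_counts <- as.matrix(planted_counts)
    counts <- rbind(counts, planted_counts)
    planted <- c(planted, rep(TRUE, nrow(planted_counts)))
  }
  rownames(counts) <- sprintf("CL%03d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("ACC%02d", seq_len(n_accessions))
  list(counts = counts, planted = planted)
}
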