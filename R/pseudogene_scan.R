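# Mechanistic dissection of CNVs: frameshift-aware protein-to-DNA alignment
# and event calling (premature stops, frameshift InDels, large insertions).

FS_ALPHA <- c(AMINO_ACIDS, "X")

fs_submat <- function() {
  if (is.null(.pkg_cache$fs_submat)) {
    S <- blosum62()
    .pkg_cache$fs_submat <- S[FS_ALPHA, FS_ALPHA]
  }
  .pkg_cache$fs_submat
}

fs_codon_aa <- function() {
  if (is.null(.pkg_cache$fs_codon_aa)) {
    bases <- c("A", "C", "G", "T")
    idx <- expand.grid(b3 = bases, b2 = bases, b1 = bases)[, 3:1]
    codons <- paste0(idx$b1, idx$b2, idx$b3)
    aa <- Biostrings::GENETIC_CODE[codons]
    .pkg_cache$fs_codon_aa <- ifelse(aa == "*", -1L,
                                     match(aa, FS_ALPHA) - 1L)
  }
  .pkg_cache$fs_codon_aa
}

#' Scoring parameters for the frameshift-aware aligner
#'
#' Codon substitutions are scored with BLOSUM62 on the translated codon;
#' whole-codon gaps are affine per codon; a frameshift costs a flat penalty
#' per +-1/+-2 shift; stop codons are read through at a penalty so stops
#' downstream of the first are still observed; `long_gap_open` opens a long
#' DNA gap with free extension (models multi-kb insertions; set to `-Inf`
#' to disable).
#'
#' @param gap_open,gap_ext per-codon affine gap penalties.
#' @param frameshift frameshift penalty.
#' @param stop stop-codon read-through penalty.
#' @param long_gap_open long-gap opening penalty.
#' @return parameter list.
#' @export
fs_align_params <- function(gap_open = -11, gap_ext = -1, frameshift = -30,
                            stop = -20, long_gap_open = -40) {
  list(gap_open = gap_open, gap_ext = gap_ext, frameshift = frameshift,
       stop = stop, long_gap_open = long_gap_open)
}

#' Align a protein to a genomic DNA region, frameshift-aware
#'
#' Dynamic programming in codon space: codon match/substitution, whole-codon
#' gaps, +-1/+-2 frameshift codons, stop-codon read-through and (optionally)
#' long free-extension DNA gaps.  Glocal: the DNA flanks are free, the whole
#' protein is consumed.  Deterministic tie-break prefers codon alignment
#' over gaps over frameshifts, then leftmost.
#'
#' @param protein amino-acid string (>= 10 aa).
#' @param dna DNA string (>= 1.5 x protein length in nt).
#' @param params scoring parameters from [fs_align_params()].
#' @param ends_free when `TRUE` (default) the DNA flanks are free, as
#'   appropriate for a padded genomic region; `FALSE` forces the whole DNA
#'   to be consumed (exact-region alignment).
#' @return object of class `fs_alignment`: `score`, `ops` (data.frame with
#'   `op` in codon_match / codon_substitution / stop_codon / frameshift /
#'   protein_gap / dna_gap_3n / dna_gap_long, `shift`, `aa_idx` (1-based),
#'   `dna_start`, `dna_end` 0-based half-open within `dna`), `dna_aln`
#'   (c(start,end) of the aligned DNA span).
#' @export
frameshift_align <- function(protein, dna, params = fs_align_params(),
                             ends_free = TRUE) {
  stopifnot(nchar(protein) >= 4L)
  if (nchar(dna) < 1.5 * nchar(protein)) stop("region too short")
  aa <- strsplit(toupper(protein), "")[[1L]]
  aa[!(aa %in% FS_ALPHA)] <- "X"
  prot_idx <- match(aa, FS_ALPHA) - 1L
  dna_idx <- match(strsplit(toupper(dna), "")[[1L]],
                   c("A", "C", "G", "T")) - 1L
  dna_idx[is.na(dna_idx)] <- 4L
  res <- frameshift_align_cpp(prot_idx, dna_idx, fs_submat(), fs_codon_aa(),
                              params$gap_open, params$gap_ext,
                              params$frameshift, params$stop,
                              params$long_gap_open, ends_free)
  ops <- data.frame(op = res$op, shift = res$shift, aa_idx = res$aa_idx,
                    dna_start = res$dna_start, dna_end = res$dna_end)
  # name ops; split codon ops into match/substitution/stop
  nm <- character(nrow(ops))
  for (i in seq_len(nrow(ops))) {
    nm[i] <- switch(ops$op[i],
      `1` = {
        codon <- substr(dna, ops$dna_start[i] + 1L, ops$dna_end[i])
        tr <- Biostrings::GENETIC_CODE[[toupper(codon)]] %||% "X"
        if (identical(tr, "*")) "stop_codon"
        else if (identical(tr, aa[ops$aa_idx[i]])) "codon_match"
        else "codon_substitution"
      },
      `2` = "frameshift",
      `3` = "protein_gap",
      `4` = "dna_gap_3n",
      `5` = "dna_gap_long")
  }
  ops$op <- nm
  structure(list(score = res$score, ops = ops,
                 dna_aln = c(res$dna_aln_start, res$dna_aln_end),
                 protein_length = nchar(protein), dna_length = nchar(dna)),
            class = "fs_alignment")
}

#' @export
print.fs_alignment <- function(x, ...) {
  tab <- table(x$ops$op)
  cat("<fs_alignment> score", round(x$score, 1), "| dna span [",
      x$dna_aln[1L], ",", x$dna_aln[2L], ") |",
      paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

# conservation invariant: the op path reproduces the protein length and
# tiles the aligned DNA span
fs_alignment_consistent <- function(aln) {
  ops <- aln$ops
  aa_consumed <- sum(ops$op %in% c("codon_match", "codon_substitution",
                                   "stop_codon", "frameshift",
                                   "protein_gap"))
  dna_consumed <- sum(ops$dna_end - ops$dna_start)
  aa_consumed == aln$protein_length &&
    dna_consumed == (aln$dna_aln[2L] - aln$dna_aln[1L])
}

#' Call pseudogenization events from a frameshift alignment
#'
#' Stop-codon read-throughs become premature stops, frameshift operations
#' frameshift insertions/deletions, and DNA gap runs of at least
#' `large_insertion_min` bp large insertions.  Events are sorted by position
#' within the aligned DNA.
#'
#' @param aln an `fs_alignment`.
#' @param large_insertion_min minimum DNA gap run length (bp) called as a
#'   large insertion.
#' @return data.frame: `type`, `dna_pos` (0-based within the aligned
#'   region), `codon_index` (1-based protein position, NA for insertions),
#'   `length`.
#' @export
detect_events <- function(aln, large_insertion_min = 1000L) {
  ops <- aln$ops
  rows <- list()
  add <- function(type, dna_pos, dna_end, codon_index, length) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, dna_pos = dna_pos, dna_end = dna_end,
      codon_index = codon_index, length = length, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] == "stop_codon") {
      add("premature_stop", ops$dna_start[i], ops$dna_end[i],
          ops$aa_idx[i], 3L)
    } else if (ops$op[i] == "frameshift") {
      # the op localizes the InDel to its span (one codon plus the shift);
      # finer placement is not defined when junction bases coincide
      type <- if (ops$shift[i] > 0L) "frameshift_insertion" else
        "frameshift_deletion"
      add(type, ops$dna_start[i], ops$dna_end[i], ops$aa_idx[i],
          abs(ops$shift[i]))
    }
  }
  # dna gap runs (codon gaps and long gaps merge if adjacent)
  is_gap <- ops$op %in% c("dna_gap_3n", "dna_gap_long")
  if (any(is_gap)) {
    run_id <- cumsum(!is_gap)[is_gap]
    for (r in unique(run_id)) {
      seg <- ops[is_gap, , drop = FALSE][run_id == r, , drop = FALSE]
      len <- sum(seg$dna_end - seg$dna_start)
      if (len >= large_insertion_min) {
        add("large_insertion", min(seg$dna_start), max(seg$dna_end),
            NA_integer_, len)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), dna_pos = numeric(0),
               dna_end = numeric(0), codon_index = integer(0),
               length = numeric(0))
  out[order(out$dna_pos), , drop = FALSE]
}

invert_chain <- function(blocks) {
  inv <- blocks
  inv$ref_start <- blocks$qry_start; inv$ref_end <- blocks$qry_end
  inv$qry_start <- blocks$ref_start; inv$qry_end <- blocks$ref_end
  inv
}

#' Compare a reference gene with its syntenic region in another accession
#'
#' Projects the reference gene interval into the query accession through the
#' (inverted) anchor chain, pads it, aligns the reference protein to the
#' region on both strands and keeps the better strand.  Verdicts:
#' `conserved` (protein aligns, no events), `pseudogenized` (premature
#' stops, frameshifts or large insertions), `absent` (no anchor, or less
#' than half the protein aligns to codons).
#'
#' @param ref_record one-row NLR record of the reference accession (with
#'   `protein`, `seq_id`, `start`, `end`).
#' @param qry_genome the query accession's [genome()].
#' @param chains that accession's chain list (query seq -> blocks, as built
#'   by [accession_chains()]).
#' @param window_pad bp added on both sides of the projected interval.
#' @param params aligner parameters.
#' @param large_insertion_min event threshold, see [detect_events()].
#' @return list: `verdict`, `reason`, `strand`, `score`,
#'   `aligned_fraction`, `region` (seq, start, end), `events` (with genomic
#'   positions on the query).
#' @export
compare_region <- function(ref_record, qry_genome, chains,
                           window_pad = 10000L,
                           params = fs_align_params(),
                           large_insertion_min = 1000L) {
  no_events <- data.frame(type = character(0), dna_pos = numeric(0),
                          dna_end = numeric(0), codon_index = integer(0),
                          length = numeric(0),
                          genomic_pos = numeric(0))
  absent <- function(reason) {
    list(verdict = "absent", reason = reason, strand = NA_character_,
         score = NA_real_, aligned_fraction = 0, region = NULL,
         events = no_events)
  }
  # locate the chain that targets the gene's reference sequence
  hit <- NULL
  for (qseq in names(chains)) {
    ch <- chains[[qseq]]
    if (nrow(ch) && ch$ref_seq[1L] == ref_record$seq_id) {
      hit <- list(qseq = qseq, blocks = ch)
      break
    }
  }
  if (is.null(hit)) return(absent("no_anchor"))
  pr <- project_interval(invert_chain(hit$blocks),
                         c(ref_record$start, ref_record$end))
  if (pr$status == "unmapped") return(absent("no_anchor"))
  seq <- qry_genome$seqs[[hit$qseq]]
  rs <- max(0, pr$ref_start - window_pad)
  re <- min(nchar(seq), pr$ref_end + window_pad)
  dna <- substr(seq, rs + 1L, re)
  aln_f <- frameshift_align(ref_record$protein, dna, params)
  aln_r <- frameshift_align(ref_record$protein, revcomp(dna), params)
  use_rev <- aln_r$score > aln_f$score
  aln <- if (use_rev) aln_r else aln_f
  # identity-level evidence that the protein is really there: exact codon
  # matches; a deleted gene leaves only near-random matching (~5%)
  aligned <- sum(aln$ops$op == "codon_match") / aln$protein_length
  if (aligned < 0.5) return(absent("low_alignment"))
  events <- detect_events(aln, large_insertion_min)
  # convert region-relative to genomic coordinates on the query
  events$genomic_pos <- if (!use_rev) rs + events$dna_pos else
    re - events$dna_end
  verdict <- if (nrow(events)) "pseudogenized" else "conserved"
  list(verdict = verdict, reason = NA_character_,
       strand = if (use_rev) "-" else "+", score = aln$score,
       aligned_fraction = aligned,
       region = list(seq_id = hit$qseq, start = rs, end = re),
       events = events)
}
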