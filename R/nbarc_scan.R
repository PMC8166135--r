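# NB-ARC motif detection and intact/partial NLR classification.
#
# An NLR candidate is any protein carrying at least one of the four NB-ARC
# motifs.  A candidate is "intact" when at least three of the four motifs are
# present in the canonical architecture order
#     P-loop < Kinase2 < GLPL < MHDV
# (order tested on the motifs present) and the span from the first selected
# hit's start to the last selected hit's end is at least 160 amino acids.
# Everything else with a motif hit is "partial".

MOTIF_ORDER <- c("P-loop", "Kinase2", "GLPL", "MHDV")

#' Default NB-ARC motif patterns
#'
#' Curated regular-expression consensus patterns for the four major NB-ARC
#' motifs.  Each entry may instead be a list with elements `pwm` (a
#' position-weight matrix of log-odds scores, rows named by amino acid) and
#' `cutoff` (minimum window score) to plug in profile models.
#'
#' @return named list of patterns in canonical order.
#' @export
default_motif_patterns <- function() {
  list(
    "P-loop"  = "G....GK[ST]",
    "Kinase2" = "[LIVMF][LIVMF][LIVMF]DD",
    "GLPL"    = "GLPL[AST]",
    "MHDV"    = "MHD[VLIA]"
  )
}

scan_one_pattern <- function(protein, pattern) {
  m <- gregexpr(pattern, protein, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"),
             score = 1)
}

scan_one_pwm <- function(protein, pwm, cutoff) {
  w <- ncol(pwm)
  n <- nchar(protein)
  if (n < w) {
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  }
  aa <- strsplit(protein, "")[[1L]]
  scores <- vapply(seq_len(n - w + 1L), function(s) {
    idx <- cbind(match(aa[s:(s + w - 1L)], rownames(pwm)), seq_len(w))
    if (anyNA(idx[, 1L])) return(-Inf)
    sum(pwm[idx])
  }, numeric(1))
  keep <- which(scores >= cutoff)
  data.frame(start = keep - 1L, end = keep - 1L + w, score = scores[keep])
}

# collapse overlapping hits of one motif to the best-scoring one (tie ->
# leftmost); hits must be sorted by start
collapse_overlaps <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- logical(nrow(hits))
  i <- 1L
  while (i <= nrow(hits)) {
    j <- i
    while (j < nrow(hits) && hits$start[j + 1L] < hits$end[i]) j <- j + 1L
    grp <- i:j
    best <- grp[which.max(hits$score[grp])]  # which.max: leftmost on tie
    keep[best] <- TRUE
    i <- j + 1L
  }
  hits[keep, , drop = FALSE]
}

#' Scan a protein for NB-ARC motifs
#'
#' All matches of each motif are reported sorted by start; overlapping matches
#' of the same motif are collapsed to the best-scoring (tie: leftmost) one.
#'
#' @param protein amino-acid string.
#' @param motif_set named list of regex patterns or `list(pwm=, cutoff=)`
#'   profile entries; defaults to [default_motif_patterns()].
#' @return data.frame with columns `motif`, `start`, `end` (0-based half-open
#'   amino-acid positions), `score`.
#' @export
scan_motifs <- function(protein, motif_set = default_motif_patterns()) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  if (length(motif_set) == 0L) stop("empty motif set")
  out <- lapply(names(motif_set), function(nm) {
    spec <- motif_set[[nm]]
    hits <- if (is.list(spec)) {
      scan_one_pwm(protein, spec$pwm, spec$cutoff)
    } else {
      scan_one_pattern(protein, spec)
    }
    hits <- hits[order(hits$start), , drop = FALSE]
    hits <- collapse_overlaps(hits)
    if (nrow(hits)) cbind(motif = nm, hits) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), score = numeric(0))
  }
  out[order(out$start, out$motif), , drop = FALSE]
}

#' Classify an NLR candidate as intact or partial
#'
#' One best hit per motif type is selected (highest score, ties to the
#' leftmost).  The candidate is intact iff at least `min_motifs` distinct
#' motif types are present, their starts strictly increase in the canonical
#' order restricted to the motifs present, and the span from the first
#' selected hit start to the last selected hit end is at least `min_span`
#' amino acids.
#'
#' @param hits data.frame from [scan_motifs()].
#' @param protein_length protein length in aa (used for validation only).
#' @param min_span minimum NB-ARC span (aa).
#' @param min_motifs minimum number of distinct motifs.
#' @return list with `status` ("intact"/"partial") and `nbarc_span`
#'   (`c(start, end)` 0-based half-open, or `NULL` when partial).
#' @export
classify_intact <- function(hits, protein_length, min_span = 160L,
                            min_motifs = 3L) {
  if (nrow(hits) == 0L) return(list(status = "partial", nbarc_span = NULL))
  stopifnot(all(hits$end <= protein_length), all(hits$start >= 0L))
  sel <- do.call(rbind, lapply(MOTIF_ORDER, function(m) {
    h <- hits[hits$motif == m, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    h <- h[order(-h$score, h$start), , drop = FALSE]
    h[1L, , drop = FALSE]
  }))
  if (is.null(sel) || nrow(sel) < min_motifs) {
    return(list(status = "partial", nbarc_span = NULL))
  }
  in_order <- all(diff(sel$start) > 0)  # sel rows are in canonical order
  span <- c(min(sel$start), max(sel$end))
  if (in_order && (span[2L] - span[1L]) >= min_span) {
    list(status = "intact", nbarc_span = span)
  } else {
    list(status = "partial", nbarc_span = NULL)
  }
}

#' Select NLR candidates from a proteome
#'
#' Every gene whose protein has at least one NB-ARC motif hit becomes an NLR
#' record; its status is set by [classify_intact()].
#'
#' @param genes gene table with columns `gene_id`, `accession`, `seq_id`,
#'   `start`, `end`, `strand`, `protein` (e.g. from [read_gff3()] or the
#'   simulator).
#' @param motif_set motif patterns, see [scan_motifs()].
#' @param min_span,min_motifs classification thresholds.
#' @return data.frame of NLR records: gene fields plus `n_motifs`, `motifs`
#'   (comma-joined names found), `status`, `span_start`, `span_end`,
#'   `subgroup` (NA, filled in by group assignment).
#' @export
select_candidates <- function(genes, motif_set = default_motif_patterns(),
                              min_span = 160L, min_motifs = 3L) {
  stopifnot(nrow(genes) > 0L)
  recs <- lapply(seq_len(nrow(genes)), function(i) {
    p <- genes$protein[i]
    if (is.na(p) || !nzchar(p)) return(NULL)
    hits <- scan_motifs(p, motif_set)
    if (nrow(hits) == 0L) return(NULL)
    cl <- classify_intact(hits, nchar(p), min_span, min_motifs)
    data.frame(
      gene_id = genes$gene_id[i], accession = genes$accession[i],
      seq_id = genes$seq_id[i], start = genes$start[i], end = genes$end[i],
      strand = genes$strand[i], protein = p,
      n_motifs = length(unique(hits$motif)),
      motifs = paste(intersect(MOTIF_ORDER, unique(hits$motif)),
                     collapse = ","),
      status = cl$status,
      span_start = if (is.null(cl$nbarc_span)) NA_integer_ else cl$nbarc_span[1L],
      span_end = if (is.null(cl$nbarc_span)) NA_integer_ else cl$nbarc_span[2L],
      subgroup = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), accession = character(0),
                      seq_id = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      protein = character(0), n_motifs = integer(0),
                      motifs = character(0), status = character(0),
                      span_start = integer(0), span_end = integer(0),
                      subgroup = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Extract the NB-ARC domain sequence of an intact record
#'
#' @param record one-row NLR record from [select_candidates()].
#' @return amino-acid substring at the record's NB-ARC span.
#' @export
extract_nbarc <- function(record) {
  if (!identical(record$status, "intact")) {
    stop("extract_nbarc() requires an intact record (gene ",
         record$gene_id, " is ", record$status, ")")
  }
  substr(record$protein, record$span_start + 1L, record$span_end)
}
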