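# NLR map: project every accession's NLRs onto the reference coordinate
# system through chains of unique exact-match anchors (1-to-1 alignment
# semantics).  All coordinates are 0-based half-open bp.

# positions (0-based) whose k-mer occurs exactly once in the sequence,
# together with the k-mer strings
unique_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list(pos = integer(0), kmer = character(0)))
  km <- substring(seq, 1:(n - k + 1L), k:n)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  list(pos = which(!dup) - 1L, kmer = km[!dup])
}

merge_diagonal_runs <- function(rpos, qpos, k) {
  if (length(rpos) == 0L) {
    return(data.frame(ref_start = numeric(0), ref_end = numeric(0),
                      qry_start = numeric(0), qry_end = numeric(0)))
  }
  d <- rpos - qpos
  o <- order(d, qpos)
  rpos <- rpos[o]; qpos <- qpos[o]; d <- d[o]
  new_run <- c(TRUE, diff(qpos) != 1L | diff(d) != 0L)
  run_id <- cumsum(new_run)
  first <- !duplicated(run_id)
  last <- !duplicated(run_id, fromLast = TRUE)
  data.frame(ref_start = rpos[first], ref_end = rpos[last] + k,
             qry_start = qpos[first], qry_end = qpos[last] + k)
}

#' Find unique exact matches between two sequences
#'
#' Maximal runs of k-mers (k = `min_length`) that occur exactly once in each
#' sequence, merged along diagonals; both strands are searched.  This is the
#' anchor-seeding stand-in for a maximal-unique-match aligner.
#'
#' @param ref,qry DNA strings.
#' @param min_length minimum anchor length (>= 12; guards against spurious
#'   matches).
#' @return data.frame of anchors: `ref_start`, `ref_end`, `qry_start`,
#'   `qry_end` (0-based half-open), `strand`, `length`.
#' @export
find_mums <- function(ref, qry, min_length = 21L) {
  stopifnot(nchar(ref) > 0L, nchar(qry) > 0L)
  if (min_length < 12L) {
    stop("min_length below 12 invites spurious matches; refusing")
  }
  k <- as.integer(min_length)
  ur <- unique_kmers(ref, k)
  out <- list()
  for (strand in c("+", "-")) {
    q_seq <- if (strand == "+") qry else revcomp(qry)
    uq <- unique_kmers(q_seq, k)
    hit <- match(uq$kmer, ur$kmer)
    ok <- !is.na(hit)
    blocks <- merge_diagonal_runs(ur$pos[hit[ok]], uq$pos[ok], k)
    if (strand == "-" && nrow(blocks)) {
      qlen <- nchar(qry)
      qs <- qlen - blocks$qry_end
      qe <- qlen - blocks$qry_start
      blocks$qry_start <- qs; blocks$qry_end <- qe
    }
    if (nrow(blocks)) {
      blocks$strand <- strand
      out[[strand]] <- blocks
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(ref_start = numeric(0), ref_end = numeric(0),
                      qry_start = numeric(0), qry_end = numeric(0),
                      strand = character(0))
  }
  res$length <- res$ref_end - res$ref_start
  rownames(res) <- NULL
  res[order(res$ref_start), , drop = FALSE]
}

# best-weight collinear chain (LIS-style DP, weight = matched bp) among
# blocks of one strand; anchors may extend a few bp across a variant
# junction, so small overlaps (up to `slack`) are allowed and trimmed
# afterwards rather than forcing a whole block out of the chain
chain_one_strand <- function(b, minus = FALSE, slack = 30L) {
  n <- nrow(b)
  if (n == 0L) return(b)
  b <- b[order(b$ref_start, b$qry_start), , drop = FALSE]
  w <- b$length
  best <- w
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    # collinear predecessor: ref before; qry before (+) / after (-)
    ok_q <- if (minus) b$qry_start >= b$qry_end[i] - slack else
      b$qry_end <= b$qry_start[i] + slack
    cand <- which(b$ref_end <= b$ref_start[i] + slack & ok_q &
                    b$ref_start < b$ref_start[i])
    if (length(cand)) {
      j <- cand[which.max(best[cand])]
      if (best[j] + w[i] > best[i]) {
        best[i] <- best[j] + w[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  keep <- integer(0)
  while (i > 0L) { keep <- c(i, keep); i <- prev[i] }
  out <- b[keep, , drop = FALSE]
  # trim residual overlaps off the later block
  if (nrow(out) > 1L) {
    for (i in 2L:nrow(out)) {
      o_ref <- out$ref_end[i - 1L] - out$ref_start[i]
      o_qry <- if (minus) out$qry_end[i] - out$qry_start[i - 1L] else
        out$qry_end[i - 1L] - out$qry_start[i]
      o <- max(o_ref, o_qry, 0L)
      if (o > 0L) {
        out$ref_start[i] <- out$ref_start[i] + o
        if (minus) out$qry_end[i] <- out$qry_end[i] - o else
          out$qry_start[i] <- out$qry_start[i] + o
      }
    }
    out$length <- out$ref_end - out$ref_start
    out <- out[out$length > 0L, , drop = FALSE]
  }
  out
}

#' Chain anchors into a 1-to-1 collinear block set
#'
#' Keeps, per strand, the collinear chain of maximum total matched bp
#' (crossing or overlapping leftovers are discarded), then returns the
#' heavier strand's chain — the "1-to-1 alignment" filtering contract.
#'
#' @param matches anchor data.frame from [find_mums()].
#' @return chained blocks (same columns), strictly increasing on both
#'   genomes (mirrored for "-").
#' @export
chain_blocks <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  chains <- lapply(c("+", "-"), function(s) {
    chain_one_strand(matches[matches$strand == s, , drop = FALSE],
                     minus = (s == "-"))
  })
  weights <- vapply(chains, function(x) sum(x$length), numeric(1))
  chains[[which.max(weights)]]
}

#' Project a query interval onto the reference through a chain
#'
#' The interval midpoint decides the mode: inside a block, the exact-match
#' offset is applied; between two chain blocks at most `max_bridge` apart the
#' interval is bridged proportionally between the block edges (a zero-length
#' reference gap marks an accession-specific insertion); otherwise the
#' interval is unmapped.
#'
#' @param blocks chained blocks from [chain_blocks()] for one (ref seq, qry
#'   seq) pair.
#' @param qry_interval numeric `c(start, end)`, 0-based half-open.
#' @param max_bridge maximum query-side bridge span (default 100 kb).
#' @return list with `status` ("mapped", "bridged", "inserted" or
#'   "unmapped"), `ref_start`, `ref_end`.
#' @export
project_interval <- function(blocks, qry_interval, max_bridge = 1e5) {
  unmapped <- list(status = "unmapped", ref_start = NA_real_,
                   ref_end = NA_real_)
  if (nrow(blocks) == 0L) return(unmapped)
  qs <- qry_interval[1L]; qe <- qry_interval[2L]
  mid <- (qs + qe) / 2
  minus <- blocks$strand[1L] == "-"
  inb <- which(blocks$qry_start <= mid & mid < blocks$qry_end)
  if (length(inb)) {
    b <- blocks[inb[1L], ]
    if (!minus) {
      off <- b$ref_start - b$qry_start
      return(list(status = "mapped", ref_start = qs + off,
                  ref_end = qe + off))
    }
    rs <- b$ref_start + (b$qry_end - qe)
    return(list(status = "mapped", ref_start = rs,
                ref_end = rs + (qe - qs)))
  }
  ord <- order(blocks$qry_start)
  bq <- blocks[ord, , drop = FALSE]
  prev <- which(bq$qry_end <= mid)
  nxt <- which(bq$qry_start > mid)
  if (!length(prev) || !length(nxt)) return(unmapped)
  p <- bq[max(prev), ]; nx <- bq[min(nxt), ]
  span <- nx$qry_start - p$qry_end
  if (span > max_bridge) return(unmapped)
  if (!minus) {
    lo <- p$ref_end; hi <- nx$ref_start
  } else {
    lo <- nx$ref_end; hi <- p$ref_start
  }
  ref_gap <- hi - lo
  if (ref_gap <= 0L) {
    return(list(status = "inserted", ref_start = lo, ref_end = lo))
  }
  frac <- (mid - p$qry_end) / span
  if (minus) frac <- 1 - frac
  centre <- lo + frac * ref_gap
  half <- min(qe - qs, ref_gap) / 2
  list(status = "bridged", ref_start = max(lo, floor(centre - half)),
       ref_end = min(hi, ceiling(centre + half)))
}

#' Anchor chains of one accession against the reference genome
#'
#' Sequence pairing is by name when ref and query share sequence names,
#' otherwise every query sequence is chained against every reference
#' sequence and the heaviest chain wins.
#'
#' @param ref_genome,qry_genome [genome()] objects.
#' @param min_length anchor length for [find_mums()].
#' @return named list: query seq id -> chained block data.frame (with
#'   `ref_seq` column).
#' @export
accession_chains <- function(ref_genome, qry_genome, min_length = 21L) {
  chains <- list()
  shared <- intersect(names(ref_genome$seqs), names(qry_genome$seqs))
  by_name <- length(shared) > 0L
  for (qseq in names(qry_genome$seqs)) {
    targets <- if (by_name) {
      if (qseq %in% shared) qseq else character(0)
    } else {
      names(ref_genome$seqs)
    }
    best <- NULL; best_w <- -1
    for (rseq in targets) {
      m <- find_mums(ref_genome$seqs[[rseq]], qry_genome$seqs[[qseq]],
                     min_length)
      ch <- chain_blocks(m)
      w <- sum(ch$length)
      if (w > best_w) {
        best_w <- w
        if (nrow(ch)) ch$ref_seq <- rseq
        best <- ch
      }
    }
    if (!is.null(best) && nrow(best)) chains[[qseq]] <- best
  }
  chains
}

#' Build the NLR map of a panel
#'
#' Projects every accession's NLR records onto the reference accession's
#' coordinates.  Reference NLRs map to themselves; genes on query sequences
#' without a usable chain are reported unmapped.
#'
#' @param panel an `nlr_panel` (or any named list of `nlr_accession`-like
#'   objects with `$genome`).
#' @param records NLR record table pooled over accessions (from
#'   [select_candidates()] per accession, row-bound).
#' @param reference accession id of the reference; must be in the panel.
#' @param min_length anchor length for [find_mums()].
#' @param max_bridge see [project_interval()].
#' @param chains optional precomputed chain lists (accession ->
#'   [accession_chains()] result) to avoid recomputation.
#' @return `records` with added columns `ref_seq`, `ref_start`, `ref_end`,
#'   `map_status`; attribute `unmapped` holds the unmapped subset.
#' @export
build_map <- function(panel, records, reference, min_length = 21L,
                      max_bridge = 1e5, chains = NULL) {
  accs <- panel$accessions %||% panel
  if (!reference %in% names(accs)) {
    stop("reference accession '", reference, "' absent from panel")
  }
  ref_genome <- accs[[reference]]$genome
  records$ref_seq <- NA_character_
  records$ref_start <- NA_real_
  records$ref_end <- NA_real_
  records$map_status <- "unmapped"

  is_ref <- records$accession == reference
  records$ref_seq[is_ref] <- records$seq_id[is_ref]
  records$ref_start[is_ref] <- records$start[is_ref]
  records$ref_end[is_ref] <- records$end[is_ref]
  records$map_status[is_ref] <- "mapped"

  for (acc in setdiff(unique(records$accession), reference)) {
    acc_ch <- chains[[acc]] %||%
      accession_chains(ref_genome, accs[[acc]]$genome, min_length)
    rows <- which(records$accession == acc)
    for (i in rows) {
      ch <- acc_ch[[records$seq_id[i]]]
      if (is.null(ch)) next
      pr <- project_interval(ch, c(records$start[i], records$end[i]),
                             max_bridge)
      if (pr$status == "unmapped") next
      records$ref_seq[i] <- ch$ref_seq[1L]
      records$ref_start[i] <- pr$ref_start
      records$ref_end[i] <- pr$ref_end
      records$map_status[i] <- pr$status
    }
  }
  structure(records, unmapped = records[records$map_status == "unmapped", ,
                                        drop = FALSE])
}

#' Export / import anchor chains as minimal PAF
#'
#' Lets a production whole-genome aligner substitute the in-house anchoring:
#' the minimal PAF columns (query name, length, start, end, strand, target
#' name, length, start, end) round-trip through these helpers.
#'
#' @param chains named list (query seq -> block data.frame) as produced by
#'   internals of [build_map()].
#' @param qry_lens,ref_lens named vectors of sequence lengths.
#' @param path output file.
#' @export
write_paf <- function(chains, qry_lens, ref_lens, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (qseq in names(chains)) {
    b <- chains[[qseq]]
    for (i in seq_len(nrow(b))) {
      writeLines(paste(qseq, qry_lens[[qseq]], b$qry_start[i], b$qry_end[i],
                       b$strand[i], b$ref_seq[i], ref_lens[[b$ref_seq[i]]],
                       b$ref_start[i], b$ref_end[i], b$length[i],
                       b$length[i], 60, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_paf
#' @export
read_paf <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  blocks <- data.frame(ref_start = raw$V8, ref_end = raw$V9,
                       qry_start = raw$V3, qry_end = raw$V4,
                       strand = raw$V5, length = raw$V10,
                       ref_seq = raw$V6, qry_seq = raw$V1,
                       stringsAsFactors = FALSE)
  split(blocks, blocks$qry_seq)
}
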