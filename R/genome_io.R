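# Genome and annotation I/O.
#
# Conventions used throughout the package:
#   * all internal coordinates are 0-based, half-open [start, end) base pairs;
#   * GFF3 (1-based, inclusive) and BED (0-based, half-open) conversions happen
#     only at the I/O boundary;
#   * a "genome" is a list(accession, seqs) where seqs is a named character
#     vector of chromosome/scaffold sequences over {A,C,G,T,N};
#   * a gene table is a data.frame with one row per gene model (one
#     representative mRNA per gene) and a list-column `exons` holding a
#     2-column matrix (start, end) of CDS sub-intervals in genomic order.

#' Construct a genome object
#'
#' @param accession accession identifier.
#' @param seqs named character vector of uppercase DNA sequences.
#' @return a list with class `nlr_genome`.
#' @export
genome <- function(accession, seqs) {
  stopifnot(is.character(accession), length(accession) == 1L,
            is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate seq_id within accession '", accession, "'")
  }
  structure(list(accession = accession, seqs = toupper(seqs)),
            class = "nlr_genome")
}

#' @export
print.nlr_genome <- function(x, ...) {
  cat("<nlr_genome> accession:", x$accession, "-", length(x$seqs),
      "sequence(s),", sum(nchar(x$seqs)), "bp total\n")
  invisible(x)
}

#' Read a FASTA file
#'
#' Sequences are uppercased, multi-line records concatenated, and record order
#' preserved.  Malformed headers and empty records are reported with their
#' line numbers.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @param alphabet `"dna"` rejects characters outside {A,C,G,T,N};
#'   `"protein"` and `"any"` accept letters and `*`/`-`.
#' @return named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("FASTA parse error at line ", line_no[1L],
         ": expected a '>' header")
  }
  hdr_idx <- which(is_hdr)
  bad_hdr <- hdr_idx[nchar(lines[hdr_idx]) < 2L]
  if (length(bad_hdr)) {
    stop("FASTA parse error at line ", line_no[bad_hdr[1L]],
         ": empty header")
  }
  rec_of <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", lines[hdr_idx])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, character(1), 1L)
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    body <- lines[!is_hdr & rec_of == i]
    paste(body, collapse = "")
  }, character(1))
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop("FASTA parse error at line ", line_no[hdr_idx[empty[1L]]],
         ": record '", ids[empty[1L]], "' has no sequence")
  }
  seqs <- toupper(seqs)
  if (alphabet == "dna") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("record '", ids[which(bad)[1L]],
           "' contains characters outside {A,C,G,T,N}; ",
           "ambiguity codes other than N are not supported")
    }
  }
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Extract and translate the protein of a gene model
#'
#' Exon sub-intervals are spliced in genomic order, reverse-complemented for
#' minus-strand genes, the GFF3 phase of the first coding exon is honoured,
#' and the standard genetic code applied.  Translation stops at the first stop
#' codon (never included in the protein); an internal stop before the final
#' codon flags the model.
#'
#' @param model one-row gene data.frame (or list) with fields `seq_id`,
#'   `strand`, `phase` and list-column/element `exons`.
#' @param genome an [genome()] object holding `seq_id`.
#' @return protein string with attribute `premature_stop`.
#' @export
extract_protein <- function(model, genome) {
  exons <- model$exons
  if (is.list(exons) && !is.matrix(exons)) exons <- exons[[1L]]
  seq <- genome$seqs[[model$seq_id]]
  if (is.null(seq)) stop("unknown seq_id: ", model$seq_id)
  if (any(exons[, 2L] > nchar(seq)) || any(exons[, 1L] < 0L)) {
    stop("exons out of sequence bounds for gene ", model$gene_id %||% "?")
  }
  pieces <- substring(seq, exons[, 1L] + 1L, exons[, 2L])
  cds <- paste(pieces, collapse = "")
  if (identical(model$strand, "-")) cds <- revcomp(cds)
  phase <- model$phase %||% 0L
  if (is.na(phase)) phase <- 0L
  if (phase > 0L) cds <- substr(cds, phase + 1L, nchar(cds))
  translate_cds(cds)
}

#' Read gene models from a GFF3 file
#'
#' Accepts gene/mRNA/CDS (and exon) features; keeps the mRNA with the longest
#' total CDS per gene (ties broken by mRNA identifier) and converts the GFF3
#' 1-based inclusive coordinates to the package's 0-based half-open
#' convention.  Proteins are translated from the genome.
#'
#' @param path GFF3 file.
#' @param genome an [genome()] object supplying the sequences.
#' @return gene table data.frame (see file header) with columns `gene_id`,
#'   `accession`, `seq_id`, `start`, `end`, `strand`, `phase`, `exons`
#'   (list-column), `protein`, `premature_stop`, `len3_ok`.
#' @export
read_gff3 <- function(path, genome) {
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand", "phase"),
    tags = c("ID", "Parent")
  ))
  gff$Parent <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))
  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) stop("no CDS features in ", path)
  unknown <- setdiff(unique(as.character(cds$seqid)), names(genome$seqs))
  if (length(unknown)) {
    stop("CDS references unknown seq_id: ", paste(unknown, collapse = ", "))
  }
  cds_len <- tapply(cds$end - cds$start + 1L, cds$Parent, sum)
  # representative mRNA per gene: longest CDS, tie -> smallest mRNA ID
  mrna$cds_len <- as.integer(cds_len[mrna$ID])
  mrna <- mrna[!is.na(mrna$cds_len), , drop = FALSE]
  mrna <- mrna[order(mrna$Parent, -mrna$cds_len, mrna$ID), , drop = FALSE]
  rep_mrna <- mrna[!duplicated(mrna$Parent), , drop = FALSE]

  rows <- lapply(seq_len(nrow(rep_mrna)), function(i) {
    m <- rep_mrna[i, ]
    cc <- cds[cds$Parent == m$ID, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    exons <- cbind(start = cc$start - 1L, end = cc$end)
    # phase of the first coding exon in translation order
    ph <- if (m$strand == "-") cc$phase[nrow(cc)] else cc$phase[1L]
    ph <- suppressWarnings(as.integer(ph))
    if (is.na(ph)) ph <- 0L
    list(gene_id = m$Parent %||% m$ID, seq_id = as.character(m$seqid),
         start = min(exons[, 1L]), end = max(exons[, 2L]),
         strand = as.character(m$strand), phase = ph, exons = exons)
  })
  out <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    accession = genome$accession,
    seq_id = vapply(rows, `[[`, character(1), "seq_id"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    phase = vapply(rows, `[[`, integer(1), "phase"),
    stringsAsFactors = FALSE
  )
  out$exons <- lapply(rows, `[[`, "exons")
  prot <- lapply(seq_len(nrow(out)), function(i)
    extract_protein(out[i, ], genome))
  out$protein <- vapply(prot, as.character, character(1))
  out$premature_stop <- vapply(prot, attr, logical(1), "premature_stop")
  cds_tot <- vapply(out$exons, function(e) sum(e[, 2L] - e[, 1L]), numeric(1))
  out$len3_ok <- (cds_tot - out$phase) %% 3L == 0L
  if (any(!out$len3_ok)) {
    warning(sum(!out$len3_ok), " gene(s) with CDS length not divisible by 3 ",
            "after phase correction (flagged in column 'len3_ok')")
  }
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Write gene models to GFF3
#'
#' @param genes gene table as returned by [read_gff3()].
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1L]]
    lines <- c(
      paste(g$seq_id, "nlrpan", "gene", g$start + 1L, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$seq_id, "nlrpan", "mRNA", g$start + 1L, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id),
            sep = "\t"),
      paste(g$seq_id, "nlrpan", "CDS", ex[, 1L] + 1L, ex[, 2L], ".",
            g$strand, g$phase,
            paste0("ID=", g$gene_id, ".cds;Parent=", g$gene_id, ".t1"),
            sep = "\t")
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a catalog as a tab-separated table
#'
#' Header row, deterministic column order (as given), UTF-8, numeric `NA`
#' written as an empty field.  List columns are dropped with a message.
#'
#' @param records data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  is_list <- vapply(records, is.list, logical(1))
  if (any(is_list)) {
    message("dropping list column(s): ",
            paste(names(records)[is_list], collapse = ", "))
    records <- records[, !is_list, drop = FALSE]
  }
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated catalog written by [write_table()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table <- function(path) {
  read.delim(path, sep = "\t", na.strings = "", stringsAsFactors = FALSE,
             check.names = FALSE)
}
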