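# Copy-number-variation statistics on physical clusters plus per-window
# subgroup enrichment.
#
# Clusters whose per-accession counts have a sample standard deviation above
# `sd_min` are tested by a chi-square goodness-of-fit against equal copy
# number across accessions; p-values over the tested clusters are
# Benjamini-Hochberg adjusted and clusters with q < alpha are flagged.

#' Standard-deviation filter for a count row
#'
#' @param row integer vector of per-accession counts (>= 2).
#' @param sd_min retain iff sample SD (n-1 denominator) strictly exceeds
#'   this (default 2).
#' @return logical retain flag.
#' @export
sd_filter <- function(row, sd_min = 2.0) {
  stopifnot(length(row) >= 2L)
  sd(row) > sd_min
}

#' Chi-square goodness-of-fit against uniform copy number
#'
#' Expected count is the row mean; `chi2 = sum((o - e)^2 / e)` with
#' `df = n - 1` and an upper-tail p-value.  A warning attribute marks rows
#' with any expected count below 5 (the asymptotic approximation is then
#' shaky, as for any small-count chi-square use).
#'
#' @param row integer vector of per-accession counts with positive total.
#' @return list `chi2`, `df`, `p`, `expected_ok`.
#' @export
chisq_uniform <- function(row) {
  total <- sum(row)
  if (total <= 0) stop("chi-square test needs a positive total count")
  e <- mean(row)
  chi2 <- sum((row - e)^2 / e)
  df <- length(row) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       expected_ok = e >= 5)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvals numeric vector in `[0,1]`.
#' @return q-values (step-up FDR adjustment).
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Detect physical clusters with significant copy-number variation
#'
#' Applies the SD filter, chi-square tests the retained rows, adjusts across
#' the tested rows with Benjamini-Hochberg, and flags clusters with
#' `q < alpha`.
#'
#' @param counts cluster x accession count matrix from
#'   [cluster_count_matrix()] (or any integer matrix with cluster rownames).
#' @param alpha FDR level (default 0.05).
#' @param sd_min SD filter threshold (default 2).
#' @return data.frame per cluster: counts, `sd`, `tested`, `chi2`, `df`,
#'   `p`, `q`, `significant`; untested rows carry NA statistics.
#' @export
detect_cnv_regions <- function(counts, alpha = 0.05, sd_min = 2.0) {
  stopifnot(alpha > 0, alpha < 1)
  n <- nrow(counts)
  res <- data.frame(cluster_id = rownames(counts) %||%
                      sprintf("CL%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  res <- cbind(res, as.data.frame(counts))
  res$sd <- apply(counts, 1L, sd)
  res$tested <- res$sd > sd_min & rowSums(counts) > 0
  res$chi2 <- NA_real_; res$df <- NA_integer_; res$p <- NA_real_
  for (i in which(res$tested)) {
    t <- chisq_uniform(counts[i, ])
    res$chi2[i] <- t$chi2; res$df[i] <- t$df; res$p[i] <- t$p
  }
  res$q <- NA_real_
  if (any(res$tested)) res$q[res$tested] <- bh_adjust(res$p[res$tested])
  res$significant <- !is.na(res$q) & res$q < alpha
  res
}

#' Subgroup enrichment in non-overlapping genomic windows
#'
#' Tiles each reference sequence with non-overlapping windows and tests, per
#' (window, subgroup) with at least one member in the window, whether the
#' window holds more subgroup members than expected from the genome-wide
#' background: hypergeometric upper tail for drawing `k` of the window's `n`
#' NLRs from a genome with `K` subgroup members among `N`, BH-adjusted over
#' all emitted tests.  A binomial tail is available as an alternative.
#'
#' @param mapped NLR map table with `ref_seq`, `ref_start`, `ref_end` and a
#'   `subgroup` column (unmapped rows and NA subgroups are ignored).
#' @param seq_lengths named vector of reference sequence lengths.
#' @param window window size in bp (default 1 Mb).
#' @param alpha FDR level.
#' @param distribution "hypergeometric" (exact, default) or "binomial".
#' @return data.frame: `ref_seq`, `win_start`, `win_end`, `subgroup`, `k`,
#'   `n`, `K`, `N`, `p`, `q`, `enriched`.
#' @export
window_subgroup_enrichment <- function(mapped, seq_lengths,
                                       window = 1e6, alpha = 0.05,
                                       distribution = c("hypergeometric",
                                                        "binomial")) {
  distribution <- match.arg(distribution)
  ok <- mapped$map_status != "unmapped" & !is.na(mapped$subgroup)
  mm <- mapped[ok, , drop = FALSE]
  if (nrow(mm) == 0L) {
    return(data.frame(ref_seq = character(0), win_start = numeric(0),
                      win_end = numeric(0), subgroup = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      enriched = logical(0)))
  }
  N <- nrow(mm)
  K_of <- table(mm$subgroup)
  mid <- (mm$ref_start + mm$ref_end) / 2
  win_idx <- floor(mid / window)
  rows <- list()
  for (rs in unique(mm$ref_seq)) {
    sel <- mm$ref_seq == rs
    for (w in sort(unique(win_idx[sel]))) {
      inw <- sel & win_idx == w
      n_w <- sum(inw)
      for (sg in sort(unique(mm$subgroup[inw]))) {
        k <- sum(inw & mm$subgroup == sg)
        K <- as.integer(K_of[[sg]])
        p <- if (distribution == "hypergeometric") {
          phyper(k - 1L, K, N - K, n_w, lower.tail = FALSE)
        } else {
          stats::pbinom(k - 1L, n_w, K / N, lower.tail = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          ref_seq = rs, win_start = w * window,
          win_end = min((w + 1) * window, seq_lengths[[rs]]),
          subgroup = sg, k = k, n = n_w, K = K, N = N, p = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < alpha
  rownames(out) <- NULL
  out
}

#' Write significant CNV clusters as BED
#'
#' @param cnv result of [detect_cnv_regions()].
#' @param clusters cluster table from [merge_physical_clusters()].
#' @param path output BED path (0-based half-open, as BED requires).
#' @export
write_cnv_bed <- function(cnv, clusters, path) {
  sig <- cnv$cluster_id[cnv$significant]
  cl <- clusters[clusters$cluster_id %in% sig, , drop = FALSE]
  bed <- data.frame(cl$ref_seq, format(cl$start, scientific = FALSE,
                                       trim = TRUE),
                    format(cl$end, scientific = FALSE, trim = TRUE),
                    cl$cluster_id)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
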