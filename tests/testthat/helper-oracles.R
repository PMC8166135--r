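# Independent oracles used to cross-check implementations.

# brute-force O(n^2) interval union with gap padding: two intervals belong
# to one cluster iff a chain of pairwise gaps < max_gap connects them
oracle_merge_intervals <- function(starts, ends, max_gap) {
  n <- length(starts)
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (grp[i] != grp[j] &&
            starts[j] - ends[i] < max_gap && starts[i] - ends[j] < max_gap) {
          grp[grp == grp[j]] <- grp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    c(start = min(starts[grp == g]), end = max(ends[grp == g]))
  }))
  out[order(out[, 1L]), , drop = FALSE]
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# textbook chi-square goodness of fit against the row mean
oracle_chisq <- function(row) {
  e <- sum(row) / length(row)
  chi2 <- sum((row - e)^2 / e)
  c(chi2 = chi2,
    p = stats::pchisq(chi2, length(row) - 1L, lower.tail = FALSE))
}

# reference global pairwise alignment score (Biostrings); penalties chosen
# so a gap of length L costs open + L * ext in both conventions
oracle_nw_score <- function(a, b, open = 10, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = e$BLOSUM62, gapOpening = open, gapExtension = ext,
    scoreOnly = TRUE))
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "E", "F", "G", "H", "I", "L", "N", "Q",
                 "R", "S", "T", "V", "W", "Y", "K", "D", "M", "P"),
               n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
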