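# Subgroup assignment: progressive multiple alignment of NB-ARC domains,
# gap-column trimming, identity distances, neighbor-joining, column-resampling
# bootstrap, and the clade / similarity-vote assignment rules.
#
# An MSA is represented as a named character vector of equal-length aligned
# strings with '-' as the gap character.

.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$blosum62 <- e$BLOSUM62
  }
  .pkg_cache$blosum62
}

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa), ""))
  rownames(m) <- names(msa)
  m
}

# amino-acid frequency profile (rows = substitution alphabet, gaps excluded)
seq_profile <- function(aligned, alphabet) {
  m <- msa_matrix(aligned)
  m[!(m %in% alphabet)] <- "X"   # unknowns score as X; '-' handled below
  gap <- do.call(rbind, strsplit(unname(aligned), "")) == "-"
  prof <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(factor(m[!gap[, j], j], levels = alphabet))
    as.numeric(tab) / nrow(m)
  }, numeric(length(alphabet)))
  rownames(prof) <- alphabet
  prof
}

merge_msas <- function(msa_a, msa_b, gap_open, gap_ext, S) {
  alphabet <- rownames(S)
  pa <- seq_profile(msa_a, alphabet)
  pb <- seq_profile(msa_b, alphabet)
  C <- t(pa) %*% S %*% pb
  path <- align_profiles_cpp(C, gap_open, gap_ext)$ops
  a_cols <- path != 3L   # columns where A contributes
  b_cols <- path != 2L
  expand <- function(s, keep) {
    out <- rep("-", length(keep))
    out[keep] <- strsplit(s, "")[[1L]]
    paste(out, collapse = "")
  }
  c(vapply(msa_a, expand, character(1), keep = a_cols),
    vapply(msa_b, expand, character(1), keep = b_cols))
}

#' Progressive multiple alignment
#'
#' Deterministic in-house progressive aligner: a 3-mer-composition guide tree
#' (average-linkage) orders profile-profile merges, each merge being a global
#' affine-gap alignment of amino-acid frequency profiles scored with
#' BLOSUM62.  An externally computed MSA (e.g. from a production aligner) can
#' be used anywhere the package expects one: any named character vector of
#' equal-length gapped strings qualifies.
#'
#' @param seqs named character vector of amino-acid sequences (>= 1).
#' @param gap_open,gap_ext affine gap penalties (negative).
#' @return named character vector of aligned rows; de-gapping any row
#'   returns its input sequence.
#' @export
progressive_align <- function(seqs, gap_open = -10, gap_ext = -1) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  S <- blosum62()
  S <- S[setdiff(rownames(S), c("*", "-")), setdiff(colnames(S), c("*", "-"))]
  if (length(seqs) == 2L) {
    return(merge_msas(seqs[1L], seqs[2L], gap_open, gap_ext, S))
  }
  # guide tree from 3-mer composition
  kmers <- sort(unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s); if (n < 3L) return(character(0))
    unique(substring(s, 1:(n - 2L), 3:n))
  }))))
  counts <- t(vapply(seqs, function(s) {
    n <- nchar(s)
    km <- if (n >= 3L) substring(s, 1:(n - 2L), 3:n) else character(0)
    tabulate(match(km, kmers), nbins = length(kmers))
  }, numeric(length(kmers))))
  hc <- hclust(stats::dist(counts), method = "average")
  nodes <- vector("list", nrow(hc$merge))
  for (r in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) seqs[-x] else nodes[[x]]
    nodes[[r]] <- merge_msas(pick(hc$merge[r, 1L]), pick(hc$merge[r, 2L]),
                             gap_open, gap_ext, S)
  }
  out <- nodes[[length(nodes)]]
  out[names(seqs)]
}

#' Remove high-gap alignment columns
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` are removed (strict
#' `>`, so a column at exactly the threshold is retained); row order is
#' preserved.
#'
#' @param msa named character vector of aligned rows.
#' @param max_gap_fraction gap-fraction cutoff (default 0.92).
#' @return trimmed MSA.
#' @export
trim_columns <- function(msa, max_gap_fraction = 0.92) {
  m <- msa_matrix(msa)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) stop("alignment fully trimmed")
  setNames(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""),
           names(msa))
}

#' Pairwise identity distances from an MSA
#'
#' `d(i,j) = 1 - identical/comparable` over columns where neither row is
#' gapped; pairs with no comparable columns get distance 1 with a warning.
#'
#' @param msa named character vector of aligned rows.
#' @return symmetric numeric matrix with zero diagonal, values in `[0,1]`.
#' @export
identity_distance <- function(msa) {
  m <- msa_matrix(msa)
  codes <- matrix(match(m, c("-", LETTERS)), nrow = nrow(m))
  res <- identity_dist_cpp(codes, 1L)
  d <- res$d
  dimnames(d) <- list(names(msa), names(msa))
  if (length(msa) > 1L && any(res$comparable[upper.tri(res$comparable)] == 0L)) {
    warning("sequence pair(s) with no comparable columns; distance set to 1")
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei neighbor joining on an identity-distance matrix.
#'
#' @param dm symmetric distance matrix with ids as dimnames (>= 3 ids).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 ids")
  ape::nj(as.dist(dm))
}

#' Column-resampling bootstrap supports for the NJ tree
#'
#' Resamples alignment columns with replacement, recomputes identity
#' distances and the NJ tree per replicate, and labels each internal edge of
#' the point-estimate tree with the percentage of replicates containing its
#' bipartition.
#'
#' @param msa named character vector of aligned rows (>= 4).
#' @param n_reps bootstrap replicates; 0 returns the tree without supports.
#' @param seed integer seed.
#' @return `phylo` tree; `node.label` holds supports in `[0,100]` (`NA` on
#'   the root).
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L) {
  stopifnot(length(msa) >= 4L)
  base <- nj_tree(identity_distance(msa))
  if (n_reps == 0L) return(base)
  m <- msa_matrix(msa)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    mm <- m[, cols, drop = FALSE]
    rs <- setNames(apply(mm, 1L, paste, collapse = ""), names(msa))
    reps[[r]] <- nj_tree(identity_distance(rs))
  }
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  base$node.label <- round(100 * counts / n_reps, 1)
  base
}

#' Assign subgroups to intact NLRs from supported clades
#'
#' Each unlabelled leaf receives the group of the smallest clade (either side
#' of an internal edge with bootstrap support >= `support_min`) that contains
#' it and whose labelled reference members are all of one group; leaves with
#' no such clade stay unassigned.
#'
#' @param tree `phylo` with `node.label` supports (e.g. from
#'   [bootstrap_support()] or an imported Newick tree with supports as
#'   internal node labels).
#' @param reference_labels named character vector: leaf id -> group.
#' @param support_min minimum support (default 90).
#' @return named character vector: query leaf id -> group or `NA`.
#' @export
assign_intact_groups <- function(tree, reference_labels, support_min = 90) {
  tips <- tree$tip.label
  refs <- reference_labels[names(reference_labels) %in% tips]
  queries <- setdiff(tips, names(refs))
  if (length(queries) == 0L) return(setNames(character(0), character(0)))
  support <- suppressWarnings(as.numeric(tree$node.label))
  pp <- ape::prop.part(tree)
  # candidate clades: both sides of every sufficiently supported bipartition
  cands <- list()
  for (k in seq_along(pp)) {
    s <- support[k]
    if (is.na(s) || s < support_min) next
    side <- tips[pp[[k]]]
    cands[[length(cands) + 1L]] <- side
    cands[[length(cands) + 1L]] <- setdiff(tips, side)
  }
  out <- setNames(rep(NA_character_, length(queries)), queries)
  if (length(cands)) {
    sizes <- lengths(cands)
    ord <- order(sizes)
    for (q in queries) {
      for (k in ord) {
        cl <- cands[[k]]
        if (!(q %in% cl)) next
        grps <- unique(refs[names(refs) %in% cl])
        if (length(grps) == 1L) { out[q] <- grps; break }
      }
    }
  }
  if (all(is.na(out)) && length(refs)) {
    warning("no query could be assigned: reference labels conflict within ",
            "(or are absent from) every supported clade")
  }
  out
}

# positives fraction over all alignment columns + per-sequence coverage of a
# pairwise alignment given as two gapped strings
alignment_stats <- function(a_aln, b_aln) {
  S <- blosum62()
  a <- strsplit(a_aln, "")[[1L]]
  b <- strsplit(b_aln, "")[[1L]]
  both <- a != "-" & b != "-"
  pos <- sum(S[cbind(a[both], b[both])] > 0)
  list(similarity = pos / length(a),
       cov_a = sum(both) / sum(a != "-"),
       cov_b = sum(both) / sum(b != "-"))
}

#' Assign subgroups to partial NLRs by similarity vote
#'
#' Each partial protein is locally aligned (Smith-Waterman, BLOSUM62) against
#' every intact NB-ARC reference; an alignment is a "match" when its
#' similarity (fraction of alignment columns with a positive substitution
#' score) is >= `sim_min` and it covers >= `cov_min` of the reference NB-ARC.
#' The group with the most matches wins; ties go to the group of the single
#' highest-similarity match, then to the lexicographically smallest group.
#'
#' @param partials data.frame with columns `gene_id`, `protein`.
#' @param intact_refs data.frame with columns `nbarc`, `group`.
#' @param sim_min,cov_min match thresholds.
#' @return named character vector: gene_id -> group or `NA`.
#' @export
assign_partial_groups <- function(partials, intact_refs, sim_min = 0.5,
                                  cov_min = 0.3) {
  stopifnot(nrow(intact_refs) > 0L, !is.null(intact_refs$group))
  S <- blosum62()
  out <- setNames(rep(NA_character_, nrow(partials)), partials$gene_id)
  if (nrow(partials) == 0L) return(out)
  pats <- Biostrings::AAStringSet(partials$protein)
  for (g in seq_len(nrow(partials))) {
    sims <- numeric(0); grps <- character(0)
    for (r in seq_len(nrow(intact_refs))) {
      aln <- Biostrings::pairwiseAlignment(
        pats[g], Biostrings::AAString(intact_refs$nbarc[r]),
        type = "local", substitutionMatrix = S,
        gapOpening = 10, gapExtension = 1)
      st <- alignment_stats(
        as.character(Biostrings::alignedPattern(aln)),
        as.character(Biostrings::alignedSubject(aln)))
      cov_ref <- (Biostrings::end(Biostrings::subject(aln)) -
                    Biostrings::start(Biostrings::subject(aln)) + 1L) /
        nchar(intact_refs$nbarc[r])
      if (st$similarity >= sim_min && cov_ref >= cov_min) {
        sims <- c(sims, st$similarity)
        grps <- c(grps, intact_refs$group[r])
      }
    }
    if (!length(sims)) next
    votes <- table(grps)
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1L) {
      out[g] <- top
    } else {
      cand <- grps %in% top
      best <- which(cand & sims == max(sims[cand]))
      tied <- sort(unique(grps[best]))
      out[g] <- tied[1L]
    }
  }
  out
}

#' Globally align two proteins
#'
#' Needleman-Wunsch-Gotoh with BLOSUM62; returns the aligned strings plus the
#' similarity/coverage statistics used for reciprocal-best-hit orthology.
#'
#' @param a,b amino-acid strings.
#' @param gap_open,gap_ext affine gap penalties.
#' @return list with `a_aln`, `b_aln`, `score`, `similarity`, `cov_a`,
#'   `cov_b`.
#' @export
align_protein_pair <- function(a, b, gap_open = -10, gap_ext = -1) {
  S <- blosum62()
  S <- S[setdiff(rownames(S), c("*", "-")), setdiff(colnames(S), c("*", "-"))]
  aa <- strsplit(a, "")[[1L]]; bb <- strsplit(b, "")[[1L]]
  aa[!(aa %in% rownames(S))] <- "X"; bb[!(bb %in% rownames(S))] <- "X"
  C <- S[aa, bb, drop = FALSE]
  res <- align_profiles_cpp(C, gap_open, gap_ext)
  path <- res$ops
  a_aln <- rep("-", length(path)); b_aln <- rep("-", length(path))
  a_aln[path != 3L] <- strsplit(a, "")[[1L]]
  b_aln[path != 2L] <- strsplit(b, "")[[1L]]
  a_aln <- paste(a_aln, collapse = ""); b_aln <- paste(b_aln, collapse = "")
  st <- alignment_stats(a_aln, b_aln)
  c(list(a_aln = a_aln, b_aln = b_aln, score = res$score), st)
}

#' Read/write trees with supports as internal node labels
#'
#' Thin Newick wrappers so externally computed trees (e.g. maximum-likelihood
#' trees with ultrafast-bootstrap supports) can replace the in-house NJ
#' stage.
#'
#' @param path Newick file.
#' @return `phylo` tree.
#' @export
read_support_tree <- function(path) ape::read.tree(path)

#' @rdname read_support_tree
#' @param tree `phylo` tree.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
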