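# Physical clusters, ortholog groups and the core/dispensable/specific
# catalog.
#
# A physical cluster is a maximal run of mapped NLRs on the reference in
# which consecutive genes are separated by strictly less than `max_gap` bp
# (bedtools-merge distance semantics; a gap of exactly 50,000 bp separates
# clusters).  Orthology is inferred within clusters only (synteny-
# constrained) by reciprocal best hits, with components split until no group
# holds more than one member per accession.

#' Merge mapped NLRs into physical clusters
#'
#' @param mapped NLR map table from [build_map()] (rows with `map_status`
#'   "unmapped" are ignored).
#' @param max_gap clustering gap in bp (strict `<`; default 50,000).
#' @return data.frame of clusters: `cluster_id`, `ref_seq`, `start`, `end`,
#'   `n_members`; attribute `membership` maps row indices of `mapped` to
#'   cluster ids (column `cluster_id` is also added to the attribute copy of
#'   the map).
#' @export
merge_physical_clusters <- function(mapped, max_gap = 50000L) {
  ok <- mapped$map_status != "unmapped" & !is.na(mapped$ref_start)
  mm <- mapped[ok, , drop = FALSE]
  mm$cluster_id <- rep(NA_character_, nrow(mm))
  clusters <- list()
  cl_n <- 0L
  for (rs in sort(unique(mm$ref_seq))) {
    rows <- which(mm$ref_seq == rs)
    ir <- IRanges::IRanges(start = mm$ref_start[rows] + 1L,
                           end = pmax(mm$ref_end[rows], mm$ref_start[rows]))
    merged <- IRanges::reduce(ir, min.gapwidth = max_gap)
    hit <- IRanges::findOverlaps(ir, merged, maxgap = 0L,
                                 type = "within", select = "first")
    # width-0 insertion points can miss "within"; fall back to nearest
    miss <- is.na(hit)
    if (any(miss)) {
      hit[miss] <- IRanges::nearest(ir[miss], merged)
    }
    ids <- sprintf("CL%04d", cl_n + seq_len(length(merged)))
    mm$cluster_id[rows] <- ids[hit]
    clusters[[rs]] <- data.frame(
      cluster_id = ids, ref_seq = rs,
      start = IRanges::start(merged) - 1L, end = IRanges::end(merged),
      stringsAsFactors = FALSE)
    cl_n <- cl_n + length(merged)
  }
  out <- do.call(rbind, clusters) %||%
    data.frame(cluster_id = character(0), ref_seq = character(0),
               start = numeric(0), end = numeric(0))
  tab <- table(mm$cluster_id)
  out$n_members <- as.integer(tab[out$cluster_id])
  rownames(out) <- NULL
  structure(out, membership = mm)
}

#' Per-cluster, per-accession NLR count matrix
#'
#' @param clusters result of [merge_physical_clusters()].
#' @param accession_ids all accessions of the panel (columns are zero-filled
#'   for accessions without members).
#' @return integer matrix, rows ordered by reference position.
#' @export
cluster_count_matrix <- function(clusters, accession_ids) {
  mm <- attr(clusters, "membership")
  ord <- clusters$cluster_id[order(clusters$ref_seq, clusters$start)]
  counts <- matrix(0L, nrow = length(ord), ncol = length(accession_ids),
                   dimnames = list(ord, accession_ids))
  if (nrow(mm)) {
    tab <- table(mm$cluster_id, mm$accession)
    counts[rownames(tab), colnames(tab)] <- tab
  }
  counts
}

#' Infer ortholog groups within one physical cluster
#'
#' Global-alignment similarity (positives fraction, BLOSUM62) between
#' members of different accessions defines reciprocal-best-hit edges where
#' similarity >= `sim_min` and coverage >= `cov_min` on both sequences.
#' Connected components are split greedily (weakest edge first) until no
#' component holds more than one member per accession; leftovers are
#' singleton groups.
#'
#' @param members data.frame of cluster members with `gene_id`, `accession`,
#'   `protein`.
#' @param sim_min,cov_min edge thresholds.
#' @return data.frame `gene_id`, `accession`, `group_id` (long format, group
#'   ids local to the cluster).
#' @export
build_ortho_groups <- function(members, sim_min = 0.5, cov_min = 0.3) {
  n <- nrow(members)
  members <- members[order(members$accession, members$gene_id), , drop = FALSE]
  if (n <= 1L) {
    return(data.frame(gene_id = members$gene_id,
                      accession = members$accession,
                      group_id = if (n) "g1" else character(0),
                      stringsAsFactors = FALSE))
  }
  # pairwise cross-accession similarities
  sim <- matrix(NA_real_, n, n)
  ok <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (members$accession[i] == members$accession[j]) next
      al <- align_protein_pair(members$protein[i], members$protein[j])
      sim[i, j] <- sim[j, i] <- al$similarity
      ok[i, j] <- ok[j, i] <- al$similarity >= sim_min &&
        al$cov_a >= cov_min && al$cov_b >= cov_min
    }
  }
  # reciprocal best hits per accession pair
  edges <- NULL
  for (i in seq_len(n)) {
    for (acc in setdiff(unique(members$accession), members$accession[i])) {
      js <- which(members$accession == acc)
      s <- sim[i, js]
      if (all(is.na(s))) next
      best_j <- js[which.max(s)]
      # reciprocal: i is acc_i's best for best_j
      back <- which(members$accession == members$accession[i])
      if (back[which.max(sim[best_j, back])] == i && ok[i, best_j] &&
          i < best_j) {
        edges <- rbind(edges, c(i, best_j, sim[i, best_j]))
      }
    }
  }
  comp_of <- seq_len(n)
  if (!is.null(edges)) {
    g <- igraph::graph_from_edgelist(cbind(edges[, 1L], edges[, 2L]),
                                     directed = FALSE)
    g <- igraph::set_edge_attr(g, "weight", value = edges[, 3L])
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    repeat {
      comp <- igraph::components(g)$membership
      bad <- NULL
      for (cid in unique(comp)) {
        vs <- which(comp == cid)
        if (anyDuplicated(members$accession[vs])) { bad <- cid; break }
      }
      if (is.null(bad)) break
      vs <- which(comp == bad)
      es <- sort(unique(unlist(igraph::incident_edges(g, vs))))
      w <- igraph::E(g)$weight[es]
      g <- igraph::delete_edges(g, es[order(w)][1L])
    }
    comp_of <- igraph::components(g)$membership
  }
  data.frame(gene_id = members$gene_id, accession = members$accession,
             group_id = sprintf("g%d", match(comp_of, unique(comp_of))),
             stringsAsFactors = FALSE)
}

#' Build ortholog groups for every physical cluster
#'
#' @param clusters result of [merge_physical_clusters()] (its membership
#'   attribute supplies proteins).
#' @param sim_min,cov_min see [build_ortho_groups()].
#' @return long data.frame `group_id` (globally unique,
#'   `<cluster_id>.<local>`), `cluster_id`, `gene_id`, `accession`.
#' @export
ortho_catalog <- function(clusters, sim_min = 0.5, cov_min = 0.3) {
  mm <- attr(clusters, "membership")
  out <- lapply(clusters$cluster_id, function(cl) {
    members <- mm[mm$cluster_id == cl, , drop = FALSE]
    grp <- build_ortho_groups(members, sim_min, cov_min)
    grp$group_id <- paste(cl, grp$group_id, sep = ".")
    grp$cluster_id <- cl
    grp
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Categorize ortholog groups as core / dispensable / specific
#'
#' core = members in all accessions; specific = exactly one accession;
#' dispensable = in between.  Percentages are computed against the total NLR
#' candidate count of the panel (mapped or not), rounded half-up to one
#' decimal.
#'
#' @param groups long data.frame with `group_id`, `accession` (and
#'   optionally `gene_id`), e.g. from [ortho_catalog()].
#' @param accession_ids all panel accessions.
#' @param total_candidates total NLR candidate count used as the percentage
#'   denominator; defaults to the number of genes in `groups`.
#' @return list of class `nlr_catalog_summary`: `by_group` (group ->
#'   category), `summary` (per-category group/gene counts and percentages),
#'   `specific_by_accession`, `total_categorized`, `total_candidates`,
#'   `pct_categorized`.
#' @export
categorize <- function(groups, accession_ids,
                       total_candidates = nrow(groups)) {
  n_acc <- length(accession_ids)
  per_group <- tapply(groups$accession, groups$group_id,
                      function(a) length(unique(a)))
  size <- tapply(groups$accession, groups$group_id, length)
  # specific takes precedence so a single-accession panel is all-specific
  category <- ifelse(per_group == 1L, "specific",
                     ifelse(per_group == n_acc, "core", "dispensable"))
  by_group <- data.frame(group_id = names(per_group),
                         n_accessions = as.integer(per_group),
                         n_genes = as.integer(size),
                         category = as.character(category),
                         stringsAsFactors = FALSE)
  pct <- function(x) round_half_up(100 * x / total_candidates, 1L)
  summ <- do.call(rbind, lapply(c("core", "dispensable", "specific"),
    function(cat) {
      sel <- by_group$category == cat
      data.frame(category = cat, n_groups = sum(sel),
                 n_genes = sum(by_group$n_genes[sel]),
                 pct_genes = pct(sum(by_group$n_genes[sel])),
                 stringsAsFactors = FALSE)
    }))
  spec_groups <- by_group$group_id[by_group$category == "specific"]
  spec_acc <- groups[groups$group_id %in% spec_groups, , drop = FALSE]
  spec_tab <- table(factor(spec_acc$accession, levels = accession_ids))
  total_categorized <- sum(by_group$n_genes)
  structure(list(
    by_group = by_group, summary = summ,
    specific_by_accession = data.frame(
      accession = accession_ids, n_genes = as.integer(spec_tab),
      pct_genes = pct(as.integer(spec_tab)), stringsAsFactors = FALSE),
    total_categorized = total_categorized,
    total_candidates = total_candidates,
    pct_categorized = pct(total_categorized)
  ), class = "nlr_catalog_summary")
}

#' @export
print.nlr_catalog_summary <- function(x, ...) {
  cat("NLR ortholog catalog:", x$total_categorized, "of",
      x$total_candidates, "candidates categorized (",
      x$pct_categorized, "% )\n", sep = " ")
  print(x$summary, row.names = FALSE)
  cat("specific NLRs per accession:\n")
  print(x$specific_by_accession, row.names = FALSE)
  invisible(x)
}

#' Pan / core accumulation curve
#'
#' For an ordering of accessions, `pan(k)` counts groups with at least one
#' member among the first k accessions and `core(k)` the groups present in
#' all first k.  All k! orderings are enumerated up to `max_exact`
#' accessions; beyond that, orderings are sampled.
#'
#' @param groups long data.frame with `group_id`, `accession`.
#' @param accession_ids accession order universe.
#' @param max_exact enumerate all orderings up to this panel size.
#' @param n_samples sampled orderings beyond `max_exact`.
#' @param seed seed for sampling.
#' @return data.frame per k: `pan_mean`, `pan_min`, `pan_max`, `core_mean`,
#'   `core_min`, `core_max`.
#' @export
pan_core_curve <- function(groups, accession_ids, max_exact = 6L,
                           n_samples = 200L, seed = 1L) {
  stopifnot(length(accession_ids) >= 1L)
  gids <- unique(groups$group_id)
  memb <- matrix(FALSE, length(gids), length(accession_ids),
                 dimnames = list(gids, accession_ids))
  memb[cbind(match(groups$group_id, gids),
             match(groups$accession, accession_ids))] <- TRUE
  n <- length(accession_ids)
  orderings <- if (n <= max_exact) {
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    perms(seq_len(n))
  } else {
    set.seed(seed)
    lapply(seq_len(n_samples), function(i) sample.int(n))
  }
  pan <- matrix(0L, length(orderings), n)
  core <- matrix(0L, length(orderings), n)
  for (o in seq_along(orderings)) {
    idx <- orderings[[o]]
    any_so_far <- rep(FALSE, length(gids))
    all_so_far <- rep(TRUE, length(gids))
    for (k in seq_len(n)) {
      any_so_far <- any_so_far | memb[, idx[k]]
      all_so_far <- all_so_far & memb[, idx[k]]
      pan[o, k] <- sum(any_so_far)
      core[o, k] <- sum(all_so_far)
    }
  }
  data.frame(
    k = seq_len(n),
    pan_mean = colMeans(pan), pan_min = apply(pan, 2L, min),
    pan_max = apply(pan, 2L, max),
    core_mean = colMeans(core), core_min = apply(core, 2L, min),
    core_max = apply(core, 2L, max)
  )
}
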