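# End-to-end orchestration: simulate (or load) a panel, classify NLRs,
# assign subgroups, build the NLR map, catalogue orthologs, test for CNVs
# and dissect significant clusters mechanistically.

#' Validated pipeline configuration
#'
#' @param mode `"simulate"` (panel generated from `panel_cfg`/`mut_cfg`) or
#'   `"user_data"` (a prebuilt panel object is passed to [run_pipeline()]).
#' @param panel_cfg a [panel_config()] (simulate mode).
#' @param mut_cfg a [mutation_config()] (simulate mode).
#' @param planted_counts optional planted-CNV count matrix, see
#'   [simulate_panel()].
#' @param seed master seed (mandatory in simulate mode).
#' @param boot_reps bootstrap replicates for subgroup supports.
#' @param support_min minimum clade support for subgroup assignment.
#' @param sim_min,cov_min orthology / partial-vote thresholds.
#' @param max_gap physical-cluster gap (bp).
#' @param sd_min,alpha CNV test parameters.
#' @param window enrichment window (bp).
#' @param min_anchor,max_bridge NLR-map parameters.
#' @param window_pad pseudogene-scan region padding (bp).
#' @return config list of class `nlr_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "user_data"),
                            panel_cfg = panel_config(),
                            mut_cfg = mutation_config(),
                            planted_counts = NULL, seed = 1L,
                            boot_reps = 100L, support_min = 90,
                            sim_min = 0.5, cov_min = 0.3,
                            max_gap = 50000L, sd_min = 2.0, alpha = 0.05,
                            window = 1e6, min_anchor = 21L,
                            max_bridge = 1e5, window_pad = 10000L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, sd_min >= 0, max_gap > 0,
            boot_reps >= 0, support_min >= 0, support_min <= 100,
            sim_min >= 0, sim_min <= 1, cov_min >= 0, cov_min <= 1,
            window > 0, min_anchor >= 12, window_pad >= 0)
  if (mode == "simulate" && (is.null(seed) || is.na(seed))) {
    stop("a seed is mandatory in simulate mode")
  }
  structure(as.list(environment()), class = "nlr_pipeline_config")
}

scan_panel <- function(panel) {
  recs <- lapply(panel$accessions, function(a) {
    if (nrow(a$genes) == 0L) return(NULL)
    select_candidates(a$genes)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# subgroup assignment across the panel: tree route for intact NLRs with the
# reference accession's labels as references, similarity vote for partials
assign_panel_subgroups <- function(records, reference_labels, boot_reps,
                                   support_min, sim_min, cov_min, seed) {
  uid <- paste(records$accession, records$gene_id, sep = "|")
  intact <- which(records$status == "intact")
  nbarc <- setNames(
    vapply(intact, function(i) extract_nbarc(records[i, ]), character(1)),
    uid[intact])
  refs_uid <- uid %in% names(reference_labels)
  records$subgroup[refs_uid] <- reference_labels[uid[refs_uid]]
  queries <- setdiff(names(nbarc), names(reference_labels))
  tree <- NULL
  if (length(queries) && length(nbarc) >= 4L) {
    msa <- trim_columns(progressive_align(nbarc))
    tree <- bootstrap_support(msa, n_reps = boot_reps, seed = seed)
    assigned <- assign_intact_groups(tree, reference_labels, support_min)
    hit <- match(names(assigned), uid)
    records$subgroup[hit] <- unname(assigned)
  }
  partial <- which(records$status == "partial")
  if (length(partial)) {
    ref_intact <- which(uid %in% names(reference_labels) &
                          records$status == "intact")
    if (length(ref_intact)) {
      refs <- data.frame(
        nbarc = vapply(ref_intact, function(i)
          extract_nbarc(records[i, ]), character(1)),
        group = records$subgroup[ref_intact], stringsAsFactors = FALSE)
      voted <- assign_partial_groups(
        data.frame(gene_id = uid[partial],
                   protein = records$protein[partial],
                   stringsAsFactors = FALSE),
        refs, sim_min, cov_min)
      records$subgroup[partial] <- unname(voted)
    }
  }
  list(records = records, tree = tree)
}

#' Run the full NLR divergence pipeline
#'
#' Stage order: simulate/load -> motif scan -> subgroup assignment -> NLR
#' map -> physical clusters & ortholog catalog -> CNV tests & window
#' enrichment -> pseudogene scan of significant clusters.  With `out_dir`
#' all catalogs are written as TSV/BED plus a JSON manifest.
#'
#' @param config a [pipeline_config()].
#' @param panel prebuilt `nlr_panel` (required in user_data mode; optional
#'   override in simulate mode).
#' @param reference_labels named vector `accession|gene_id` -> subgroup for
#'   user_data mode; in simulate mode the reference accession's truth labels
#'   are used (they stand in for previously classified known NLRs).
#' @param out_dir optional output directory.
#' @return list of class `nlr_pipeline_result` with `panel`, `records`,
#'   `tree`, `map`, `clusters`, `counts`, `groups`, `catalog`, `pan_core`,
#'   `cnv`, `enrichment`, `pseudogenes`, `config`.
#' @export
run_pipeline <- function(config, panel = NULL, reference_labels = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "nlr_pipeline_config"))
  if (config$mode == "simulate" && is.null(panel)) {
    panel <- simulate_panel(config$panel_cfg, config$mut_cfg,
                            seed = config$seed,
                            planted_counts = config$planted_counts)
  }
  if (is.null(panel)) stop("user_data mode requires a panel object")
  reference <- names(panel$accessions)[1L]

  records <- scan_panel(panel)
  if (is.null(reference_labels)) {
    ref_genes <- panel$accessions[[reference]]$genes
    reference_labels <- setNames(
      ref_genes$subgroup, paste(reference, ref_genes$gene_id, sep = "|"))
    reference_labels <- reference_labels[!is.na(reference_labels)]
  }
  sg <- assign_panel_subgroups(records, reference_labels, config$boot_reps,
                               config$support_min, config$sim_min,
                               config$cov_min, config$seed)
  records <- sg$records

  ref_genome <- panel$accessions[[reference]]$genome
  chains <- lapply(setdiff(names(panel$accessions), reference), function(a)
    accession_chains(ref_genome, panel$accessions[[a]]$genome,
                     config$min_anchor))
  names(chains) <- setdiff(names(panel$accessions), reference)

  map <- build_map(panel, records, reference, config$min_anchor,
                   config$max_bridge, chains = chains)
  clusters <- merge_physical_clusters(map, config$max_gap)
  counts <- cluster_count_matrix(clusters, names(panel$accessions))
  groups <- ortho_catalog(clusters, config$sim_min, config$cov_min)
  catalog <- categorize(groups, names(panel$accessions),
                        total_candidates = nrow(records))
  pan_core <- pan_core_curve(groups, names(panel$accessions),
                             seed = config$seed)
  cnv <- detect_cnv_regions(counts, config$alpha, config$sd_min)
  enrich <- window_subgroup_enrichment(
    map, vapply(ref_genome$seqs, nchar, numeric(1)),
    window = config$window, alpha = config$alpha)

  # mechanistic dissection of significant clusters
  pseudo <- list()
  sig <- cnv$cluster_id[cnv$significant]
  for (cl in sig) {
    cl_row <- clusters[clusters$cluster_id == cl, ]
    ref_in_cl <- which(map$accession == reference &
                         map$ref_seq == cl_row$ref_seq &
                         map$ref_start >= cl_row$start &
                         map$ref_end <= cl_row$end)
    for (i in ref_in_cl) {
      for (acc in names(chains)) {
        cmp <- compare_region(map[i, ], panel$accessions[[acc]]$genome,
                              chains[[acc]], config$window_pad)
        pseudo[[length(pseudo) + 1L]] <- data.frame(
          cluster_id = cl, gene_id = map$gene_id[i], accession = acc,
          verdict = cmp$verdict,
          n_premature_stops = sum(cmp$events$type == "premature_stop"),
          n_frameshifts = sum(grepl("^frameshift", cmp$events$type)),
          n_large_insertions = sum(cmp$events$type == "large_insertion"),
          positions = paste(cmp$events$genomic_pos, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  pseudo <- if (length(pseudo)) do.call(rbind, pseudo) else
    data.frame(cluster_id = character(0), gene_id = character(0),
               accession = character(0), verdict = character(0),
               n_premature_stops = integer(0), n_frameshifts = integer(0),
               n_large_insertions = integer(0), positions = character(0))

  result <- structure(list(panel = panel, records = records, tree = sg$tree,
                           map = map, clusters = clusters, counts = counts,
                           groups = groups, catalog = catalog,
                           pan_core = pan_core, cnv = cnv,
                           enrichment = enrich, pseudogenes = pseudo,
                           config = config),
                      class = "nlr_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write_table(df, file.path(out_dir, name))
  map_out <- result$map
  map_out$protein <- NULL
  w(map_out, "nlr_map.tsv")
  w(result$clusters, "clusters.tsv")
  w(cbind(cluster_id = rownames(result$counts),
          as.data.frame(result$counts)), "cluster_counts.tsv")
  w(result$groups, "ortho_groups.tsv")
  w(result$catalog$summary, "catalog_summary.tsv")
  w(result$catalog$specific_by_accession, "specific_by_accession.tsv")
  w(result$pan_core, "pan_core_curve.tsv")
  w(result$cnv, "cnv_tests.tsv")
  w(result$enrichment, "window_enrichment.tsv")
  w(result$pseudogenes, "pseudogene_report.tsv")
  write_cnv_bed(result$cnv, result$clusters,
                file.path(out_dir, "cnv_regions.bed"))
  if (!is.null(result$tree)) {
    write_support_tree(result$tree, file.path(out_dir, "nlr_tree.nwk"))
  }
  if (!is.null(result$panel$planted_cnv)) {
    w(result$panel$planted_cnv, "planted_cnv.tsv")
  }
  cfg <- result$config
  manifest <- list(
    package = "nlrpan",
    version = as.character(utils::packageVersion("nlrpan")),
    mode = cfg$mode, seed = cfg$seed,
    parameters = cfg[c("boot_reps", "support_min", "sim_min", "cov_min",
                       "max_gap", "sd_min", "alpha", "window", "min_anchor",
                       "max_bridge", "window_pad")],
    n_accessions = length(result$panel$accessions),
    n_candidates = nrow(result$records),
    n_clusters = nrow(result$clusters),
    n_significant_cnv = sum(result$cnv$significant)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.nlr_pipeline_result <- function(x, ...) {
  cat("<nlr_pipeline_result>\n")
  cat("  candidates:", nrow(x$records),
      sprintf("(%d intact, %d partial)\n",
              sum(x$records$status == "intact"),
              sum(x$records$status == "partial")))
  cat("  mapped:", sum(x$map$map_status != "unmapped"), "/",
      nrow(x$map), "\n")
  cat("  clusters:", nrow(x$clusters), "| significant CNV:",
      sum(x$cnv$significant), "\n")
  invisible(x)
}

#' Human-readable run summary from a pipeline output directory
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return invisibly, a list of the parsed tables.
#' @export
pipeline_report <- function(out_dir) {
  need <- function(name, stage) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) {
      stop("missing output '", name, "' - did stage '", stage,
           "' complete?")
    }
    read_table(p)
  }
  summ <- need("catalog_summary.tsv", "ortho_catalog")
  spec <- need("specific_by_accession.tsv", "ortho_catalog")
  curve <- need("pan_core_curve.tsv", "ortho_catalog")
  cnv <- need("cnv_tests.tsv", "cnv_stats")
  cat("== NLR catalog ==\n")
  print(summ, row.names = FALSE)
  cat("\nspecific NLRs per accession:\n")
  print(spec, row.names = FALSE)
  cat("\n== pan/core accumulation ==\n")
  print(curve, row.names = FALSE)
  sig <- cnv[which(cnv$significant), , drop = FALSE]
  cat("\n==", nrow(sig), "significant CNV region(s) ==\n")
  if (nrow(sig)) print(sig, row.names = FALSE)
  conf <- NULL
  if (file.exists(file.path(out_dir, "planted_cnv.tsv"))) {
    planted <- read_table(file.path(out_dir, "planted_cnv.tsv"))
    clusters <- need("clusters.tsv", "ortho_catalog")
    hit <- vapply(seq_len(nrow(planted)), function(i) {
      ov <- clusters$ref_seq == planted$seq_id[i] &
        clusters$start < planted$end[i] & clusters$end > planted$start[i]
      any(clusters$cluster_id[ov] %in% sig$cluster_id)
    }, logical(1))
    conf <- data.frame(planted_cluster = planted$cluster_id,
                       detected = hit)
    cat("\n== planted-CNV confusion table ==\n")
    print(conf, row.names = FALSE)
  }
  invisible(list(summary = summ, specific = spec, curve = curve,
                 cnv = cnv, confusion = conf))
}
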