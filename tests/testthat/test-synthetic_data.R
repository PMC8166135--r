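test_that("panel and mutation configs validate their fields", {
  expect_error(panel_config(intra_cluster_gap = c(1000, 60000)), "50 kb")
  expect_error(panel_config(inter_cluster_gap = c(1000, 60000)), "50 kb")
  expect_error(mutation_config(gene_deletion_prob = 1.2))
  cfg <- panel_config(n_clusters = 20L, n_chromosomes = 1L,
                      chromosome_length = 1e5)
  expect_error(simulate_reference(cfg, seed = 1), "too short")
})

test_that("the simulated reference satisfies its construction contract", {
  ref <- tiny_ref()
  cfg <- ref$cfg
  expect_equal(nrow(ref$genes), 9L)
  # every gene intact with the four motifs in order
  recs <- select_candidates(ref$genes)
  expect_true(all(recs$status == "intact"))
  expect_true(all(recs$n_motifs == 4L))
  # each requested subgroup used at least once
  expect_setequal(unique(ref$genes$subgroup), cfg$subgroup_labels)
  # gaps: < 50 kb within clusters, > 50 kb between
  g <- ref$genes[order(ref$genes$start), ]
  gaps <- g$start[-1L] - g$end[-nrow(g)]
  same_cluster <- g$cluster_id[-1L] == g$cluster_id[-nrow(g)]
  expect_true(all(gaps[same_cluster] < 50000))
  expect_true(all(gaps[!same_cluster] > 50000))
})

test_that("simulation is deterministic down to written bytes", {
  cfg <- panel_config(n_accessions = 2L, n_chromosomes = 1L,
                      chromosome_length = 6e5, n_clusters = 2L)
  p1 <- simulate_panel(cfg, mutation_config(), seed = 33L)
  p2 <- simulate_panel(cfg, mutation_config(), seed = 33L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_panel(p1, d1); write_panel(p2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  p3 <- simulate_panel(cfg, mutation_config(), seed = 34L)
  expect_false(identical(p1$accessions[[2]]$genome$seqs,
                         p3$accessions[[2]]$genome$seqs))
})

test_that("null mutation config reproduces the reference exactly", {
  ref <- tiny_ref()
  acc <- derive_accession(ref, mutation_config(0, 0, 0, 0, 0, 0), "Z",
                          seed = 1L)
  expect_identical(acc$genome$seqs, ref$genome$seqs)
  expect_equal(nrow(acc$truth), 0L)
  expect_identical(acc$genes$protein, ref$genes$protein)
})

test_that("SNV counts follow the binomial model on non-genic sequence", {
  cfg <- panel_config(n_accessions = 2L, n_chromosomes = 1L,
                      chromosome_length = 1e6, n_clusters = 1L,
                      genes_per_cluster = c(1L, 1L))
  ref <- simulate_reference(cfg, seed = 21L)
  acc <- derive_accession(ref, mutation_config(snv_rate = 0.001,
                                               small_indel_rate = 0,
                                               0, 0, 0, 0),
                          "Z", seed = 22L)
  n_snv <- sum(acc$truth$event_type == "snv")
  expect_lt(abs(n_snv - 1e6 * 0.001), 3 * sqrt(1e6 * 0.001 * 0.999))
  # every recorded SNV is recoverable by diffing the sequences
  s_ref <- strsplit(ref$genome$seqs[[1L]], "")[[1L]]
  s_acc <- strsplit(acc$genome$seqs[[1L]], "")[[1L]]
  expect_equal(length(s_ref), length(s_acc))
  diff_pos <- which(s_ref != s_acc) - 1L
  expect_setequal(diff_pos, acc$truth$ref_pos[acc$truth$event_type == "snv"])
})

test_that("planted premature stops truncate the annotated protein", {
  ref <- tiny_ref()
  acc <- derive_accession(ref, mutation_config(0, 0, 0, 0, 0,
                                               premature_stop_prob = 1),
                          "Z", seed = 5L)
  expect_true(all(acc$genes$premature_stop))
  expect_true(all(select_candidates(acc$genes)$status == "partial"))
  expect_equal(sum(acc$truth$event_type == "premature_stop"),
               nrow(ref$genes))
})

test_that("gene deletions and duplications change annotation counts", {
  ref <- tiny_ref()
  del <- derive_accession(ref, mutation_config(0, 0, 0,
                                               gene_deletion_prob = 1,
                                               0, 0), "Z", seed = 2L)
  expect_equal(nrow(del$genes), 0L)
  dup <- derive_accession(ref, mutation_config(0, 0, 0, 0,
                                               gene_duplication_prob = 1,
                                               0), "Z", seed = 2L)
  expect_equal(nrow(dup$genes), 2L * nrow(ref$genes))
  # duplicates carry their parent lineage and stay within 50 kb
  dups <- dup$genes[grepl("_dup$", dup$genes$gene_id), ]
  parents <- dup$genes[!grepl("_dup$", dup$genes$gene_id), ]
  off <- dups$start - parents$end[match(dups$lineage_id,
                                        parents$gene_id)]
  expect_true(all(off > 0 & off < 50000))
  # unmutated duplicates translate identically to their parents
  expect_identical(dups$protein,
                   parents$protein[match(dups$lineage_id,
                                         parents$gene_id)])
})

test_that("simulate_panel plants CNV clusters with requested counts", {
  cfg <- panel_config(n_accessions = 5L, n_chromosomes = 1L,
                      chromosome_length = 9e5, n_clusters = 5L,
                      genes_per_cluster = c(2L, 3L))
  planted <- rbind(c(4L, 4L, 1L, 2L, 3L))
  p <- simulate_panel(cfg, mutation_config(0, 0, 0, 0, 0, 0), seed = 9L,
                      planted_counts = planted)
  expect_equal(nrow(p$planted_cnv), 1L)
  cl <- p$planted_cnv$cluster_id[1L]
  counts <- vapply(p$accessions, function(a)
    sum(a$genes$lineage_id %in%
          p$reference$genes$gene_id[p$reference$genes$cluster_id == cl]),
    numeric(1))
  expect_equal(unname(counts), c(4, 4, 1, 2, 3))
  # config errors
  expect_error(simulate_panel(cfg, mutation_config(), seed = 1,
                              planted_counts = matrix(1, 9, 5)),
               "more planted")
  expect_error(simulate_panel(cfg, mutation_config(), seed = 1,
                              planted_counts = rbind(c(2, 4, 1, 1, 1))),
               "row maximum")
})
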