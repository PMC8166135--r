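fake_map <- function(starts, ends, seq = "chr01", acc = "A") {
  n <- length(starts)
  data.frame(gene_id = if (n) sprintf("%s_g%03d", acc, seq_len(n))
               else character(0),
             accession = rep(acc, n), seq_id = rep(seq, n),
             start = starts, end = ends, strand = rep("+", n),
             protein = rep(strrep("A", 10), n), ref_seq = rep(seq, n),
             ref_start = starts, ref_end = ends,
             map_status = rep("mapped", n), stringsAsFactors = FALSE)
}

test_that("physical clustering applies the strict 50 kb gap rule", {
  # gap 49,500 -> one cluster
  m <- fake_map(c(0, 50500), c(1000, 51500))
  cl <- merge_physical_clusters(m)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 2L)
  # gap exactly 50,000 -> two clusters
  m2 <- fake_map(c(0, 51000), c(1000, 52000))
  expect_equal(nrow(merge_physical_clusters(m2)), 2L)
  # single gene -> singleton cluster
  m3 <- fake_map(1000, 2000)
  cl3 <- merge_physical_clusters(m3)
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$n_members, 1L)
})

test_that("clustering equals the brute-force union oracle", {
  withr::with_seed(77, {
    for (r in 1:50) {
      n <- sample(2:12, 1)
      starts <- sort(sample.int(5e5, n))
      ends <- starts + sample(100:2000, n, replace = TRUE)
      gap <- sample(c(1000L, 20000L, 50000L), 1)
      cl <- merge_physical_clusters(fake_map(starts, ends), max_gap = gap)
      orc <- oracle_merge_intervals(starts, ends, gap)
      expect_equal(nrow(cl), nrow(orc))
      expect_equal(cl$start, unname(orc[, "start"]))
      expect_equal(cl$end, unname(orc[, "end"]))
    }
  })
})

test_that("cluster count matrix zero-fills and conserves totals", {
  m <- rbind(fake_map(c(0, 1000), c(500, 1500), acc = "A"),
             fake_map(5000, 5500, acc = "C"))
  cl <- merge_physical_clusters(m, max_gap = 600L)
  counts <- cluster_count_matrix(cl, c("A", "B", "C"))
  expect_equal(dim(counts), c(2L, 3L))
  expect_equal(unname(colSums(counts)), c(2, 0, 1))
  expect_equal(unname(counts[1L, ]), c(2, 0, 0))
  expect_equal(unname(counts[2L, ]), c(0, 0, 1))
  empty <- merge_physical_clusters(fake_map(numeric(0), numeric(0)))
  expect_equal(nrow(cluster_count_matrix(empty, "A")), 0L)
})

test_that("ortholog grouping is RBH-based with the one-per-accession rule", {
  ref <- tiny_ref()
  prot <- ref$genes$protein
  # one identical gene per accession -> a single group of 5
  mem <- data.frame(gene_id = sprintf("a%d", 1:5),
                    accession = sprintf("ACC%02d", 1:5),
                    protein = prot[1L], stringsAsFactors = FALSE)
  grp <- build_ortho_groups(mem)
  expect_equal(length(unique(grp$group_id)), 1L)
  # a duplicated copy in one accession is split into its own group
  mem2 <- rbind(mem, data.frame(gene_id = "a1b", accession = "ACC01",
                                protein = prot[1L]))
  grp2 <- build_ortho_groups(mem2)
  tab <- table(grp2$group_id)
  expect_equal(sort(unname(as.integer(tab))), c(1L, 5L))
  # members below the similarity floor become singletons
  mem3 <- data.frame(gene_id = c("x", "y"), accession = c("A1", "A2"),
                     protein = c(strrep("W", 60), strrep("G", 60)),
                     stringsAsFactors = FALSE)
  expect_equal(length(unique(build_ortho_groups(mem3)$group_id)), 2L)
})

test_that("ortholog grouping is invariant to member order", {
  ref <- tiny_ref()
  g <- ref$genes[ref$genes$cluster_id == ref$genes$cluster_id[1L], ]
  mem <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(gene_id = g$gene_id, accession = sprintf("ACC%02d", k),
               protein = g$protein, stringsAsFactors = FALSE)
  }))
  base <- build_ortho_groups(mem)
  key <- function(grp) {
    member <- paste(grp$accession, grp$gene_id)
    unname(sort(vapply(split(member, grp$group_id),
                       function(v) paste(sort(v), collapse = "+"),
                       character(1))))
  }
  withr::with_seed(5, {
    perm <- mem[sample.int(nrow(mem)), ]
    expect_identical(key(build_ortho_groups(perm)), key(base))
  })
})

test_that("categorization partitions genes and computes percentages", {
  groups <- rbind(
    data.frame(group_id = "g1", accession = c("A", "B", "C")),
    data.frame(group_id = "g2", accession = c("A", "B")),
    data.frame(group_id = "g3", accession = "C"))
  cat3 <- categorize(groups, c("A", "B", "C"), total_candidates = 8L)
  s <- cat3$summary
  expect_equal(s$n_genes[s$category == "core"], 3L)
  expect_equal(s$n_genes[s$category == "dispensable"], 2L)
  expect_equal(s$n_genes[s$category == "specific"], 1L)
  expect_equal(cat3$total_categorized, 6L)
  expect_equal(cat3$pct_categorized, round(6 / 8 * 100, 1))
  # partition property: categories sum to all categorized genes
  expect_equal(sum(s$n_genes), nrow(groups))
  # single-accession panel -> everything specific
  solo <- data.frame(group_id = c("g1", "g2"), accession = "A")
  cs <- categorize(solo, "A")
  expect_equal(cs$summary$n_genes[cs$summary$category == "specific"], 2L)
})

test_that("pan/core curves behave at the boundaries and monotonically", {
  ids <- c("A", "B", "C")
  identical_groups <- do.call(rbind, lapply(c("g1", "g2"), function(g)
    data.frame(group_id = g, accession = ids)))
  flat <- pan_core_curve(identical_groups, ids)
  expect_true(all(flat$pan_mean == 2) && all(flat$core_mean == 2))
  # pairwise-disjoint accessions
  disj <- data.frame(group_id = c("g1", "g2", "g3"), accession = ids)
  d <- pan_core_curve(disj, ids)
  expect_equal(d$pan_mean, c(1, 2, 3))
  expect_equal(d$core_mean[2:3], c(0, 0))
  expect_equal(d$pan_mean[1L], d$core_mean[1L])
  # monotonicity on a random membership pattern
  withr::with_seed(2, {
    memb <- expand.grid(group_id = sprintf("g%d", 1:12),
                        accession = sprintf("A%d", 1:4))
    memb <- memb[sample(nrow(memb), 30), ]
    cv <- pan_core_curve(memb, sprintf("A%d", 1:4))
    expect_true(all(diff(cv$pan_min) >= 0))
    expect_true(all(diff(cv$core_max) <= 0))
  })
})
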