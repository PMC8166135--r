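test_that("find_mums handles identity, SNV splits and disjoint input", {
  withr::with_seed(8, {
    s <- random_dna_str(5000)
    m <- find_mums(s, s)
    plus <- m[m$strand == "+", ]
    expect_equal(nrow(plus), 1L)
    expect_equal(plus$ref_start, 0)
    expect_equal(plus$ref_end, 5000)

    # one SNV -> two abutting matches around it
    p <- 2500L
    base <- substr(s, p + 1L, p + 1L)
    alt <- setdiff(c("A", "C", "G", "T"), base)[1L]
    q <- paste0(substr(s, 1, p), alt, substr(s, p + 2L, 5000))
    m2 <- find_mums(s, q)
    m2 <- m2[m2$strand == "+", ]
    expect_equal(nrow(m2), 2L)
    expect_equal(sort(m2$ref_start), c(0, p + 1))
    expect_equal(sort(m2$ref_end), c(p, 5000))

    # sequences sharing no 21-mer
    a <- strrep("AC", 300)
    b <- strrep("GT", 300)
    expect_equal(nrow(find_mums(a, b)), 0L)
  })
  expect_error(find_mums("ACGT", "ACGT", min_length = 8), "min_length")
})

test_that("find_mums reports reverse-strand matches", {
  withr::with_seed(9, {
    s <- random_dna_str(2000)
    m <- find_mums(s, revcomp(s))
    minus <- m[m$strand == "-", ]
    expect_gte(sum(minus$length), 1990)
  })
})

test_that("chain_blocks keeps the heaviest collinear chain", {
  # two crossing matches: the longer survives
  matches <- data.frame(
    ref_start = c(0, 500), ref_end = c(400, 550),
    qry_start = c(600, 0), qry_end = c(1000, 50),
    strand = "+", length = c(400, 50))
  ch <- chain_blocks(matches)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$length, 400)
  # already collinear -> all retained
  coll <- data.frame(ref_start = c(0, 500), ref_end = c(100, 700),
                     qry_start = c(10, 520), qry_end = c(110, 720),
                     strand = "+", length = c(100, 200))
  expect_equal(nrow(chain_blocks(coll)), 2L)
})

test_that("projection is exact in blocks and flags insertions between", {
  ident <- data.frame(ref_start = 0, ref_end = 1e4, qry_start = 0,
                      qry_end = 1e4, strand = "+", length = 1e4)
  pr <- project_interval(ident, c(100, 200))
  expect_identical(pr$status, "mapped")
  expect_equal(c(pr$ref_start, pr$ref_end), c(100, 200))

  shifted <- ident
  shifted$ref_start <- 500; shifted$ref_end <- 10500
  pr2 <- project_interval(shifted, c(100, 200))
  expect_equal(c(pr2$ref_start, pr2$ref_end), c(600, 700))

  # interval inside a query-specific insertion: zero-length ref bridge
  two <- data.frame(ref_start = c(0, 1000), ref_end = c(1000, 2000),
                    qry_start = c(0, 9000), qry_end = c(1000, 10000),
                    strand = "+", length = 1000)
  pr3 <- project_interval(two, c(4000, 4100))
  expect_identical(pr3$status, "inserted")
  expect_equal(pr3$ref_start, 1000)
  expect_equal(pr3$ref_end, 1000)
  # bridge beyond max_bridge -> unmapped
  expect_identical(project_interval(two, c(4000, 4100),
                                    max_bridge = 5000)$status, "unmapped")
})

test_that("projection round-trips and preserves order along a chain", {
  blocks <- data.frame(ref_start = c(0, 3000), ref_end = c(2000, 6000),
                       qry_start = c(100, 2600), qry_end = c(2100, 5600),
                       strand = "+", length = c(2000, 3000))
  inv <- nlrpan:::invert_chain(blocks)
  withr::with_seed(3, {
    mids <- numeric(0)
    for (r in 1:20) {
      s <- sample(c(150:1900, 2700:5400), 1)
      iv <- c(s, s + 80)
      fwd <- project_interval(blocks, iv)
      expect_identical(fwd$status, "mapped")
      back <- project_interval(inv, c(fwd$ref_start, fwd$ref_end))
      expect_equal(c(back$ref_start, back$ref_end), iv)
      mids <- rbind(mids, c(s, (fwd$ref_start + fwd$ref_end) / 2))
    }
    o <- order(mids[, 1L])
    expect_true(all(diff(mids[o, 2L]) >= 0))
  })
})

test_that("an unmutated panel maps every NLR onto its source locus", {
  cp <- clean_panel()
  map <- cp$map
  expect_true(all(map$map_status == "mapped"))
  expect_equal(map$ref_start, map$start)
  expect_equal(map$ref_end, map$end)
  expect_equal(nrow(attr(map, "unmapped")), 0L)
})

test_that("deleted genes vanish and anchorless scaffolds go unmapped", {
  ref <- tiny_ref()
  mc_del <- mutation_config(0, 0, 0, gene_deletion_prob = 1, 0, 0)
  del <- derive_accession(ref, mc_del, "ACC02", seed = 2L)
  panel <- list(ACC01 = list(genome = ref$genome, genes = ref$genes),
                ACC02 = del)
  recs <- select_candidates(ref$genes)
  map <- build_map(panel, recs, "ACC01")
  expect_false("ACC02" %in% map$accession)  # nothing annotated to map

  # an accession whose NLR sits on a scaffold sharing nothing with the ref
  withr::with_seed(41, {
    orphan_seq <- random_dna_str(5e4)
  })
  g1 <- ref$genes[1L, ]
  orphan_genes <- data.frame(
    gene_id = "orphan1", accession = "ACC03", seq_id = "scaf1",
    start = 1000, end = 1000 + (g1$end - g1$start), strand = "+",
    protein = g1$protein, stringsAsFactors = FALSE)
  panel$ACC03 <- list(
    genome = genome("ACC03", c(scaf1 = orphan_seq)),
    genes = orphan_genes)
  recs3 <- rbind(recs, select_candidates(orphan_genes))
  map3 <- build_map(panel, recs3, "ACC01")
  orphan_row <- map3[map3$accession == "ACC03", ]
  expect_identical(orphan_row$map_status, "unmapped")
  expect_true("orphan1" %in% attr(map3, "unmapped")$gene_id)
})

test_that("PAF round trip preserves anchor chains", {
  ref <- tiny_ref()
  acc <- derive_accession(ref, mutation_config(snv_rate = 1e-4,
                                               small_indel_rate = 0,
                                               0, 0, 0, 0), "Z", seed = 6L)
  chains <- accession_chains(ref$genome, acc$genome)
  f <- withr::local_tempfile(fileext = ".paf")
  write_paf(chains,
            vapply(acc$genome$seqs, nchar, numeric(1)),
            vapply(ref$genome$seqs, nchar, numeric(1)), f)
  back <- read_paf(f)
  expect_setequal(names(back), names(chains))
  for (q in names(chains)) {
    a <- chains[[q]][, c("ref_start", "ref_end", "qry_start", "qry_end")]
    b <- back[[q]][, c("ref_start", "ref_end", "qry_start", "qry_end")]
    expect_equal(unname(as.matrix(a)), unname(as.matrix(b)))
  }
})
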