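test_that("pairwise global alignment matches a reference DP oracle", {
  al <- align_protein_pair("ACDEF", "ACEF", gap_open = -11, gap_ext = -1)
  expect_identical(al$a_aln, "ACDEF")
  expect_identical(al$b_aln, "AC-EF")
  withr::with_seed(42, {
    for (r in 1:15) {
      a <- random_protein(sample(30:80, 1))
      b <- random_protein(sample(30:80, 1))
      mine <- align_protein_pair(a, b, gap_open = -11, gap_ext = -1)$score
      expect_equal(mine, oracle_nw_score(a, b, open = 10, ext = 1))
    }
  })
})

test_that("progressive alignment preserves sequences and handles edges", {
  seqs <- c(s1 = "ACDEFGHIKL", s2 = "ACDEGHIKL", s3 = "ACDEFGHIKL",
            s4 = "ACEFGHIKL")
  msa <- progressive_align(seqs)
  expect_true(all(nchar(msa) == nchar(msa[1L])))
  for (id in names(seqs)) {
    expect_identical(gsub("-", "", msa[[id]]), seqs[[id]])
  }
  expect_identical(progressive_align(seqs[1L]), seqs[1L])
  two <- progressive_align(c(a = "ACDEF", b = "ACDEF"))
  expect_identical(unname(two), c("ACDEF", "ACDEF"))
})

test_that("trim_columns removes columns strictly above the gap threshold", {
  rows <- setNames(paste0("A", c("C", rep("-", 9L)), "G"), letters[1:10])
  trimmed <- trim_columns(rows)              # 0.90 <= 0.92 kept
  expect_true(all(nchar(trimmed) == 3L))
  rows2 <- setNames(paste0("A", rep("-", 10L), "G"),
                    letters[1:10])           # 1.00 > 0.92 removed
  rows2 <- setNames(paste0("A", "-", "G")[rep(1, 10)], letters[1:10])
  trimmed2 <- trim_columns(rows2)
  expect_true(all(nchar(trimmed2) == 2L))
  gapless <- c(a = "ACDE", b = "ACDE")
  expect_identical(trim_columns(gapless), gapless)
  expect_error(trim_columns(c(a = "-", b = "-")), "fully trimmed")
})

test_that("identity distances follow the comparable-column definition", {
  msa <- c(a = strrep("A", 100), b = paste0(strrep("A", 95), "CCCCC"))
  d <- identity_distance(msa)
  expect_equal(d["a", "b"], 0.05)
  expect_equal(diag(d), c(a = 0, b = 0))
  expect_warning(d2 <- identity_distance(c(a = "A-", b = "-A")),
                 "no comparable")
  expect_equal(d2["a", "b"], 1)
})

test_that("neighbor joining recovers additive trees, order-invariantly", {
  withr::with_seed(13, {
    tr <- ape::rtree(7)
    dm <- stats::cophenetic(tr)
    nj <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0,
                 ignore_attr = TRUE)
    perm <- sample(rownames(dm))
    nj2 <- nj_tree(dm[perm, perm])
    expect_equal(ape::dist.topo(nj, nj2), 0, ignore_attr = TRUE)
  })
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
})

test_that("bootstrap supports are deterministic under a fixed seed", {
  ref <- tiny_ref()
  recs <- select_candidates(ref$genes)
  nb <- setNames(vapply(seq_len(nrow(recs)), function(i)
    extract_nbarc(recs[i, ]), character(1)), recs$gene_id)
  msa <- trim_columns(progressive_align(nb))
  t1 <- bootstrap_support(msa, n_reps = 50L, seed = 3L)
  t2 <- bootstrap_support(msa, n_reps = 50L, seed = 3L)
  expect_identical(t1$node.label, t2$node.label)
  t0 <- bootstrap_support(msa, n_reps = 0L, seed = 3L)
  expect_null(t0$node.label)
})

test_that("clade-based assignment follows the supported-monophyly rule", {
  # q1 sits in a 98-support clade whose only reference is G2; q2's
  # smallest unanimous supported clade is {q1,r1,r2,q2} (the far side of
  # the (r3,r4) edge), whose references r1,r2 are both G2
  txt <- "((q1,r1)98,(r2,(q2,(r3,r4)95)40)98);"
  tree <- ape::read.tree(text = txt)
  refs <- c(r1 = "G2", r2 = "G2", r3 = "G1", r4 = "G1")
  out <- assign_intact_groups(tree, refs, support_min = 90)
  expect_identical(out[["q1"]], "G2")
  expect_identical(out[["q2"]], "G2")
  # every supported clade containing the query mixes groups -> unassigned
  mixed <- ape::read.tree(text = "((q2,(r1,r2)95)90,(r3,r4)95);")
  refs_mixed <- c(r1 = "G1", r2 = "G2", r3 = "G1", r4 = "G2")
  expect_warning(out_m <- assign_intact_groups(mixed, refs_mixed),
                 "no query")
  expect_true(is.na(out_m[["q2"]]))
  # no supported edges at all -> everything unassigned
  tree2 <- ape::read.tree(text = "((q1,r1)10,(r2,q2)20);")
  expect_warning(out2 <- assign_intact_groups(tree2, refs[1:2]),
                 "no query")
  expect_true(all(is.na(out2)))
})

test_that("partial-NLR vote counts matches and breaks ties as documented", {
  ref <- tiny_ref()
  recs <- select_candidates(ref$genes)
  nb <- vapply(seq_len(nrow(recs)), function(i) extract_nbarc(recs[i, ]),
               character(1))
  refs <- data.frame(
    nbarc = nb,
    group = ref$genes$subgroup[match(recs$gene_id, ref$genes$gene_id)],
    stringsAsFactors = FALSE)
  # a G1 fragment votes G1 (several qualifying G1 matches, fewer G2)
  g1_idx <- which(refs$group == "G1")[1L]
  frag <- data.frame(gene_id = "p1",
                     protein = substr(nb[g1_idx], 1L, 120L),
                     stringsAsFactors = FALSE)
  expect_identical(unname(assign_partial_groups(frag, refs)), "G1")
  # invariant to reference order
  perm <- withr::with_seed(1, sample(nrow(refs)))
  expect_identical(unname(assign_partial_groups(frag, refs[perm, ])), "G1")
  # nothing above the similarity floor -> unassigned
  junk <- data.frame(gene_id = "p2", protein = strrep("W", 80),
                     stringsAsFactors = FALSE)
  expect_true(is.na(assign_partial_groups(junk, refs)[[1L]]))
  # vote ties resolve by the single best similarity
  two <- data.frame(nbarc = c("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSAVWY"),
                    group = c("GB", "GA"), stringsAsFactors = FALSE)
  q <- data.frame(gene_id = "p3", protein = "ACDEFGHIKLMNPQRSTVWY",
                  stringsAsFactors = FALSE)
  expect_identical(unname(assign_partial_groups(q, two)), "GB")
})
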