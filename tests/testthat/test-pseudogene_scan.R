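# helper: back-translate a protein deterministically (first codon per aa)
bt <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  first <- vapply(strsplit(protein, "")[[1L]], function(a)
    names(gc)[gc == a][1L], character(1))
  paste(first, collapse = "")
}

test_that("exact back-translations align as pure codon matches", {
  aln <- frameshift_align("MKLV", "ATGAAGCTTGTG", ends_free = FALSE)
  expect_true(all(aln$ops$op == "codon_match"))
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  self <- sum(diag(e$BLOSUM62[c("M", "K", "L", "V"), c("M", "K", "L", "V")]))
  expect_equal(aln$score, self)
  expect_equal(nrow(detect_events(aln)), 0L)
  expect_error(frameshift_align("MKLV", "ATG"), "region too short")
})

test_that("single planted InDels produce single frameshift events", {
  p <- "MKLVAGHEWQRNST"
  base <- bt(p)
  for (shift in c(1L, 2L, -1L, -2L)) {
    at <- 6L  # after codon 2
    dna <- if (shift > 0) {
      paste0(substr(base, 1, at), strrep("G", shift),
             substr(base, at + 1, nchar(base)))
    } else {
      paste0(substr(base, 1, at), substr(base, at + 1 - shift, nchar(base)))
    }
    aln <- frameshift_align(p, dna, ends_free = FALSE)
    fs <- aln$ops[aln$ops$op == "frameshift", ]
    expect_equal(nrow(fs), 1L, label = paste("shift", shift))
    expect_equal(fs$shift, shift)
    ev <- detect_events(aln)
    expect_identical(ev$type, if (shift > 0) "frameshift_insertion" else
      "frameshift_deletion")
    expect_equal(ev$dna_pos, 6)
  }
})

test_that("mutated stop codons are read through and reported", {
  p <- "MKLVAGHEWQ"
  dna <- paste0(substr(bt(p), 1, 6), "TAA", substr(bt(p), 10, 30))
  ev <- detect_events(frameshift_align(p, dna, ends_free = FALSE))
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$type, "premature_stop")
  expect_equal(ev$codon_index, 3L)
  expect_equal(ev$dna_pos, 6)
  # several well-separated stops are all counted (read-through, not
  # truncation); nearby stops can instead be absorbed by one gap pair
  p2 <- "MKLVAGHEWQRNSTYFILVCMKLVAGHEWQ"
  b2 <- bt(p2)
  dna3 <- paste0(substr(b2, 1, 12), "TAA", substr(b2, 16, 72),
                 "TGA", substr(b2, 76, nchar(b2)))
  ev3 <- detect_events(frameshift_align(p2, dna3, ends_free = FALSE))
  expect_equal(sum(ev3$type == "premature_stop"), 2L)
  expect_equal(ev3$codon_index[ev3$type == "premature_stop"], c(5L, 25L))
})

test_that("DNA flanks are free in glocal mode", {
  p <- "MKLVAGHEWQ"
  dna <- paste0(strrep("C", 500), bt(p), strrep("G", 500))
  aln <- frameshift_align(p, dna)
  expect_equal(aln$dna_aln[1L], 500)
  expect_true(all(aln$ops$op == "codon_match"))
})

test_that("large insertions inside the CDS are called", {
  p <- tiny_ref()$genes$protein[1L]
  base <- bt(p)
  withr::with_seed(6, {
    ins <- random_dna_str(2000)
  })
  dna <- paste0(substr(base, 1, 300), ins, substr(base, 301, nchar(base)))
  ev <- detect_events(frameshift_align(p, dna, ends_free = FALSE))
  li <- ev[ev$type == "large_insertion", ]
  expect_equal(nrow(li), 1L)
  expect_gte(li$length, 1000)
  expect_lt(abs(li$dna_pos - 300), 30)
})

test_that("the op path conserves protein and region lengths", {
  withr::with_seed(31, {
    for (r in 1:10) {
      p <- random_protein(40)
      dna <- bt(p)
      # random mutations: substitutions and a small indel
      pos <- sample(nchar(dna) - 10, 3)
      for (q in pos) substr(dna, q, q) <- sample(c("A", "C", "G", "T"), 1)
      if (r %% 2 == 0) {
        dna <- paste0(substr(dna, 1, 30), "AC", substr(dna, 31, nchar(dna)))
      }
      aln <- frameshift_align(p, dna, ends_free = FALSE)
      expect_true(nlrpan:::fs_alignment_consistent(aln))
      expect_equal(aln$dna_aln, c(0, nchar(dna)))
    }
  })
})

test_that("with frameshifts and long gaps off, scores match plain global
           protein alignment of the translated region", {
  withr::with_seed(57, {
    params <- fs_align_params(frameshift = -1e9, long_gap_open = -Inf)
    for (r in 1:10) {
      a <- random_protein(30)
      b <- random_protein(30)
      dna <- bt(b)
      mine <- frameshift_align(a, dna, params, ends_free = FALSE)$score
      ref <- align_protein_pair(a, b, gap_open = -11, gap_ext = -1)$score
      expect_equal(mine, ref)
    }
  })
})

test_that("compare_region recovers planted events against truth", {
  ref <- tiny_ref()
  recs <- select_candidates(ref$genes)
  chains_of <- function(acc) accession_chains(ref$genome, acc$genome)

  stop_acc <- derive_accession(
    ref, mutation_config(0, 0, 0, 0, 0, premature_stop_prob = 1),
    "S", seed = 8L)
  ch <- chains_of(stop_acc)
  for (i in seq_len(3L)) {
    cmp <- compare_region(recs[i, ], stop_acc$genome, ch)
    expect_identical(cmp$verdict, "pseudogenized")
    truth <- stop_acc$truth[stop_acc$truth$gene_id == recs$gene_id[i] &
                              stop_acc$truth$event_type == "premature_stop", ]
    stops <- cmp$events[cmp$events$type == "premature_stop", ]
    expect_equal(stops$genomic_pos, truth$ref_pos)
  }

  del_acc <- derive_accession(
    ref, mutation_config(0, 0, 0, gene_deletion_prob = 1, 0, 0),
    "D", seed = 9L)
  cmp_d <- compare_region(recs[1L, ], del_acc$genome, chains_of(del_acc))
  expect_identical(cmp_d$verdict, "absent")

  cons <- derive_accession(ref, mutation_config(0, 0, 0, 0, 0, 0),
                           "C", seed = 10L)
  cmp_c <- compare_region(recs[1L, ], cons$genome, chains_of(cons))
  expect_identical(cmp_c$verdict, "conserved")
  expect_equal(nrow(cmp_c$events), 0L)

  ins_acc <- derive_accession(
    ref, mutation_config(0, 0, large_insertion_prob = 1, 0, 0, 0),
    "I", seed = 11L)
  cmp_i <- compare_region(recs[1L, ], ins_acc$genome, chains_of(ins_acc))
  expect_identical(cmp_i$verdict, "pseudogenized")
  expect_gte(sum(cmp_i$events$type == "large_insertion"), 1L)
  li_len <- cmp_i$events$length[cmp_i$events$type == "large_insertion"]
  truth_len <- as.integer(sub("len=", "", ins_acc$truth$detail[
    ins_acc$truth$gene_id == recs$gene_id[1L]]))
  expect_equal(max(li_len), truth_len)
})
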