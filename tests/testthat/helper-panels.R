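# Shared simulated fixtures, built once per test run (lazily cached).

.fixtures <- new.env(parent = emptyenv())

# small two-subgroup reference: 3 clusters x 3 genes on one chromosome
tiny_ref <- function() {
  if (is.null(.fixtures$tiny_ref)) {
    cfg <- panel_config(n_accessions = 2L, n_chromosomes = 1L,
                        chromosome_length = 6e5, n_clusters = 3L,
                        genes_per_cluster = c(3L, 3L),
                        subgroup_labels = c("G1", "G2"))
    .fixtures$tiny_ref <- simulate_reference(cfg, seed = 4L)
  }
  .fixtures$tiny_ref
}

# zero-mutation 3-accession panel plus its scan and map
clean_panel <- function() {
  if (is.null(.fixtures$clean_panel)) {
    cfg <- panel_config(n_accessions = 3L, n_chromosomes = 1L,
                        chromosome_length = 6e5, n_clusters = 3L,
                        genes_per_cluster = c(2L, 4L))
    mc0 <- mutation_config(0, 0, 0, 0, 0, 0)
    panel <- simulate_panel(cfg, mc0, seed = 11L)
    records <- do.call(rbind, lapply(panel$accessions, function(a)
      select_candidates(a$genes)))
    rownames(records) <- NULL
    map <- build_map(panel, records, "ACC01")
    .fixtures$clean_panel <- list(panel = panel, records = records,
                                  map = map)
  }
  .fixtures$clean_panel
}
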