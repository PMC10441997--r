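# writes a small two-group synthetic study into dir and returns a config list
pipeline_fixture <- function(dir, seed = 5, with_tree = TRUE) {
  tabA <- simulate_correlated_community(
    community_scenario(n_taxa = 24, n_samples = 8, depth = 1500,
                       module_blocks = list(c(8, 0.8), c(8, 0.8)),
                       positive_fraction = 0.8, seed = seed))
  tabB <- simulate_correlated_community(
    community_scenario(n_taxa = 24, n_samples = 8, depth = 1500,
                       module_blocks = list(c(8, 0.8), c(8, 0.8)),
                       cross_block_correlation = 0.5, positive_fraction = 1,
                       seed = seed + 1))
  colnames(tabB) <- sprintf("sample_%d", 9:16)
  tab <- cbind(tabA, tabB)
  write_asv_table(asv_table(tab), file.path(dir, "counts.tsv"))
  meta <- data.frame(sample_id = colnames(tab),
                     group = rep(c("ctl", "trt"), each = 8))
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (with_tree) {
    tr <- with_seed(seed, ape::rphylo(nrow(tab), 1, 0))
    tr$tip.label <- rownames(tab)
    ape::write.tree(tr, file.path(dir, "tree.nwk"))
  }
  list(table = file.path(dir, "counts.tsv"),
       metadata = file.path(dir, "meta.tsv"),
       tree = if (with_tree) file.path(dir, "tree.nwk") else NULL,
       seed = 11,
       rarefy = list(enabled = TRUE, depth = 1200),
       network = list(rho_threshold = 0.55, q_threshold = 0.05),
       cohesion = list(iterations = 50),
       stability = list(repetitions = 20),
       ncm = list(bootstrap = 50),
       consentrait = list(permutations = 100, reference_group = "ctl",
                          treatment_group = "trt"),
       mantel = list(permutations = 49))
}

run_quiet <- function(cfg) {
  suppressWarnings(suppressMessages(run_pipeline(cfg)))
}
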