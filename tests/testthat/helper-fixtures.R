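# Shared fixtures: small simulated worlds, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_env <- new.env()

# Small WGD clade used by several module tests.
small_wgd_sim <- function() {
  if (is.null(fixture_env$small_wgd)) {
    fixture_env$small_wgd <- simulate_dataset(
      sim_config(n_anc_chromosomes = 4L, genes_per_chromosome = 30L,
                 seed = 42L))
  }
  fixture_env$small_wgd
}

# Clean world: one shared WGD, full retention, no other processes. Every
# ingroup family has exactly its two WGD copies.
clean_wgd_config <- function(seed = 7L, retention = 1) {
  sim_config(n_anc_chromosomes = 2L, genes_per_chromosome = 30L,
             retention = retention, bg_dup_rate = 0, loss_rate = 0,
             fission_rate = 0, fusion_rate = 0, ks_log_noise_sd = 0.05,
             seed = seed)
}

clean_wgd_sim <- function() {
  if (is.null(fixture_env$clean_wgd)) {
    fixture_env$clean_wgd <- simulate_dataset(clean_wgd_config())
  }
  fixture_env$clean_wgd
}

# True ancestral chromosome of a gene, reconstructed from its family index.
true_ac <- function(genes, genes_per_chromosome) {
  fam <- as.integer(sub("^F", "", genes$family))
  sprintf("AC%02d", (fam - 1L) %/% genes_per_chromosome + 1L)
}

# Ks lookup helper mirroring the pipeline's source.
ks_lookup <- function(sim, pairs) {
  lut <- setNames(sim$ks_pairs$ks,
                  paste(sim$ks_pairs$gene_a, sim$ks_pairs$gene_b, sep = "|"))
  unname(lut[paste(pairs$gene_a, pairs$gene_b, sep = "|")])
}

expected_wgd_ks <- function(cfg) {
  tr <- ape::read.tree(text = cfg$species_tree)
  nt <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  lab <- cfg$wgd_node[1]
  child <- if (lab %in% tr$tip.label) match(lab, tr$tip.label)
           else nt + match(lab, tr$node.label)
  parent <- tr$edge[tr$edge[, 2] == child, 1]
  t_wgd <- depth[parent] + cfg$wgd_time * (depth[child] - depth[parent])
  2 * cfg$ks_rate * (max(depth[seq_len(nt)]) - t_wgd)
}
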