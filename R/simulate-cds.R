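# Codon-sequence simulation along the gene genealogy. A deliberately simple
# two-rate scheme: third codon positions mutate at the synonymous rate
# (ks_rate per site per unit time), first/second positions at 20% of it;
# mutations that would create a stop codon are reverted. This is enough to
# exercise counting-based Ks estimation; no codon-model fidelity is claimed.

BASES <- c("A", "C", "G", "T")

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

mutate_cds <- function(seq, dt, cfg) {
  if (dt <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  len <- length(ch)
  third <- seq.int(3L, len, 3L)
  other <- setdiff(seq_len(len), third)
  p3 <- 1 - exp(-cfg$ks_rate * dt)
  p12 <- 1 - exp(-0.2 * cfg$ks_rate * dt)
  hit <- c(third[runif(length(third)) < p3],
           other[runif(length(other)) < p12])
  if (!length(hit)) return(seq)
  old <- ch
  for (i in sort(hit)) {
    ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  }
  # revert any codon that became a stop
  stops <- stop_codons()
  cod_idx <- unique((sort(hit) - 1L) %/% 3L)
  for (ci in cod_idx) {
    rng <- (ci * 3L + 1L):(ci * 3L + 3L)
    if (paste(ch[rng], collapse = "") %in% stops) ch[rng] <- old[rng]
  }
  paste(ch, collapse = "")
}

# Evolve sequences down the genealogy. Parents are always created before
# their children, and all children of a node share one event time, so a
# single ascending pass suffices.
simulate_cds <- function(st, genes, cfg) {
  np <- st$np
  par <- st$n_par[seq_len(np)]
  tim <- st$n_time[seq_len(np)]
  has_par <- which(par > 0L)
  child_of <- split(has_par, par[has_par])
  seqs <- character(np)
  roots <- which(par == 0L)
  for (r in roots) seqs[r] <- random_cds(cfg$cds_codons)
  for (i in seq_len(np)) {
    ch <- child_of[[as.character(i)]]
    if (is.null(ch)) next
    evolved <- mutate_cds(seqs[i], tim[ch[1L]] - tim[i], cfg)
    seqs[ch] <- evolved
    seqs[i] <- ""  # free memory
  }
  out <- character(nrow(genes))
  for (k in seq_len(nrow(genes))) {
    nd <- st$g_node[genes$instance[k]]
    out[k] <- mutate_cds(seqs[nd], st$g_tipt[genes$instance[k]] - tim[nd], cfg)
  }
  setNames(out, genes$gene_id)
}
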