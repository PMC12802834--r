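#' Configuration for the genome-evolution simulator
#'
#' Builds and validates the parameter set of [simulate_dataset()]. Defaults
#' describe a small clade of three ingroup species sharing one stem-lineage
#' WGD plus one unduplicated outgroup — the scenario the pipeline is designed
#' to detect. Time is in arbitrary units; all rates are per unit time.
#'
#' @param species_tree Newick string, rooted, with branch lengths. Internal
#'   nodes may be labelled so they can be named as WGD branches.
#' @param outgroup Tip label of the designated outgroup lineage. Must not
#'   descend from any WGD branch; its genes serve as ancestral-chromosome
#'   proxies.
#' @param wgd_node `NULL` for no WGD, or a character vector of branch labels
#'   (each branch named by its child node's label). One entry gives a shared
#'   stem WGD; one entry per ingroup tip gives independent duplications.
#' @param wgd_time Fraction in (0, 1) along each WGD branch at which the
#'   duplication happens.
#' @param retention Probability in \[0, 1\] that a WGD duplicate pair survives
#'   fractionation (applied once, at the WGD).
#' @param bg_dup_rate Small-scale duplications per gene per unit time.
#' @param dup_dispersed_frac Fraction of small-scale duplications inserted at
#'   a random genomic position (the rest are tandem, adjacent to the parent).
#' @param loss_rate Gene losses per gene per unit time.
#' @param n_anc_chromosomes,genes_per_chromosome Ancestral karyotype size.
#' @param fission_rate,fusion_rate Karyotype events per genome per unit time.
#' @param ks_rate Synonymous distance accumulated per lineage per unit time
#'   (a pair diverging at time t ago has true Ks = 2 * ks_rate * t).
#' @param ks_log_noise_sd Standard deviation of the lognormal multiplicative
#'   noise applied to observed Ks (and, through them, to hit scores).
#' @param hit_score_s0,hit_score_lambda Similarity-hit score model:
#'   score = s0 * exp(-lambda * ks_observed), e-value = 10^(-score / 10).
#' @param emit_cds If `TRUE`, simulate codon sequences along the gene
#'   genealogy (two-rate scheme: synonymous third positions at `ks_rate`,
#'   other positions slower) so sequence-based Ks estimation can be exercised.
#' @param cds_codons Codons per gene when `emit_cds = TRUE`.
#' @param seed Integer seed; identical (config, seed) reproduces byte-identical
#'   outputs.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_anc_chromosomes = 2, genes_per_chromosome = 20)
#' cfg$retention
#' @export
sim_config <- function(species_tree = "((A:0.8,(B:0.5,C:0.5)BC:0.3)ING:0.6,OUT:1.4)ROOT;",
                       outgroup = "OUT",
                       wgd_node = "ING",
                       wgd_time = 0.5,
                       retention = 0.4,
                       bg_dup_rate = 0.1,
                       dup_dispersed_frac = 0.5,
                       loss_rate = 0.02,
                       n_anc_chromosomes = 10L,
                       genes_per_chromosome = 100L,
                       fission_rate = 0.3,
                       fusion_rate = 0.2,
                       ks_rate = 0.4,
                       ks_log_noise_sd = 0.25,
                       hit_score_s0 = 200,
                       hit_score_lambda = 1,
                       emit_cds = FALSE,
                       cds_codons = 100L,
                       seed = 1L) {
  cfg <- list(
    species_tree = species_tree, outgroup = outgroup,
    wgd_node = wgd_node, wgd_time = wgd_time, retention = retention,
    bg_dup_rate = bg_dup_rate, dup_dispersed_frac = dup_dispersed_frac,
    loss_rate = loss_rate,
    n_anc_chromosomes = as.integer(n_anc_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    fission_rate = fission_rate, fusion_rate = fusion_rate,
    ks_rate = ks_rate, ks_log_noise_sd = ks_log_noise_sd,
    hit_score_s0 = hit_score_s0, hit_score_lambda = hit_score_lambda,
    emit_cds = isTRUE(emit_cds), cds_codons = as.integer(cds_codons),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

cfg_stop <- function(field, why) {
  stop(sprintf("invalid configuration: field `%s` %s", field, why), call. = FALSE)
}

chk_rate <- function(cfg, field) {
  v <- cfg[[field]]
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
    cfg_stop(field, "must be a single non-negative number")
}

validate_sim_config <- function(cfg) {
  if (!is.character(cfg$species_tree) || length(cfg$species_tree) != 1L)
    cfg_stop("species_tree", "must be a single newick string")
  tr <- tryCatch(ape::read.tree(text = cfg$species_tree),
                 error = function(e) NULL)
  if (is.null(tr)) cfg_stop("species_tree", "is not parseable newick")
  if (length(tr$tip.label) < 2L) cfg_stop("species_tree", "needs >= 2 leaves")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length) ||
      any(tr$edge.length <= 0))
    cfg_stop("species_tree", "needs positive branch lengths on every edge")
  if (anyDuplicated(tr$tip.label))
    cfg_stop("species_tree", "has duplicated tip labels")
  if (!cfg$outgroup %in% tr$tip.label)
    cfg_stop("outgroup", "must be a tip label of species_tree")

  for (f in c("retention", "bg_dup_rate", "dup_dispersed_frac", "loss_rate",
              "fission_rate", "fusion_rate", "ks_log_noise_sd"))
    chk_rate(cfg, f)
  if (cfg$retention > 1) cfg_stop("retention", "must lie in [0, 1]")
  if (cfg$dup_dispersed_frac > 1)
    cfg_stop("dup_dispersed_frac", "must lie in [0, 1]")
  if (!is.numeric(cfg$ks_rate) || cfg$ks_rate <= 0)
    cfg_stop("ks_rate", "must be > 0")
  if (cfg$n_anc_chromosomes < 1L) cfg_stop("n_anc_chromosomes", "must be >= 1")
  if (cfg$genes_per_chromosome < 1L)
    cfg_stop("genes_per_chromosome", "must be >= 1")
  if (cfg$hit_score_s0 <= 0) cfg_stop("hit_score_s0", "must be > 0")
  if (cfg$hit_score_lambda <= 0) cfg_stop("hit_score_lambda", "must be > 0")
  if (cfg$cds_codons < 1L) cfg_stop("cds_codons", "must be >= 1")
  if (is.na(cfg$seed)) cfg_stop("seed", "must be an integer")

  if (!is.null(cfg$wgd_node)) {
    if (!(is.numeric(cfg$wgd_time) && length(cfg$wgd_time) == 1L &&
          cfg$wgd_time > 0 && cfg$wgd_time < 1))
      cfg_stop("wgd_time", "must lie in (0, 1) when wgd_node is set")
    labs <- branch_labels(tr)
    bad <- setdiff(cfg$wgd_node, labs)
    if (length(bad))
      cfg_stop("wgd_node", sprintf(
        "names unknown branch(es): %s (known: %s)",
        paste(bad, collapse = ", "), paste(labs, collapse = ", ")))
    for (lab in cfg$wgd_node) {
      if (cfg$outgroup %in% clade_tips(tr, lab))
        cfg_stop("wgd_node",
                 sprintf("branch `%s` contains the outgroup lineage", lab))
    }
  }
  invisible(cfg)
}

# Branches are named by the label at their child end (tip label or internal
# node label); the root itself has no parent branch.
branch_labels <- function(tr) {
  nt <- length(tr$tip.label)
  kids <- tr$edge[, 2]
  vapply(kids, function(k) {
    if (k <= nt) tr$tip.label[k]
    else if (!is.null(tr$node.label)) tr$node.label[k - nt] else ""
  }, character(1))
}

# Tip labels descending from (and including) the branch named `lab`.
clade_tips <- function(tr, lab) {
  nt <- length(tr$tip.label)
  if (lab %in% tr$tip.label) return(lab)
  node <- nt + match(lab, tr$node.label)
  ape::extract.clade(tr, node)$tip.label
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  tree:     ", x$species_tree, "\n", sep = "")
  cat("  outgroup: ", x$outgroup, "\n", sep = "")
  cat("  WGD:      ",
      if (is.null(x$wgd_node)) "none"
      else sprintf("on %s at fraction %g, retention %g",
                   paste(x$wgd_node, collapse = "+"), x$wgd_time, x$retention),
      "\n", sep = "")
  cat(sprintf("  karyotype: %d chromosomes x %d genes\n",
              x$n_anc_chromosomes, x$genes_per_chromosome))
  cat(sprintf("  rates: dup %g (dispersed %g), loss %g, fission %g, fusion %g\n",
              x$bg_dup_rate, x$dup_dispersed_frac, x$loss_rate,
              x$fission_rate, x$fusion_rate))
  cat(sprintf("  Ks: rate %g, log-noise sd %g; seed %d\n",
              x$ks_rate, x$ks_log_noise_sd, x$seed))
  invisible(x)
}
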