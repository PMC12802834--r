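# Forward simulator of chromosome-scale genome evolution.
#
# State lives in an environment of growable parallel arrays:
#   * genealogy nodes: n_par (parent node, 0 = root), n_time (creation time).
#     Every copying event (speciation, WGD, small-scale duplication) retires
#     the parent node and creates fresh child nodes, so all children of a node
#     share one event time and extant genes are always leaves. The divergence
#     of two genes is then read off the creation time of the children of
#     their most recent common ancestor node.
#   * gene instances: g_fam (family), g_node (current genealogy node),
#     g_sub (subgenome: 0 none, 1, 2), plus name/species/tip-time filled at
#     the tips.
# A genome is a list of integer vectors (chromosomes) of gene-instance ids.

st_new <- function() {
  st <- new.env(parent = emptyenv())
  st$np <- 0L
  st$n_par <- integer(1024L)
  st$n_time <- numeric(1024L)
  st$ng <- 0L
  st$g_fam <- integer(1024L)
  st$g_node <- integer(1024L)
  st$g_sub <- integer(1024L)
  st$g_name <- character(0L)
  st$g_species <- character(0L)
  st$g_tipt <- numeric(0L)
  st$events <- vector("list", 256L)
  st$nev <- 0L
  st
}

st_reserve <- function(st, fields, need) {
  for (f in fields) {
    v <- st[[f]]
    if (length(v) < need) {
      add <- max(length(v), need - length(v))
      st[[f]] <- c(v, vector(typeof(v), add))
    }
  }
}

nodes_add <- function(st, parents, time) {
  n <- length(parents)
  ids <- st$np + seq_len(n)
  st_reserve(st, c("n_par", "n_time"), st$np + n)
  st$n_par[ids] <- parents
  st$n_time[ids] <- time
  st$np <- st$np + n
  ids
}

genes_add <- function(st, fam, node, sub) {
  n <- length(fam)
  ids <- st$ng + seq_len(n)
  st_reserve(st, c("g_fam", "g_node", "g_sub"), st$ng + n)
  st$g_fam[ids] <- fam
  st$g_node[ids] <- node
  st$g_sub[ids] <- sub
  st$ng <- st$ng + n
  ids
}

log_event <- function(st, time, event, lineage, detail, ids) {
  st$nev <- st$nev + 1L
  if (st$nev > length(st$events))
    st$events <- c(st$events, vector("list", length(st$events)))
  st$events[[st$nev]] <- list(time = time, event = event, lineage = lineage,
                              detail = detail, ids = ids)
}

# One gene picked uniformly over the genome; returns c(chromosome, position).
pick_gene <- function(genome, lens) {
  idx <- sample.int(sum(lens), 1L)
  cum <- cumsum(lens)
  ci <- which(idx <= cum)[1L]
  c(ci, idx - c(0L, cum)[ci])
}

# Gillespie simulation of dup/loss/fission/fusion over [t0, t1).
gillespie_evolve <- function(st, genome, t0, t1, cfg, lineage) {
  t <- t0
  repeat {
    lens <- lengths(genome)
    n <- sum(lens)
    if (n == 0L) break
    rd <- cfg$bg_dup_rate * n
    rl <- cfg$loss_rate * n
    rf <- if (any(lens >= 2L)) cfg$fission_rate else 0
    ru <- if (length(genome) >= 2L) cfg$fusion_rate else 0
    R <- rd + rl + rf + ru
    if (R <= 0) break
    t <- t + rexp(1L, R)
    if (t >= t1) break
    u <- runif(1L) * R
    if (u < rd) {
      genome <- ev_duplicate(st, genome, lens, t, cfg, lineage)
    } else if (u < rd + rl) {
      genome <- ev_lose(st, genome, lens, t, lineage)
    } else if (u < rd + rl + rf) {
      genome <- ev_fission(st, genome, lens, t, lineage)
    } else {
      genome <- ev_fusion(st, genome, t, lineage)
    }
  }
  genome
}

ev_duplicate <- function(st, genome, lens, t, cfg, lineage) {
  cp <- pick_gene(genome, lens)
  g <- genome[[cp[1L]]][cp[2L]]
  par <- st$g_node[g]
  nn <- nodes_add(st, c(par, par), t)
  st$g_node[g] <- nn[1L]
  new <- genes_add(st, st$g_fam[g], nn[2L], st$g_sub[g])
  tandem <- runif(1L) >= cfg$dup_dispersed_frac
  if (tandem) {
    genome[[cp[1L]]] <- append(genome[[cp[1L]]], new, after = cp[2L])
  } else {
    cj <- sample.int(length(genome), 1L)
    pos <- sample.int(length(genome[[cj]]) + 1L, 1L) - 1L
    genome[[cj]] <- append(genome[[cj]], new, after = pos)
  }
  log_event(st, t, "dup", lineage,
            if (tandem) "tandem" else "dispersed", c(g, new))
  genome
}

ev_lose <- function(st, genome, lens, t, lineage) {
  cp <- pick_gene(genome, lens)
  g <- genome[[cp[1L]]][cp[2L]]
  genome[[cp[1L]]] <- genome[[cp[1L]]][-cp[2L]]
  log_event(st, t, "loss", lineage, "", g)
  genome[lengths(genome) > 0L]
}

ev_fission <- function(st, genome, lens, t, lineage) {
  # Breakpoints are uniform over internal boundaries genome-wide.
  w <- pmax(lens - 1L, 0L)
  ci <- sample.int(length(genome), 1L, prob = w)
  v <- genome[[ci]]
  b <- sample.int(length(v) - 1L, 1L)
  genome[[ci]] <- v[seq_len(b)]
  genome <- append(genome, list(v[(b + 1L):length(v)]), after = ci)
  log_event(st, t, "fission", lineage, sprintf("boundary=%d", b),
            c(v[b], v[b + 1L]))
  genome
}

ev_fusion <- function(st, genome, t, lineage) {
  ij <- sample.int(length(genome), 2L)
  genome[[ij[1L]]] <- c(genome[[ij[1L]]], genome[[ij[2L]]])
  log_event(st, t, "fusion", lineage, "",
            c(genome[[ij[1L]]][1L]))
  genome[-ij[2L]]
}

# Whole-karyotype doubling with instant fractionation: every gene's new copy
# survives with probability `retention`; retained pairs get fresh sister
# nodes dated at the WGD. Copy chromosomes are appended after the originals.
wgd_apply <- function(st, genome, tw, cfg, lineage) {
  copies <- list()
  for (v in genome) {
    st$g_sub[v] <- 1L
    keep <- v[runif(length(v)) < cfg$retention]
    if (length(keep)) {
      par <- st$g_node[keep]
      n1 <- nodes_add(st, par, tw)
      n2 <- nodes_add(st, par, tw)
      st$g_node[keep] <- n1
      nw <- genes_add(st, st$g_fam[keep], n2, 2L)
      copies <- c(copies, list(nw))
    }
  }
  log_event(st, tw, "wgd", lineage,
            sprintf("retained=%d", sum(lengths(copies))), integer(0))
  c(genome, copies)
}

# Fresh gene instances (and genealogy nodes) for one daughter lineage.
genome_copy <- function(st, genome, t) {
  lapply(genome, function(v) {
    nn <- nodes_add(st, st$g_node[v], t)
    genes_add(st, st$g_fam[v], nn, st$g_sub[v])
  })
}

finalize_tip <- function(st, genome, sp, t_tip) {
  ids <- unlist(genome, use.names = FALSE)
  n <- length(ids)
  need <- st$ng
  if (length(st$g_name) < need) {
    st$g_name <- c(st$g_name, character(need - length(st$g_name)))
    st$g_species <- c(st$g_species, character(need - length(st$g_species)))
    st$g_tipt <- c(st$g_tipt, numeric(need - length(st$g_tipt)))
  }
  st$g_name[ids] <- sprintf("%s_g%05d", sp, seq_len(n))
  st$g_species[ids] <- sp
  st$g_tipt[ids] <- t_tip
  tibble::tibble(
    gene_id = st$g_name[ids],
    species = sp,
    chromosome = rep(sprintf("%s_chr%02d", sp, seq_along(genome)),
                     lengths(genome)),
    ordinal = unlist(lapply(lengths(genome), function(k) seq_len(k) - 1L),
                     use.names = FALSE),
    family = sprintf("F%05d", st$g_fam[ids]),
    subgenome = ifelse(st$g_sub[ids] == 0L, NA_integer_, st$g_sub[ids]),
    instance = ids
  )
}

# Ancestor chain of a genealogy node, leaf first, root last.
anc_chain <- function(st, node) {
  out <- integer(32L)
  i <- 0L
  while (node > 0L) {
    i <- i + 1L
    if (i > length(out)) out <- c(out, integer(length(out)))
    out[i] <- node
    node <- st$n_par[node]
  }
  out[seq_len(i)]
}

#' Simulate a clade of genomes with an optional shared whole-genome duplication
#'
#' Evolves an ancestral karyotype forward along the configured species tree:
#' at each internal node the genome is copied into the daughter lineages;
#' along each branch small-scale duplications (tandem or dispersed), gene
#' losses, chromosome fissions and fusions occur as Poisson processes; on the
#' designated branch(es) a WGD doubles the karyotype and each duplicate pair
#' survives instant fractionation with probability `retention`. True pairwise
#' synonymous divergence for every same-family gene pair follows from the
#' recorded gene genealogy (Ks = ks_rate times the total time separating the
#' pair); observed Ks values add lognormal noise, and all-vs-all similarity
#' hits are generated from them (score = s0 * exp(-lambda * Ks_obs), e-value
#' = 10^(-score/10)), so best-hit semantics mirror a real aligner without one.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `wgd_sim`: a list with elements
#'   * `genes`: tibble of gene placements (gene_id, species, chromosome,
#'     ordinal, plus truth columns family and subgenome),
#'   * `hits`: tibble of directed similarity hits (query, subject, score,
#'     evalue), both directions of every same-family pair, no self and no
#'     cross-family hits,
#'   * `ks_pairs`: tibble of unordered same-family pairs with true and
#'     noisy observed Ks,
#'   * `alg_map`: ancestral-linkage proxy map (proxy_gene, ac, ac_ordinal)
#'     built from the outgroup genome,
#'   * `cds`: named character vector of codon sequences (when `emit_cds`),
#'   * `truth`: event log, per-pair true divergence, WGD timing, and the
#'     config echo.
#' @examples
#' sim <- simulate_dataset(sim_config(n_anc_chromosomes = 2,
#'                                    genes_per_chromosome = 15, seed = 7))
#' table(sim$genes$species)
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  cfg <- config
  tr <- ape::read.tree(text = cfg$species_tree)
  nt <- length(tr$tip.label)
  depth <- ape::node.depth.edgelength(tr)
  root <- nt + 1L
  blab <- branch_labels(tr)
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  elen <- setNames(tr$edge.length, tr$edge[, 2L])

  st <- st_new()
  tips <- list()

  with_rng(substream_seed(cfg$seed, "simulate"), {
    nfam <- cfg$n_anc_chromosomes * cfg$genes_per_chromosome
    rn <- nodes_add(st, rep(0L, nfam), 0)
    rg <- genes_add(st, seq_len(nfam), rn, 0L)
    genome0 <- split(rg, rep(seq_len(cfg$n_anc_chromosomes),
                             each = cfg$genes_per_chromosome))
    anc_chrom <- rep(seq_len(cfg$n_anc_chromosomes),
                     each = cfg$genes_per_chromosome)

    walk <- function(node, genome, t_node) {
      for (child in kids[[as.character(node)]]) {
        lab <- blab[match(child, tr$edge[, 2L])]
        len <- elen[[as.character(child)]]
        g <- genome_copy(st, genome, t_node)
        if (!is.null(cfg$wgd_node) && nzchar(lab) && lab %in% cfg$wgd_node) {
          tw <- t_node + cfg$wgd_time * len
          g <- gillespie_evolve(st, g, t_node, tw, cfg, lab)
          g <- wgd_apply(st, g, tw, cfg, lab)
          g <- gillespie_evolve(st, g, tw, t_node + len, cfg, lab)
        } else {
          g <- gillespie_evolve(st, g, t_node, t_node + len, cfg, lab)
        }
        if (child <= nt) {
          tips[[tr$tip.label[child]]] <<- finalize_tip(st, g, tr$tip.label[child],
                                                       depth[child])
        } else {
          walk(child, g, t_node + len)
        }
      }
    }
    walk(root, genome0, 0)
  })

  genes <- dplyr::bind_rows(tips[order(names(tips))])

  ks_pairs <- pairwise_divergence(st, genes, cfg)
  ks_pairs$ks <- with_rng(substream_seed(cfg$seed, "ksnoise"),
                          ks_pairs$ks_true *
                            exp(rnorm(nrow(ks_pairs), 0, cfg$ks_log_noise_sd)))

  score <- cfg$hit_score_s0 * exp(-cfg$hit_score_lambda * ks_pairs$ks)
  ev <- 10^(-score / 10)
  hits <- tibble::tibble(
    query = c(ks_pairs$gene_a, ks_pairs$gene_b),
    subject = c(ks_pairs$gene_b, ks_pairs$gene_a),
    score = c(score, score),
    evalue = c(ev, ev)
  )
  hits <- hits[order(hits$query, hits$subject), , drop = FALSE]

  alg_map <- build_alg_map(genes, cfg$outgroup, anc_chrom, st)

  cds <- NULL
  if (cfg$emit_cds) {
    cds <- with_rng(substream_seed(cfg$seed, "cds"),
                    simulate_cds(st, genes, cfg))
  }

  ev_log <- event_log_tibble(st)
  truth <- list(
    event_log = ev_log,
    pair_divergence = ks_pairs[, c("gene_a", "gene_b", "ks_true")],
    genes_truth = genes[, c("gene_id", "family", "subgenome")],
    wgd = if (is.null(cfg$wgd_node)) NULL else {
      wt <- ev_log$time[ev_log$event == "wgd"]
      list(nodes = cfg$wgd_node, times = wt,
           expected_ks = 2 * cfg$ks_rate * (max(depth[seq_len(nt)]) - wt))
    },
    tip_depths = setNames(depth[seq_len(nt)], tr$tip.label),
    anc_chromosomes = sprintf("AC%02d", seq_len(cfg$n_anc_chromosomes)),
    config = unclass(cfg)
  )

  out <- list(genes = genes[, setdiff(names(genes), "instance")],
              hits = hits, ks_pairs = ks_pairs, alg_map = alg_map,
              cds = cds, truth = truth, config = cfg)
  class(out) <- "wgd_sim"
  out
}

# True divergence for all same-family pairs of extant genes via genealogy.
pairwise_divergence <- function(st, genes, cfg) {
  fam_groups <- split(genes$instance, genes$family)
  res_a <- character(0); res_b <- character(0); res_d <- numeric(0)
  res_f <- character(0)
  for (f in names(fam_groups)) {
    ids <- fam_groups[[f]]
    k <- length(ids)
    if (k < 2L) next
    chains <- lapply(st$g_node[ids], function(nd) anc_chain(st, nd))
    for (i in seq_len(k - 1L)) {
      ca <- chains[[i]]
      for (j in (i + 1L):k) {
        cb <- chains[[j]]
        hit <- match(ca, cb)
        ii <- which(!is.na(hit))[1L]
        fork <- st$n_time[ca[ii - 1L]]
        d <- (st$g_tipt[ids[i]] - fork) + (st$g_tipt[ids[j]] - fork)
        res_a <- c(res_a, st$g_name[ids[i]])
        res_b <- c(res_b, st$g_name[ids[j]])
        res_d <- c(res_d, d)
        res_f <- c(res_f, f)
      }
    }
  }
  cp <- canonical_pairs(res_a, res_b)
  out <- tibble::tibble(gene_a = cp$gene_a, gene_b = cp$gene_b,
                        family = res_f, ks_true = cfg$ks_rate * res_d)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# The outgroup genome doubles as the ancestral-linkage proxy map: each
# outgroup gene is a probe for the ancestral chromosome its family arose on.
build_alg_map <- function(genes, outgroup, anc_chrom, st) {
  og <- genes[genes$species == outgroup, , drop = FALSE]
  fam_idx <- as.integer(sub("^F", "", og$family))
  ac <- sprintf("AC%02d", anc_chrom[fam_idx])
  ord <- order(ac, og$chromosome, og$ordinal)
  og <- og[ord, ]
  ac <- ac[ord]
  ac_ord <- stats::ave(seq_along(ac), ac, FUN = seq_along) - 1L
  tibble::tibble(proxy_gene = og$gene_id, ac = ac, ac_ordinal = ac_ord)
}

event_log_tibble <- function(st) {
  if (st$nev == 0L)
    return(tibble::tibble(time = numeric(0), event = character(0),
                          lineage = character(0), detail = character(0),
                          gene_ids = character(0)))
  evs <- st$events[seq_len(st$nev)]
  tibble::tibble(
    time = vapply(evs, `[[`, numeric(1), "time"),
    event = vapply(evs, `[[`, character(1), "event"),
    lineage = vapply(evs, `[[`, character(1), "lineage"),
    detail = vapply(evs, `[[`, character(1), "detail"),
    gene_ids = vapply(evs, function(e) paste(e$ids, collapse = ","),
                      character(1))
  )
}

#' Apply chromosome fission and fusion events to one genome
#'
#' Runs the karyotype part of the simulator on an existing gene table:
#' fissions split a chromosome at a uniformly chosen internal boundary
#' (breakpoints uniform over boundaries genome-wide), fusions concatenate two
#' distinct chromosomes end-to-start. Gene content is conserved exactly and
#' ordinals are renumbered consecutively from 0.
#'
#' @param genes Gene table for a single species (columns gene_id, chromosome,
#'   ordinal; extra columns are carried through).
#' @param fission_rate,fusion_rate Events per genome per unit time (>= 0).
#' @param duration Time span to simulate (>= 0).
#' @param seed Integer seed; zero rates or duration return the input unchanged.
#' @return The gene table with updated chromosome and ordinal columns.
#' @examples
#' g <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
#'                     chromosome = "chr1", ordinal = 0:9)
#' apply_karyotype_events(g, fission_rate = 2, fusion_rate = 0,
#'                        duration = 1, seed = 1)
#' @export
apply_karyotype_events <- function(genes, fission_rate, fusion_rate, duration,
                                   seed = 1L) {
  stopifnot(nrow(genes) > 0L, fission_rate >= 0, fusion_rate >= 0,
            duration >= 0)
  genes <- genes[order(genes$chromosome, genes$ordinal), , drop = FALSE]
  chroms <- split(seq_len(nrow(genes)), genes$chromosome)
  chroms <- chroms[unique(genes$chromosome)]
  nfis <- 0L
  with_rng(substream_seed(seed, "karyotype"), {
    t <- 0
    repeat {
      lens <- lengths(chroms)
      rf <- if (any(lens >= 2L)) fission_rate else 0
      ru <- if (length(chroms) >= 2L) fusion_rate else 0
      if (rf + ru <= 0) break
      t <- t + rexp(1L, rf + ru)
      if (t >= duration) break
      if (runif(1L) * (rf + ru) < rf) {
        w <- pmax(lens - 1L, 0L)
        ci <- sample.int(length(chroms), 1L, prob = w)
        v <- chroms[[ci]]
        b <- sample.int(length(v) - 1L, 1L)
        nfis <- nfis + 1L
        nm <- sprintf("%s_f%02d", names(chroms)[ci], nfis)
        chroms[[ci]] <- v[seq_len(b)]
        chroms <- append(chroms, setNames(list(v[(b + 1L):length(v)]), nm),
                         after = ci)
      } else {
        ij <- sample.int(length(chroms), 2L)
        chroms[[ij[1L]]] <- c(chroms[[ij[1L]]], chroms[[ij[2L]]])
        chroms <- chroms[-ij[2L]]
      }
    }
  })
  idx <- unlist(chroms, use.names = FALSE)
  out <- genes[idx, , drop = FALSE]
  out$chromosome <- rep(names(chroms), lengths(chroms))
  out$ordinal <- unlist(lapply(lengths(chroms), function(k) seq_len(k) - 1L),
                        use.names = FALSE)
  out
}

#' @export
print.wgd_sim <- function(x, ...) {
  cat("<wgd_sim>\n")
  sp <- table(x$genes$species)
  cat("  genes:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "), "\n")
  cat(sprintf("  hits: %d directed; pairs with Ks: %d\n",
              nrow(x$hits), nrow(x$ks_pairs)))
  cat(sprintf("  ALG proxies: %d over %d ancestral chromosomes\n",
              nrow(x$alg_map), length(unique(x$alg_map$ac))))
  if (!is.null(x$truth$wgd))
    cat(sprintf("  WGD on %s (expected Ks %s)\n",
                paste(x$truth$wgd$nodes, collapse = "+"),
                paste(sprintf("%.3g", x$truth$wgd$expected_ks), collapse = ", ")))
  invisible(x)
}
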