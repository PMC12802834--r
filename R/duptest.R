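# The exactly-two-segments homolog selection rule, per-AC distance trees over
# the selected duplicates, and the quartet-topology test separating a shared
# WGD from independent lineage-specific duplications.

#' Select ancestral genes with homologs on exactly two segments per species
#'
#' For every species and every AC cluster, each segment is searched for
#' reciprocal best hits between the AC's proxy genes and the genes inside the
#' segment (one homolog per proxy per segment at most, which keeps
#' within-segment small-scale duplicates from interfering). An ancestral
#' proxy gene is accepted for a species when its homologs fall on exactly two
#' distinct segments (both kept); with more than two segments the homologs
#' from the two longest segments are chosen (ties: earlier chromosome id,
#' then smaller start); with fewer than two it is rejected. Only ancestral
#' genes accepted in every ingroup species are returned.
#'
#' @param segments Segment table for all ingroup species (from
#'   [call_segments_genome()], with species column).
#' @param genes Gene table covering those species.
#' @param hits Similarity hits, both proxy-to-gene and gene-to-proxy
#'   directions.
#' @param alg_map Proxy map (proxy_gene, ac).
#' @param evalue_max E-value threshold (default 1e-3).
#' @param ingroup Species to require; defaults to all species in `segments`.
#' @return Tibble of class `homolog_sets`, one row per (ancestral gene,
#'   species, homolog): ancestral_gene, ac, species, gene, seg_id,
#'   chromosome, seg_start, seg_length. Each (ancestral_gene, species) block
#'   has exactly two rows on two distinct segments.
#' @export
select_homolog_sets <- function(segments, genes, hits, alg_map,
                                evalue_max = 1e-3, ingroup = NULL) {
  if (is.null(ingroup)) ingroup <- sort(unique(segments$species))
  rows <- list()
  for (sp in ingroup) {
    segs <- segments[segments$species == sp, , drop = FALSE]
    if (nrow(segs) == 0L) next
    segs$seg_id <- sprintf("%s:%s:%d", sp, segs$chromosome, segs$start)
    gsp <- genes[genes$species == sp, , drop = FALSE]
    gene_seg <- dplyr::bind_rows(lapply(seq_len(nrow(segs)), function(i) {
      sub <- gsp[gsp$chromosome == segs$chromosome[i] &
                   gsp$ordinal >= segs$start[i] &
                   gsp$ordinal < segs$end[i], , drop = FALSE]
      tibble::tibble(gene_id = sub$gene_id, seg_id = segs$seg_id[i],
                     ac = segs$ac[i])
    }))
    for (ac in sort(unique(segs$ac))) {
      proxies <- alg_map$proxy_gene[alg_map$ac == ac]
      gs <- gene_seg[gene_seg$ac == ac, , drop = FALSE]
      if (!length(proxies) || nrow(gs) == 0L) next
      fw <- hits[hits$query %in% proxies & hits$subject %in% gs$gene_id, ,
                 drop = FALSE]
      fw <- fw[fw$evalue <= evalue_max, , drop = FALSE]
      if (nrow(fw) == 0L) next
      fw$seg_id <- gs$seg_id[match(fw$subject, gs$gene_id)]
      # best gene per (proxy, segment)
      fw <- fw[order(fw$query, fw$seg_id, -fw$score, fw$evalue, fw$subject), ,
               drop = FALSE]
      fw <- fw[!duplicated(fw[c("query", "seg_id")]), , drop = FALSE]
      # reverse direction: each gene's best proxy of this AC
      rv <- hits[hits$query %in% gs$gene_id & hits$subject %in% proxies, ,
                 drop = FALSE]
      rb <- best_hits(rv, evalue_max)
      m <- match(fw$subject, rb$query)
      ok <- !is.na(m) & rb$subject[m] == fw$query
      fw <- fw[ok, , drop = FALSE]
      if (nrow(fw) == 0L) next
      si <- match(fw$seg_id, segs$seg_id)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        ancestral_gene = fw$query, ac = ac, species = sp,
        gene = fw$subject, seg_id = fw$seg_id,
        chromosome = segs$chromosome[si],
        seg_start = segs$start[si], seg_length = segs$length[si])
    }
  }
  empty <- tibble::tibble(ancestral_gene = character(0), ac = character(0),
                          species = character(0), gene = character(0),
                          seg_id = character(0), chromosome = character(0),
                          seg_start = integer(0), seg_length = integer(0))
  class(empty) <- c("homolog_sets", class(empty))
  if (!length(rows)) return(empty)
  hs <- dplyr::bind_rows(rows)

  # per (ancestral gene, species): exactly two distinct segments, else the
  # two longest; fewer than two -> rejected
  hs <- hs[order(hs$ancestral_gene, hs$species, -hs$seg_length,
                 hs$chromosome, hs$seg_start), , drop = FALSE]
  grp <- paste(hs$ancestral_gene, hs$species, sep = "\r")
  keep_idx <- unlist(lapply(split(seq_len(nrow(hs)), grp), function(ix) {
    if (length(ix) < 2L) return(integer(0))
    head(ix, 2L)
  }), use.names = FALSE)
  hs <- hs[sort(keep_idx), , drop = FALSE]

  # ancestral genes accepted in every ingroup species
  cnt <- table(unique(hs[c("ancestral_gene", "species")])$ancestral_gene)
  pass <- names(cnt)[cnt == length(ingroup)]
  hs <- hs[hs$ancestral_gene %in% pass, , drop = FALSE]
  hs <- hs[order(hs$ac, hs$ancestral_gene, hs$species, hs$seg_id), ,
           drop = FALSE]
  class(hs) <- c("homolog_sets", class(hs))
  hs
}

# Copy-index assignment: within a species' cluster, rank chromosomes by the
# total assigned length they carry (then id), and segments within by length
# (then start). In each homolog set the homolog on the lower-ranked segment
# is copy 1. This follows segment (and, before rearrangement, subgenome)
# identity without consulting the simulation truth.
copy_index_map <- function(hs_sp) {
  seg <- unique(hs_sp[c("seg_id", "chromosome", "seg_start", "seg_length")])
  chrom_tot <- tapply(seg$seg_length, seg$chromosome, sum)
  chrom_rank <- rank(-as.numeric(chrom_tot), ties.method = "first")
  names(chrom_rank) <- names(chrom_tot)
  o <- order(chrom_rank[seg$chromosome], -seg$seg_length, seg$seg_start)
  setNames(seq_len(nrow(seg)), seg$seg_id[o])
}

#' Mean pairwise distance matrix over the homolog sets of one AC
#'
#' Taxa are species x copy (labels `species.1`, `species.2`), with copy
#' indices assigned per segment identity (see Details in the vignette).
#' Each matrix entry is the mean pairwise distance across the AC's homolog
#' sets; taxon pairs with no observed distance are imputed with the mean of
#' the observed entries, with a warning.
#'
#' @param hsets Homolog-set rows of a single AC (from
#'   [select_homolog_sets()]).
#' @param ks_pairs Pair-distance table (gene_a, gene_b, ks), e.g. the
#'   simulator's observed Ks or NG86 estimates.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
build_distance_matrix <- function(hsets, ks_pairs) {
  if (nrow(hsets) == 0L)
    stop("insufficient data: no homolog sets", call. = FALSE)
  species <- sort(unique(hsets$species))
  if (length(species) < 2L)
    stop("insufficient data: need homolog sets from >= 2 species",
         call. = FALSE)
  taxa <- as.vector(t(outer(species, 1:2, paste, sep = ".")))
  lut <- setNames(ks_pairs$ks, pair_key(ks_pairs$gene_a, ks_pairs$gene_b))

  hsets$copy <- NA_integer_
  for (sp in species) {
    sel <- hsets$species == sp
    rk <- copy_index_map(hsets[sel, , drop = FALSE])
    srk <- rk[hsets$seg_id[sel]]
    grp <- hsets$ancestral_gene[sel]
    copy <- integer(sum(sel))
    for (g in unique(grp)) {
      ix <- which(grp == g)
      copy[ix] <- ifelse(srk[ix] == min(srk[ix]), 1L, 2L)
    }
    hsets$copy[sel] <- copy
  }
  hsets$taxon <- paste(hsets$species, hsets$copy, sep = ".")

  k <- length(taxa)
  sums <- matrix(0, k, k, dimnames = list(taxa, taxa))
  cnts <- matrix(0, k, k, dimnames = list(taxa, taxa))
  for (g in unique(hsets$ancestral_gene)) {
    sub <- hsets[hsets$ancestral_gene == g, , drop = FALSE]
    n <- nrow(sub)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- unname(lut[pair_key(sub$gene[i], sub$gene[j])])
        if (is.na(d)) next
        ti <- sub$taxon[i]
        tj <- sub$taxon[j]
        sums[ti, tj] <- sums[ti, tj] + d
        cnts[ti, tj] <- cnts[ti, tj] + 1
        sums[tj, ti] <- sums[ti, tj]
        cnts[tj, ti] <- cnts[ti, tj]
      }
    }
  }
  D <- sums / cnts
  diag(D) <- 0
  off <- upper.tri(D)
  if (any(!is.finite(D[off]))) {
    if (!any(is.finite(D[off])))
      stop("insufficient data: no pairwise distances observed", call. = FALSE)
    fill <- mean(D[off][is.finite(D[off])])
    warning(sprintf(
      "%d taxon pair(s) without observed distance imputed with mean %.4g",
      sum(!is.finite(D[off])), fill))
    D[!is.finite(D)] <- fill
    diag(D) <- 0
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via \pkg{ape}); negative branch
#' lengths are clamped to zero. The downstream topology test uses the tree
#' shape only, so any correct distance method could be swapped in behind this
#' contract.
#'
#' @param D Symmetric distance matrix with taxa as dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L)
    stop("insufficient data: neighbor joining needs >= 3 taxa", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12)
    stop("distance matrix must be symmetric", call. = FALSE)
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Classify a duplicate-gene tree as shared versus independent duplication
#'
#' Leaves must be labelled `species.copy` with exactly two leaves per
#' species. For every unordered species pair (X, Y) the tree is restricted
#' to \{X1, X2, Y1, Y2\} and the induced unrooted quartet is read: pairing
#' one copy of X with one copy of Y on each side votes "shared" (the
#' duplication predates the speciation); pairing X's two copies together
#' votes "independent"; a star or zero-length internal edge votes
#' "ambiguous". The final label is the majority of shared versus independent
#' votes (ambiguous votes are never evidence either way); ties give
#' "ambiguous". The vote depends only on topology, not on leaf order,
#' rooting, or branch lengths.
#'
#' @param tree A `phylo` object with `species.copy` tip labels.
#' @param tol Internal edges no longer than this are treated as unresolved
#'   (default 1e-10).
#' @return List with label ("shared", "independent" or "ambiguous"),
#'   quartet_votes (named counts), n_quartets.
#' @examples
#' tr <- ape::read.tree(text = "((A.1,B.1),(A.2,B.2));")
#' classify_topology(tr)$label
#' @export
classify_topology <- function(tree, tol = 1e-10) {
  labs <- tree$tip.label
  sp <- sub("\\.[^.]+$", "", labs)
  tab <- table(sp)
  if (any(tab != 2L))
    stop("labeling error: every species needs exactly two leaves (",
         paste(sprintf("%s has %d", names(tab)[tab != 2L], tab[tab != 2L]),
               collapse = "; "), ")", call. = FALSE)
  species <- sort(names(tab))
  votes <- c(shared = 0L, independent = 0L, ambiguous = 0L)
  for (i in seq_len(length(species) - 1L)) {
    for (j in (i + 1L):length(species)) {
      tips <- labs[sp %in% c(species[i], species[j])]
      v <- quartet_vote(tree, tips, tol)
      votes[v] <- votes[v] + 1L
    }
  }
  label <- if (votes["shared"] > votes["independent"]) "shared"
           else if (votes["independent"] > votes["shared"]) "independent"
           else "ambiguous"
  list(label = label, quartet_votes = votes, n_quartets = sum(votes))
}

# Read the split of one 4-leaf quartet: which two tips form the cherry.
quartet_vote <- function(tree, tips, tol) {
  tr <- ape::unroot(ape::keep.tip(tree, tips))
  nt <- length(tr$tip.label)
  if (tr$Nnode < 2L) return("ambiguous")
  internal <- which(tr$edge[, 1L] > nt & tr$edge[, 2L] > nt)
  if (length(internal) != 1L) return("ambiguous")
  if (!is.null(tr$edge.length) && tr$edge.length[internal] <= tol)
    return("ambiguous")
  cherry_node <- tr$edge[internal, 2L]
  side <- tr$tip.label[tr$edge[tr$edge[, 1L] == cherry_node &
                                 tr$edge[, 2L] <= nt, 2L]]
  sps <- sub("\\.[^.]+$", "", side)
  if (sps[1L] == sps[2L]) "independent" else "shared"
}

#' Per-AC duplication calls over all homolog sets
#'
#' Builds the mean-distance matrix, the neighbor-joining tree and the
#' topology classification for every AC with enough homolog sets.
#'
#' @param hsets Output of [select_homolog_sets()].
#' @param ks_pairs Pair-distance table (gene_a, gene_b, ks).
#' @param min_sets_per_ac Minimum ancestral genes per AC to attempt a call
#'   (default 3; sparser ACs are skipped, mirroring the alignment-length
#'   requirement a sequence-based analysis would impose).
#' @return List with `calls` (tibble: ac, label, shared, independent,
#'   ambiguous, n_genes) and `trees` (named list of `phylo`).
#' @export
duplication_calls <- function(hsets, ks_pairs, min_sets_per_ac = 3L) {
  calls <- list()
  trees <- list()
  for (ac in sort(unique(hsets$ac))) {
    sub <- hsets[hsets$ac == ac, , drop = FALSE]
    n_genes <- length(unique(sub$ancestral_gene))
    if (n_genes < min_sets_per_ac) next
    res <- tryCatch({
      D <- build_distance_matrix(sub, ks_pairs)
      tr <- nj_tree(D)
      cl <- classify_topology(tr)
      list(tree = tr, cl = cl)
    }, error = function(e) NULL)
    if (is.null(res)) next
    trees[[ac]] <- res$tree
    calls[[ac]] <- tibble::tibble(
      ac = ac, label = res$cl$label,
      shared = res$cl$quartet_votes[["shared"]],
      independent = res$cl$quartet_votes[["independent"]],
      ambiguous = res$cl$quartet_votes[["ambiguous"]],
      n_genes = n_genes)
  }
  list(calls = if (length(calls)) dplyr::bind_rows(calls)
       else tibble::tibble(ac = character(0), label = character(0),
                           shared = integer(0), independent = integer(0),
                           ambiguous = integer(0), n_genes = integer(0)),
       trees = trees)
}

#' Aggregate per-AC calls and the Ks peak count into a WGD verdict
#'
#' @param calls Tibble of duplication calls (>= 1 row).
#' @param mode_fits A `ks_mode_fit`, or a named list of them (one per
#'   ingroup species); the peak count used is the modal component count
#'   (ties resolved downwards, i.e. conservatively).
#' @param shared_threshold Minimum shared fraction for a positive verdict
#'   (default 0.5).
#' @param min_modes Minimum Ks peak count for a positive verdict (default 2).
#' @return List: n_calls, label counts, shared_fraction, ks_modes, verdict
#'   (TRUE when shared_fraction > shared_threshold AND ks_modes >=
#'   min_modes), thresholds.
#' @export
aggregate_verdict <- function(calls, mode_fits, shared_threshold = 0.5,
                              min_modes = 2L) {
  if (is.null(calls) || nrow(calls) == 0L)
    stop("need at least one duplication call", call. = FALSE)
  if (inherits(mode_fits, "ks_mode_fit")) mode_fits <- list(mode_fits)
  counts <- vapply(mode_fits, function(f) as.integer(f$n_components),
                   integer(1))
  tabm <- table(counts)
  ks_modes <- min(as.integer(names(tabm)[tabm == max(tabm)]))
  n <- nrow(calls)
  n_shared <- sum(calls$label == "shared")
  shared_fraction <- n_shared / n
  list(n_calls = n,
       labels = c(shared = n_shared,
                  independent = sum(calls$label == "independent"),
                  ambiguous = sum(calls$label == "ambiguous")),
       shared_fraction = shared_fraction,
       ks_modes = ks_modes,
       verdict = shared_fraction > shared_threshold && ks_modes >= min_modes,
       thresholds = list(shared_threshold = shared_threshold,
                         min_modes = as.integer(min_modes)))
}
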