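# Ancestral-chromosome (AC) calibration and macrosynteny segmentation.
# Outgroup proxy genes probe the ingroup genome by unidirectional best hit;
# maximal runs of one AC label become segments; segments of one AC form a
# cluster and are randomly reassembled into AC-coordinate chromosomes.

#' Label ingroup genes with ancestral chromosomes via outgroup proxies
#'
#' Each proxy gene of the ancestral-linkage map picks its single best-scoring
#' ingroup target (unidirectional best hit under the e-value threshold); a
#' target claimed by probes of different ACs takes the AC of the
#' highest-scoring claiming probe (ties: lower e-value, then smaller probe
#' id). Genes hit by no passing probe get `NA`.
#'
#' @param genes Gene table of one species (gene_id, chromosome, ordinal).
#' @param alg_map Proxy map with columns proxy_gene, ac.
#' @param hits Similarity hits containing the proxy-to-ingroup direction.
#' @param evalue_max E-value threshold (default 1e-3).
#' @return Tibble gene_id, ac (NA when unlabeled), one row per gene of
#'   `genes`, in (chromosome, ordinal) order.
#' @export
assign_ac_labels <- function(genes, alg_map, hits, evalue_max = 1e-3) {
  if (is.null(alg_map) || nrow(alg_map) == 0L)
    stop("configuration error: empty ancestral-linkage map", call. = FALSE)
  h <- hits[hits$query %in% alg_map$proxy_gene &
              hits$subject %in% genes$gene_id, , drop = FALSE]
  bh <- best_hits(h, evalue_max)
  lab <- rep(NA_character_, nrow(genes))
  if (nrow(bh) > 0L) {
    bh$ac <- alg_map$ac[match(bh$query, alg_map$proxy_gene)]
    # one label per target: highest-scoring claiming probe wins
    bh <- bh[order(bh$subject, -bh$score, bh$evalue, bh$query), , drop = FALSE]
    bh <- bh[!duplicated(bh$subject), , drop = FALSE]
    lab[match(bh$subject, genes$gene_id)] <- bh$ac
  }
  out <- tibble::tibble(gene_id = genes$gene_id,
                        chromosome = genes$chromosome,
                        ordinal = genes$ordinal, ac = lab)
  out[order(out$chromosome, out$ordinal), c("gene_id", "chromosome",
                                            "ordinal", "ac")]
}

#' Call same-AC segments along one chromosome
#'
#' A segment is a maximal run of genes labelled with one AC, tolerating up to
#' `max_gap` consecutive interloping genes (unlabeled or other-AC) inside the
#' run. Runs with fewer than `min_run` assigned genes are discarded. Segment
#' boundaries are the first and last assigned gene (ordinal coordinates,
#' half-open end); `length` counts assigned genes only. Where candidate runs
#' of different ACs overlap (possible when `max_gap > 0`), runs with more
#' assigned genes win (ties: smaller start, then AC id) and losers are
#' dropped, so segments on a chromosome never overlap.
#'
#' @param labels Character vector of AC labels in ordinal order (NA =
#'   unlabeled), i.e. one chromosome.
#' @param min_run Minimum assigned genes per segment (default 3).
#' @param max_gap Maximum interlopers tolerated inside a run (default 2).
#' @param chromosome,species Metadata attached to the output.
#' @return Tibble species, chromosome, ac, start, end, length, sorted by
#'   start.
#' @examples
#' call_segments(c("1", "1", NA, "1", "1"), min_run = 3, max_gap = 1)
#' @export
call_segments <- function(labels, min_run = 3L, max_gap = 2L,
                          chromosome = "chr", species = "sp") {
  stopifnot(min_run >= 1L, max_gap >= 0L)
  empty <- tibble::tibble(species = character(0), chromosome = character(0),
                          ac = character(0), start = integer(0),
                          end = integer(0), length = integer(0))
  if (length(labels) == 0L) return(empty)
  labels <- as.character(labels)
  cand <- list()
  for (ac in sort(unique(labels[!is.na(labels)]))) {
    pos <- which(labels == ac) - 1L  # 0-based ordinals
    brk <- c(0L, which(diff(pos) > max_gap + 1L), length(pos))
    for (g in seq_len(length(brk) - 1L)) {
      run <- pos[(brk[g] + 1L):brk[g + 1L]]
      if (length(run) >= min_run)
        cand[[length(cand) + 1L]] <-
          list(ac = ac, start = run[1L], end = run[length(run)] + 1L,
               length = length(run))
    }
  }
  if (!length(cand)) return(empty)
  cd <- tibble::tibble(
    ac = vapply(cand, `[[`, character(1), "ac"),
    start = vapply(cand, `[[`, integer(1), "start"),
    end = vapply(cand, `[[`, integer(1), "end"),
    length = vapply(cand, `[[`, integer(1), "length"))
  cd <- cd[order(-cd$length, cd$start, cd$ac), , drop = FALSE]
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (cd$start[i] < cd$end[j] && cd$start[j] < cd$end[i]) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  cd <- cd[keep, , drop = FALSE]
  cd <- cd[order(cd$start), , drop = FALSE]
  tibble::tibble(species = species, chromosome = chromosome, ac = cd$ac,
                 start = cd$start, end = cd$end, length = cd$length)
}

#' Call segments across a whole genome
#'
#' Applies [call_segments()] to every chromosome of a labelled gene table.
#'
#' @param labelled Output of [assign_ac_labels()] (gene_id, chromosome,
#'   ordinal, ac) for one species.
#' @param species Species id attached to the segments.
#' @inheritParams call_segments
#' @return Tibble of segments across all chromosomes.
#' @export
call_segments_genome <- function(labelled, min_run = 3L, max_gap = 2L,
                                 species = "sp") {
  parts <- lapply(sort(unique(labelled$chromosome)), function(ch) {
    sub <- labelled[labelled$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$ordinal), , drop = FALSE]
    call_segments(sub$ac, min_run = min_run, max_gap = max_gap,
                  chromosome = ch, species = species)
  })
  dplyr::bind_rows(parts)
}

#' Group segments by ancestral chromosome
#'
#' @param segments Segment table (from one species or several, caller's
#'   choice; the pipeline clusters per species).
#' @return Named list: one element per AC with at least one segment, each a
#'   segment tibble.
#' @export
cluster_segments <- function(segments) {
  if (nrow(segments) == 0L) return(list())
  out <- split(segments, segments$ac)
  out[order(names(out))]
}

#' Randomly reassemble cluster segments into AC-coordinate chromosomes
#'
#' Per cluster, member segments (gene runs \[start, end) on their source
#' chromosomes) are concatenated in a seeded random order into one
#' reorganized chromosome named after the AC. Gene content is conserved;
#' ordinals are renumbered from 0. Downstream logic must not depend on the
#' intra-cluster order.
#'
#' @param clusters Named list from [cluster_segments()] (one species).
#' @param genes Gene table of that species.
#' @param seed Seed for the segment order.
#' @return Tibble gene_id, chromosome (the AC id), ordinal.
#' @export
reassemble_chromosomes <- function(clusters, genes, seed = 1L) {
  if (!length(clusters))
    return(tibble::tibble(gene_id = character(0), chromosome = character(0),
                          ordinal = integer(0)))
  with_rng(substream_seed(seed, "reassemble"), {
    parts <- lapply(names(clusters), function(ac) {
      seg <- clusters[[ac]]
      ord <- sample.int(nrow(seg))
      ids <- unlist(lapply(ord, function(i) {
        sub <- genes[genes$chromosome == seg$chromosome[i] &
                       genes$ordinal >= seg$start[i] &
                       genes$ordinal < seg$end[i], , drop = FALSE]
        sub$gene_id[order(sub$ordinal)]
      }), use.names = FALSE)
      tibble::tibble(gene_id = ids, chromosome = ac,
                     ordinal = seq_along(ids) - 1L)
    })
    dplyr::bind_rows(parts)
  })
}

#' Oxford-grid table of a reorganized genome against the ACs
#'
#' One row per labelled gene of the reorganized genome: its position in
#' AC-coordinate space versus the position of its best claiming proxy gene
#' within the AC. Suitable for dot-plot (Oxford grid) validation of the
#' chromosome reconstruction.
#'
#' @param reorg Reorganized gene table from [reassemble_chromosomes()].
#' @param alg_map Proxy map (proxy_gene, ac, optional ac_ordinal; without
#'   ac_ordinal proxies are ranked by id within each AC).
#' @param hits Similarity hits (proxy-to-ingroup direction).
#' @param evalue_max E-value threshold (default 1e-3).
#' @return Tibble chromosome, ordinal, ac, ac_ordinal, gene_id, proxy_gene,
#'   deterministic (chromosome, ordinal) order; unlabeled genes absent.
#' @export
dotplot_table <- function(reorg, alg_map, hits, evalue_max = 1e-3) {
  empty <- tibble::tibble(chromosome = character(0), ordinal = integer(0),
                          ac = character(0), ac_ordinal = integer(0),
                          gene_id = character(0), proxy_gene = character(0))
  if (nrow(reorg) == 0L) return(empty)
  if (!"ac_ordinal" %in% names(alg_map)) {
    alg_map <- alg_map[order(alg_map$ac, alg_map$proxy_gene), , drop = FALSE]
    alg_map$ac_ordinal <- stats::ave(seq_len(nrow(alg_map)), alg_map$ac,
                                     FUN = seq_along) - 1L
  }
  h <- hits[hits$query %in% alg_map$proxy_gene &
              hits$subject %in% reorg$gene_id, , drop = FALSE]
  bh <- best_hits(h, evalue_max)
  if (nrow(bh) == 0L) return(empty)
  bh <- bh[order(bh$subject, -bh$score, bh$evalue, bh$query), , drop = FALSE]
  bh <- bh[!duplicated(bh$subject), , drop = FALSE]
  m <- match(bh$subject, reorg$gene_id)
  am <- match(bh$query, alg_map$proxy_gene)
  out <- tibble::tibble(chromosome = reorg$chromosome[m],
                        ordinal = reorg$ordinal[m],
                        ac = alg_map$ac[am],
                        ac_ordinal = alg_map$ac_ordinal[am],
                        gene_id = bh$subject, proxy_gene = bh$query)
  out[order(out$chromosome, out$ordinal), , drop = FALSE]
}
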