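# AC labeling, segment calling, clustering, reassembly and dot plots.

test_that("segment calling matches the stated rule on hand-worked examples", {
  s1 <- call_segments(c(1, 1, 1, 1, 2, 2, 2, 1, 1), min_run = 3, max_gap = 0)
  expect_equal(s1$ac, c("1", "2"))
  expect_equal(s1$start, c(0L, 4L))
  expect_equal(s1$end, c(4L, 7L))
  expect_equal(s1$length, c(4L, 3L))

  s2 <- call_segments(c("1", "1", NA, "1", "1"), min_run = 3, max_gap = 1)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$start, 0L)
  expect_equal(s2$end, 5L)
  expect_equal(s2$length, 4L)

  expect_equal(nrow(call_segments(character(0))), 0L)
})

test_that("segment calling agrees with the scan oracle on enumerated label strings", {
  # exhaustive over short strings, random over longer ones, several settings
  alph <- c("A", "B", NA)
  combos <- list(c(2L, 0L), c(2L, 1L), c(3L, 2L), c(1L, 0L))
  for (len in 1:5) {
    grid <- do.call(expand.grid, c(rep(list(alph), len),
                                   stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grid))) {
      labels <- as.character(unlist(grid[r, ]))
      for (cmb in combos) {
        got <- call_segments(labels, min_run = cmb[1], max_gap = cmb[2])
        want <- oracle_segments(labels, min_run = cmb[1], max_gap = cmb[2])
        expect_equal(nrow(got), nrow(want))
        if (nrow(got)) {
          expect_equal(got$ac, want$ac)
          expect_equal(got$start, want$start)
          expect_equal(got$end, want$end)
          expect_equal(got$length, want$length)
        }
      }
    }
  }
  set.seed(61)
  for (i in 1:300) {
    labels <- random_label_string(sample(6:12, 1), acs = c("A", "B", "C"))
    cmb <- combos[[sample.int(length(combos), 1)]]
    got <- call_segments(labels, min_run = cmb[1], max_gap = cmb[2])
    want <- oracle_segments(labels, min_run = cmb[1], max_gap = cmb[2])
    expect_equal(got$ac, want$ac)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$length, want$length)
  }
})

test_that("segment calling is idempotent-safe: non-overlap and bounded lengths", {
  set.seed(62)
  for (i in 1:50) {
    labels <- random_label_string(20, p_na = 0.4, acs = c("A", "B", "C"))
    seg <- call_segments(labels, min_run = 2, max_gap = 2)
    if (nrow(seg) < 2L) next
    seg <- seg[order(seg$start), ]
    expect_true(all(seg$end[-nrow(seg)] <= seg$start[-1]))
    expect_true(all(seg$length <= seg$end - seg$start))
    expect_lte(sum(seg$length), length(labels))
  }
})

test_that("AC labels recover the true ancestral chromosome on an unrearranged genome", {
  sim <- fixture_env$norr_sim
  if (is.null(sim)) {
    sim <- simulate_dataset(sim_config(
      n_anc_chromosomes = 4L, genes_per_chromosome = 50L,
      bg_dup_rate = 0, loss_rate = 0, fission_rate = 0, fusion_rate = 0,
      seed = 23L))
    fixture_env$norr_sim <- sim
  }
  ga <- sim$genes[sim$genes$species == "A", ]
  lab <- assign_ac_labels(ga, sim$alg_map, sim$hits)
  labelled <- lab[!is.na(lab$ac), ]
  expect_gt(nrow(labelled), 0.3 * nrow(ga))
  truth <- true_ac(ga, 50L)[match(labelled$gene_id, ga$gene_id)]
  expect_gte(mean(labelled$ac == truth), 0.99)
  # unlabeled genes exist (probes pick one copy) and map to NA, not junk
  expect_true(anyNA(lab$ac))
  expect_error(assign_ac_labels(ga, sim$alg_map[0, ], sim$hits),
               "configuration error")
})

test_that("clusters group segments by AC and clean WGD genomes give two segments per AC", {
  seg <- tibble::tibble(species = "S", chromosome = c("c1", "c2", "c3"),
                        ac = c("AC1", "AC1", "AC2"),
                        start = c(0L, 0L, 0L), end = c(5L, 4L, 6L),
                        length = c(5L, 4L, 6L))
  cl <- cluster_segments(seg)
  expect_named(cl, c("AC1", "AC2"))
  expect_equal(nrow(cl$AC1), 2L)
  expect_equal(length(cluster_segments(seg[0, ])), 0L)

  sim <- fixture_env$norr_sim
  ga <- sim$genes[sim$genes$species == "A", ]
  lab <- assign_ac_labels(ga, sim$alg_map, sim$hits)
  segs <- call_segments_genome(lab, species = "A")
  cl <- cluster_segments(segs)
  n2 <- vapply(cl, nrow, integer(1))
  expect_gte(mean(n2 >= 2L), 0.95)
  # fission-free world: every segment is pure for one true AC
  for (ac in names(cl)) {
    for (i in seq_len(nrow(cl[[ac]]))) {
      s <- cl[[ac]][i, ]
      sub <- ga[ga$chromosome == s$chromosome & ga$ordinal >= s$start &
                  ga$ordinal < s$end, ]
      expect_equal(unique(true_ac(sub, 50L)), ac)
    }
  }
})

test_that("reassembly conserves gene content regardless of seed", {
  sim <- fixture_env$norr_sim
  ga <- sim$genes[sim$genes$species == "A", ]
  lab <- assign_ac_labels(ga, sim$alg_map, sim$hits)
  segs <- call_segments_genome(lab, species = "A")
  cl <- cluster_segments(segs)
  r1 <- reassemble_chromosomes(cl, ga, seed = 1)
  r2 <- reassemble_chromosomes(cl, ga, seed = 2)
  expect_equal(sort(r1$gene_id), sort(r2$gene_id))
  expect_equal(nrow(r1), sum(segs$end - segs$start))
  for (ac in names(cl)) {
    expect_setequal(r1$gene_id[r1$chromosome == ac],
                    r2$gene_id[r2$chromosome == ac])
    n <- sum(r1$chromosome == ac)
    expect_equal(sort(r1$ordinal[r1$chromosome == ac]), seq_len(n) - 1L)
  }
  # single-segment cluster reproduces the segment's gene run exactly
  single <- names(cl)[vapply(cl, nrow, integer(1)) == 1L]
  if (length(single)) {
    ac <- single[1]
    s <- cl[[ac]]
    run <- ga[ga$chromosome == s$chromosome & ga$ordinal >= s$start &
                ga$ordinal < s$end, ]
    expect_equal(r1$gene_id[r1$chromosome == ac],
                 run$gene_id[order(run$ordinal)])
  }
})

test_that("dot plots of a collinear genome are monotone per chromosome", {
  # no WGD and no rearrangement: one segment per AC, perfectly collinear
  sim <- simulate_dataset(sim_config(
    wgd_node = NULL, n_anc_chromosomes = 3L, genes_per_chromosome = 40L,
    bg_dup_rate = 0, loss_rate = 0, fission_rate = 0, fusion_rate = 0,
    seed = 29L))
  ga <- sim$genes[sim$genes$species == "A", ]
  lab <- assign_ac_labels(ga, sim$alg_map, sim$hits)
  segs <- call_segments_genome(lab, species = "A")
  reorg <- reassemble_chromosomes(cluster_segments(segs), ga, seed = 3)
  dot <- dotplot_table(reorg, sim$alg_map, sim$hits)
  expect_gt(nrow(dot), 0L)
  for (ch in unique(dot$chromosome)) {
    sub <- dot[dot$chromosome == ch, ]
    expect_equal(unique(sub$ac), ch)
    rho <- suppressWarnings(cor(sub$ordinal, sub$ac_ordinal,
                                method = "spearman"))
    expect_equal(abs(rho), 1)
  }
  expect_equal(nrow(dotplot_table(reorg[0, ], sim$alg_map, sim$hits)), 0L)
})
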