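# Homolog selection, distance matrices, NJ trees, quartet classification,
# and verdict aggregation.

# A hand-built species X: AC1 has three segments of lengths 5, 4, 3.
selection_fixture <- function() {
  genes <- tibble::tibble(
    gene_id = c(sprintf("x1%s", letters[1:6]), sprintf("x2%s", letters[1:4]),
                sprintf("x3%s", letters[1:3])),
    species = "X",
    chromosome = rep(c("chrX1", "chrX2", "chrX3"), c(6L, 4L, 3L)),
    ordinal = c(0:5, 0:3, 0:2))
  segments <- tibble::tibble(
    species = "X",
    chromosome = c("chrX1", "chrX2", "chrX3"),
    ac = "AC1",
    start = c(0L, 0L, 0L), end = c(5L, 4L, 3L), length = c(5L, 4L, 3L))
  alg_map <- tibble::tibble(proxy_gene = c("p1", "p2", "p3"), ac = "AC1")
  hit <- function(q, s, sc) tibble::tibble(query = c(q, s), subject = c(s, q),
                                           score = sc, evalue = 1e-9)
  hits <- dplyr::bind_rows(
    hit("p1", "x1a", 90), hit("p1", "x2a", 80), hit("p1", "x3a", 70),
    hit("p2", "x1b", 85),
    hit("p3", "x1c", 88), hit("p3", "x2b", 84))
  list(genes = genes, segments = segments, alg_map = alg_map, hits = hits)
}

test_that("the exactly-two / two-longest-segments selection rule holds", {
  fx <- selection_fixture()
  hs <- select_homolog_sets(fx$segments, fx$genes, fx$hits, fx$alg_map,
                            ingroup = "X")
  # p1 had homologs on three segments: the 5- and 4-long ones are chosen
  p1 <- hs[hs$ancestral_gene == "p1", ]
  expect_equal(sort(p1$gene), c("x1a", "x2a"))
  expect_equal(sort(p1$seg_length), c(4L, 5L))
  # p2 had a homolog on a single segment: rejected
  expect_false("p2" %in% hs$ancestral_gene)
  # p3 had exactly two: both kept
  p3 <- hs[hs$ancestral_gene == "p3", ]
  expect_equal(sort(p3$gene), c("x1c", "x2b"))
  # never two homologs from one segment
  expect_equal(nrow(unique(hs[c("ancestral_gene", "seg_id")])), nrow(hs))
})

test_that("selection intersects ancestral genes across all ingroup species", {
  fx <- selection_fixture()
  # species Y passes only p3
  genes_y <- tibble::tibble(gene_id = c("y1a", "y1b", "y1c", "y2a", "y2b"),
                            species = "Y",
                            chromosome = rep(c("chrY1", "chrY2"), c(3L, 2L)),
                            ordinal = c(0:2, 0:1))
  segs_y <- tibble::tibble(species = "Y", chromosome = c("chrY1", "chrY2"),
                           ac = "AC1", start = 0L, end = c(3L, 2L),
                           length = c(3L, 2L))
  hit <- function(q, s, sc) tibble::tibble(query = c(q, s), subject = c(s, q),
                                           score = sc, evalue = 1e-9)
  hits <- dplyr::bind_rows(fx$hits,
                           hit("p3", "y1a", 77), hit("p3", "y2a", 75),
                           hit("p1", "y1b", 60))
  hs <- select_homolog_sets(dplyr::bind_rows(fx$segments, segs_y),
                            dplyr::bind_rows(fx$genes, genes_y),
                            hits, fx$alg_map, ingroup = c("X", "Y"))
  expect_equal(unique(hs$ancestral_gene), "p3")
  expect_equal(nrow(hs), 4L)
  expect_setequal(hs$gene[hs$species == "Y"], c("y1a", "y2a"))
})

test_that("distance matrices average homolog-set distances per taxon pair", {
  hs <- tibble::tibble(
    ancestral_gene = rep(c("p1", "p2"), each = 4L),
    ac = "AC1",
    species = rep(rep(c("X", "Y"), each = 2L), 2L),
    gene = c("x1", "x2", "y1", "y2", "x3", "x4", "y3", "y4"),
    seg_id = rep(c("sx1", "sx2", "sy1", "sy2"), 2L),
    chromosome = rep(c("cx1", "cx2", "cy1", "cy2"), 2L),
    seg_start = 0L,
    seg_length = rep(c(9L, 5L, 8L, 6L), 2L))
  ks <- tibble::tibble(
    gene_a = c("x1", "x1", "x1", "x2", "x2", "y1",
               "x3", "x3", "x3", "x4", "x4", "y3"),
    gene_b = c("x2", "y1", "y2", "y1", "y2", "y2",
               "x4", "y3", "y4", "y3", "y4", "y4"),
    ks = c(0.9, 0.2, 0.8, 0.85, 0.3, 0.95,
           1.1, 0.4, 1.0, 1.05, 0.5, 1.05))
  D <- build_distance_matrix(hs, ks)
  expect_equal(dim(D), c(4L, 4L))
  expect_true(all(abs(D - t(D)) < 1e-12))
  expect_equal(unname(diag(D)), rep(0, 4))
  # copy 1 = longer segment; X.1-Y.1 entries were 0.2 and 0.4
  expect_equal(D["X.1", "Y.1"], 0.3)
  expect_equal(D["X.2", "Y.2"], mean(c(0.3, 0.5)))
  expect_equal(D["X.1", "X.2"], mean(c(0.9, 1.1)))

  # a single homolog set is valid and reproduces its pairwise distances
  D1 <- build_distance_matrix(hs[hs$ancestral_gene == "p1", ], ks)
  expect_equal(D1["X.1", "Y.1"], 0.2)
  expect_equal(D1["X.2", "Y.2"], 0.3)

  expect_error(build_distance_matrix(hs[0, ], ks), "insufficient data")
  expect_error(build_distance_matrix(hs[hs$species == "X", ], ks),
               "insufficient data")
  # a taxon pair with no observed distance at all is imputed with a warning
  expect_warning(build_distance_matrix(hs, ks[-c(2, 8), ]), "imputed")
})

test_that("neighbor joining: three-point formulas and the four-point split", {
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D3)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))

  D4 <- matrix(4, 4, 4)
  D4[1, 2] <- D4[2, 1] <- 2
  D4[3, 4] <- D4[4, 3] <- 2
  diag(D4) <- 0
  dimnames(D4) <- list(c("A.1", "B.1", "A.2", "B.2"),
                       c("A.1", "B.1", "A.2", "B.2"))
  tr4 <- nj_tree(D4)
  # the split pairs A.1+B.1 against A.2+B.2: read through the quartet vote
  expect_equal(classify_topology(tr4)$label, "shared")

  expect_error(nj_tree(D3[1:2, 1:2]), "insufficient data")
})

test_that("NJ recovers the generating topology of random additive matrices", {
  set.seed(71)
  for (i in 1:20) {
    tr <- ape::rtree(6L)
    tr$edge.length <- runif(length(tr$edge.length), 0.2, 1.5)
    D <- ape::cophenetic.phylo(tr)
    got <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(got)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("quartet topologies classify as shared / independent / ambiguous", {
  sh <- ape::read.tree(text = "((A.1,B.1),(A.2,B.2));")
  expect_equal(classify_topology(sh)$label, "shared")
  ind <- ape::read.tree(text = "((A.1,A.2),(B.1,B.2));")
  expect_equal(classify_topology(ind)$label, "independent")

  tri <- ape::read.tree(text = "((A.1,(B.1,C.1)),(A.2,(B.2,C.2)));")
  out <- classify_topology(tri)
  expect_equal(out$label, "shared")
  expect_equal(unname(out$quartet_votes["shared"]), 3L)
  expect_equal(out$n_quartets, 3L)

  # zero-length internal edge: unresolved, evidence for neither hypothesis
  amb <- ape::read.tree(text = "((A.1,B.1):0.0,A.2,B.2);")
  expect_equal(classify_topology(amb)$label, "ambiguous")

  bad <- ape::read.tree(text = "((A.1,B.1),(A.2,(B.2,C.1)));")
  expect_error(classify_topology(bad), "labeling error")
})

test_that("classification is invariant to leaf order, rooting and branch lengths", {
  base <- ape::read.tree(text = "((A.1,(B.1,C.1)),(A.2,(B.2,C.2)));")
  variants <- list(
    ape::read.tree(text = "((C.2,B.2),(A.2,((C.1,B.1),A.1)));"),
    ape::root(base, outgroup = "B.2", resolve.root = TRUE),
    ape::unroot(base))
  set.seed(72)
  wl <- base
  wl$edge.length <- runif(nrow(wl$edge), 0.1, 2)
  variants <- c(variants, list(wl))
  for (v in variants) {
    expect_equal(classify_topology(v)$label, "shared")
    expect_equal(unname(classify_topology(v)$quartet_votes["shared"]), 3L)
  }
})

test_that("verdict aggregation combines topology calls with the Ks peak count", {
  calls <- tibble::tibble(ac = sprintf("AC%02d", 1:19),
                          label = c(rep("shared", 17), "independent",
                                    "ambiguous"),
                          shared = 3L, independent = 0L, ambiguous = 0L,
                          n_genes = 10L)
  fit2 <- structure(list(n_components = 2L), class = "ks_mode_fit")
  v <- aggregate_verdict(calls, fit2)
  expect_true(v$verdict)
  expect_equal(v$shared_fraction, 17 / 19, tolerance = 1e-12)
  expect_equal(unname(v$labels["shared"]), 17L)

  calls0 <- tibble::tibble(ac = sprintf("AC%02d", 1:10),
                           label = rep("independent", 10),
                           shared = 0L, independent = 3L, ambiguous = 0L,
                           n_genes = 5L)
  fit1 <- structure(list(n_components = 1L), class = "ks_mode_fit")
  expect_false(aggregate_verdict(calls0, fit1)$verdict)
  # two peaks but no shared topologies is still no shared WGD
  expect_false(aggregate_verdict(calls0, fit2)$verdict)
  # modal peak count across species, ties resolved conservatively
  v2 <- aggregate_verdict(calls, list(A = fit1, B = fit2))
  expect_equal(v2$ks_modes, 1L)
  expect_false(v2$verdict)
  expect_error(aggregate_verdict(calls[0, ], fit2), "at least one")
})

test_that("a clean shared-WGD world yields shared calls and subgenome-consistent distances", {
  sim <- clean_wgd_sim()
  genes <- sim$genes
  segs <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(sp) {
    gsp <- genes[genes$species == sp, ]
    lab <- assign_ac_labels(gsp, sim$alg_map, sim$hits)
    call_segments_genome(lab, species = sp)
  }))
  hs <- select_homolog_sets(segs, genes, sim$hits, sim$alg_map,
                            ingroup = c("A", "B", "C"))
  expect_gte(length(unique(hs$ancestral_gene)), 3L)
  ks <- sim$ks_pairs[, c("gene_a", "gene_b", "ks")]
  dup <- duplication_calls(hs, ks, min_sets_per_ac = 2L)
  expect_gt(nrow(dup$calls), 0L)
  expect_true(all(dup$calls$label == "shared"))
  # four-point check: copy indices are species-local, so one of the two
  # cross-species pairings follows the subgenomes and must beat the
  # within-species pairing (the WGD distance)
  for (ac in dup$calls$ac) {
    D <- suppressWarnings(build_distance_matrix(hs[hs$ac == ac, ], ks))
    cross <- min(D["A.1", "B.1"] + D["A.2", "B.2"],
                 D["A.1", "B.2"] + D["A.2", "B.1"])
    expect_lt(cross, D["A.1", "A.2"] + D["B.1", "B.2"])
  }
})
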