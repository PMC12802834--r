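# Simulator: config validation, copy-number laws, karyotype events,
# divergence model, determinism.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(retention = 1.2), "retention")
  expect_error(sim_config(bg_dup_rate = -1), "bg_dup_rate")
  expect_error(sim_config(wgd_time = 1.5), "wgd_time")
  expect_error(sim_config(wgd_node = "NOPE"), "wgd_node")
  expect_error(sim_config(outgroup = "Z"), "outgroup")
  expect_error(sim_config(n_anc_chromosomes = 0), "n_anc_chromosomes")
  expect_error(sim_config(ks_rate = 0), "ks_rate")
  # a WGD branch covering the outgroup is inconsistent
  expect_error(sim_config(wgd_node = "ROOT"), "wgd_node")
})

test_that("without any duplication process every family is single-copy everywhere", {
  sim <- simulate_dataset(sim_config(
    wgd_node = NULL, bg_dup_rate = 0, loss_rate = 0,
    n_anc_chromosomes = 2L, genes_per_chromosome = 25L, seed = 5L))
  counts <- table(sim$genes$family, sim$genes$species)
  expect_true(all(counts == 1L))
  expect_equal(nrow(sim$genes), 4L * 50L)
})

test_that("retention 1 with no turnover gives exactly two ingroup copies and one outgroup copy", {
  sim <- simulate_dataset(clean_wgd_config(seed = 11L))
  counts <- as.data.frame(table(sim$genes$family, sim$genes$species))
  for (sp in c("A", "B", "C")) {
    expect_true(all(counts$Freq[counts$Var2 == sp] == 2L), info = sp)
  }
  expect_true(all(counts$Freq[counts$Var2 == "OUT"] == 1L))
  # WGD copies start on distinct chromosomes (inter-chromosomal by design)
  ga <- sim$genes[sim$genes$species == "A", ]
  by_fam <- split(ga$chromosome, ga$family)
  expect_true(all(vapply(by_fam, function(ch) length(unique(ch)) == 2L,
                         logical(1))))
})

test_that("two-copy ingroup family count is Binomial(n_anc, retention)", {
  # closed-form oracle: mean n*p, sd sqrt(n*p*(1-p)); 3 sigma band
  cfg <- sim_config(n_anc_chromosomes = 10L, genes_per_chromosome = 200L,
                    retention = 0.4, bg_dup_rate = 0, loss_rate = 0,
                    seed = 99L)
  sim <- simulate_dataset(cfg)
  ga <- sim$genes[sim$genes$species == "A", ]
  n2 <- sum(table(ga$family) == 2L)
  mu <- 2000 * 0.4
  sig <- sqrt(2000 * 0.4 * 0.6)
  expect_gt(n2, mu - 3 * sig)
  expect_lt(n2, mu + 3 * sig)
})

test_that("karyotype events: zero rates are the identity, fission splits as stated", {
  g <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                      chromosome = "chr1", ordinal = 0:9)
  expect_identical(apply_karyotype_events(g, 0, 0, 10, seed = 1L), g)

  # force exactly one fission and locate its boundary
  set.seed(0)
  found <- FALSE
  for (s in 1:50) {
    out <- apply_karyotype_events(g, fission_rate = 0.2, fusion_rate = 0,
                                  duration = 1, seed = s)
    k <- length(unique(out$chromosome))
    if (k == 2L) {
      sizes <- as.integer(table(out$chromosome))
      expect_equal(sum(sizes), 10L)
      for (ch in unique(out$chromosome)) {
        sub <- out[out$chromosome == ch, ]
        expect_equal(sort(sub$ordinal), seq_len(nrow(sub)) - 1L)
      }
      # gene order preserved within fragments
      expect_equal(out$gene_id[order(out$chromosome, out$ordinal)][1:4][1],
                   "g01")
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("chromosome count grows by fission_rate * duration on average", {
  # Poisson-count oracle over >= 200 seeded replicates, 3 standard errors
  g <- tibble::tibble(gene_id = sprintf("g%03d", 1:60),
                      chromosome = rep(c("c1", "c2"), each = 30L),
                      ordinal = rep(0:29, 2L))
  n <- vapply(1:200, function(s) {
    out <- apply_karyotype_events(g, fission_rate = 1, fusion_rate = 0,
                                  duration = 2, seed = s)
    length(unique(out$chromosome))
  }, numeric(1))
  expect_equal(unique(vapply(1:5, function(s) {
    sum(table(apply_karyotype_events(g, 1, 0, 2, seed = s)$chromosome))
  }, numeric(1))), 60)  # conservation under fission
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - (2 + 1 * 2)), 3 * se + 1e-9)
})

test_that("fusions conserve gene content and concatenate end-to-start", {
  g <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                      chromosome = rep(c("c1", "c2"), each = 6L),
                      ordinal = rep(0:5, 2L))
  for (s in 1:20) {
    out <- apply_karyotype_events(g, fission_rate = 0, fusion_rate = 3,
                                  duration = 1, seed = s)
    expect_setequal(out$gene_id, g$gene_id)
    if (length(unique(out$chromosome)) == 1L) {
      expect_equal(sort(out$ordinal), 0:11)
      # each source chromosome's internal order is intact
      o1 <- out$ordinal[match(sprintf("g%02d", 1:6), out$gene_id)]
      expect_true(all(diff(o1) == 1L))
      break
    }
  }
})

test_that("WGD pair divergence equals 2 * ks_rate * time since WGD", {
  sim <- clean_wgd_sim()
  expected <- expected_wgd_ks(sim$config)
  ga <- sim$genes[sim$genes$species == "A", ]
  fams <- split(ga$gene_id, ga$family)
  kp <- sim$ks_pairs
  for (f in names(fams)[1:10]) {
    pair <- sort(fams[[f]])
    row <- kp[kp$gene_a == pair[1] & kp$gene_b == pair[2], ]
    expect_equal(row$ks_true, expected, tolerance = 1e-12)
  }
  expect_equal(sim$truth$wgd$expected_ks, expected, tolerance = 1e-12)
})

test_that("observed Ks is lognormal around truth with the configured log-sd", {
  # moment recovery on >= 1e4 pairs
  sim <- fixture_env$moment_sim
  if (is.null(sim)) {
    sim <- simulate_dataset(sim_config(
      n_anc_chromosomes = 10L, genes_per_chromosome = 150L,
      retention = 1, bg_dup_rate = 0, loss_rate = 0,
      ks_log_noise_sd = 0.25, seed = 13L))
    fixture_env$moment_sim <- sim
  }
  kp <- sim$ks_pairs
  expect_gt(nrow(kp), 1e4)
  lr <- log(kp$ks) - log(kp$ks_true)
  expect_lt(abs(mean(lr)), 3 * 0.25 / sqrt(nrow(kp)))
  expect_equal(sd(lr), 0.25, tolerance = 0.02)
})

test_that("hits cover exactly the same-family pairs, scores fall with divergence", {
  sim <- small_wgd_sim()
  fam <- setNames(sim$genes$family, sim$genes$gene_id)
  expect_true(all(fam[sim$hits$query] == fam[sim$hits$subject]))
  expect_true(all(sim$hits$query != sim$hits$subject))
  # both directions present
  key <- paste(sim$hits$query, sim$hits$subject)
  rev <- paste(sim$hits$subject, sim$hits$query)
  expect_true(all(rev %in% key))
  # score = s0 * exp(-lambda * ks_obs), evalue = 10^(-score/10)
  m <- match(paste(sim$ks_pairs$gene_a, sim$ks_pairs$gene_b),
             paste(sim$hits$query, sim$hits$subject))
  expect_equal(sim$hits$score[m], 200 * exp(-sim$ks_pairs$ks),
               tolerance = 1e-12)
  expect_equal(sim$hits$evalue[m], 10^(-sim$hits$score[m] / 10),
               tolerance = 1e-12)
})

test_that("gene count changes only through logged dup/loss events", {
  sim <- small_wgd_sim()
  ev <- sim$truth$event_log
  for (sp in c("A", "B", "C")) {
    lineages <- c("ING", sp, if (sp %in% c("B", "C")) "BC")
    sub <- ev[ev$lineage %in% lineages, ]
    n_wgd_retained <- sum(as.integer(sub("retained=", "",
                                         sub$detail[sub$event == "wgd"])))
    expected <- 4L * 30L + n_wgd_retained +
      sum(sub$event == "dup") - sum(sub$event == "loss")
    expect_equal(sum(sim$genes$species == sp), expected, info = sp)
  }
})

test_that("identical (config, seed) reproduces identical datasets, different seeds differ", {
  cfg <- sim_config(n_anc_chromosomes = 2L, genes_per_chromosome = 20L,
                    seed = 3L)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$hits, s2$hits)
  expect_identical(s1$ks_pairs, s2$ks_pairs)
  cfg$seed <- 4L
  s3 <- simulate_dataset(cfg)
  expect_false(identical(s1$ks_pairs$ks, s3$ks_pairs$ks))
})
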