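# End-to-end orchestration: simulate/load -> per-species paralog RBH + Ks
# modes -> AC calibration and segmentation -> homolog selection -> per-AC
# trees -> verdict. One global seed; stage-local substreams are derived from
# stage names so re-running a stage reproduces in-pipeline behaviour.

#' Pipeline configuration
#'
#' Exactly one input source must be active: the `sim` block (simulate mode)
#' or `input_dir`, a directory of dataset files in the formats of
#' [write_dataset()] (gene tables, BLAST-tabular hits, an ALG proxy map, and
#' a pair-Ks table and/or CDS FASTA).
#'
#' @param sim A [sim_config()] for simulate mode, or `NULL`.
#' @param input_dir Dataset directory for file mode, or `NULL`.
#' @param outgroup Outgroup species id (file mode; simulate mode takes it
#'   from `sim`).
#' @param ingroup Ingroup species ids; default: every species except the
#'   outgroup.
#' @param evalue_max E-value threshold for all best-hit computations.
#' @param min_run,max_gap Segment-calling parameters ([call_segments()]).
#' @param k_max,weight_floor,ks_min,ks_max Ks mixture parameters
#'   ([fit_ks_modes()]).
#' @param min_sets_per_ac Minimum homolog sets for a per-AC call.
#' @param shared_threshold,min_modes Verdict thresholds
#'   ([aggregate_verdict()]).
#' @param seed Global pipeline seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            outgroup = NULL, ingroup = NULL,
                            evalue_max = 1e-3, min_run = 3L, max_gap = 2L,
                            k_max = 4L, weight_floor = 0.05,
                            ks_min = 0.05, ks_max = 5,
                            min_sets_per_ac = 3L,
                            shared_threshold = 0.5, min_modes = 2L,
                            seed = 1L) {
  if (is.null(sim) == is.null(input_dir))
    stop("exactly one of `sim` and `input_dir` must be set", call. = FALSE)
  if (!is.null(sim)) {
    validate_sim_config(sim)
    outgroup <- outgroup %||% sim$outgroup
  } else {
    if (!dir.exists(input_dir))
      stop("input_dir does not exist: ", input_dir, call. = FALSE)
    if (is.null(outgroup))
      stop("file mode requires `outgroup`", call. = FALSE)
  }
  structure(list(sim = sim, input_dir = input_dir, outgroup = outgroup,
                 ingroup = ingroup, evalue_max = evalue_max,
                 min_run = as.integer(min_run), max_gap = as.integer(max_gap),
                 k_max = as.integer(k_max), weight_floor = weight_floor,
                 ks_min = ks_min, ks_max = ks_max,
                 min_sets_per_ac = as.integer(min_sets_per_ac),
                 shared_threshold = shared_threshold,
                 min_modes = as.integer(min_modes),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Resolve a Ks source: a lookup into a precomputed pair table, falling back
# to NG86 on CDS when only sequences are available.
make_ks_source <- function(ks_pairs, cds) {
  if (!is.null(ks_pairs)) {
    lut <- setNames(ks_pairs$ks, pair_key(ks_pairs$gene_a, ks_pairs$gene_b))
    function(pairs) unname(lut[pair_key(pairs$gene_a, pairs$gene_b)])
  } else if (!is.null(cds)) {
    cache <- new.env(parent = emptyenv())
    function(pairs) {
      vapply(seq_len(nrow(pairs)), function(i) {
        key <- pair_key(pairs$gene_a[i], pairs$gene_b[i])
        hit <- cache[[key]]
        if (!is.null(hit)) return(hit)
        val <- ng86_ks_pairs(pairs[i, , drop = FALSE], cds)$ks
        cache[[key]] <- val
        val
      }, numeric(1))
    }
  } else {
    stop("no Ks source: provide ks_pairs.tsv or cds.fasta", call. = FALSE)
  }
}

#' Run the full WGD-detection pipeline
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory; when given, every stage output is
#'   written there (TSV/Newick/JSON) together with `report.json`,
#'   `manifest.json` and a `run.log` echoing every threshold and seed.
#' @param quiet Suppress progress messages.
#' @return The report, an object of class `wgd_report` (a nested list; see
#'   the vignette for the schema). Returned invisibly when `out_dir` is set.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim = sim_config(n_anc_chromosomes = 4,
#'                                         genes_per_chromosome = 40))
#' rep <- run_pipeline(cfg, quiet = TRUE)
#' rep$verdict
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  notes <- character(0)

  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    say("simulate: %d x %d ancestral genes, seed %d",
        sim_cfg$n_anc_chromosomes, sim_cfg$genes_per_chromosome, config$seed)
    data <- simulate_dataset(sim_cfg)
  } else {
    say("load: %s", config$input_dir)
    data <- read_dataset(config$input_dir)
    if (is.null(data$alg_map))
      stop("input_dir lacks alg_map.tsv", call. = FALSE)
  }
  genes <- data$genes
  hits <- data$hits
  species <- sort(unique(genes$species))
  outgroup <- config$outgroup
  if (!outgroup %in% species)
    stop("outgroup ", outgroup, " absent from gene tables", call. = FALSE)
  ingroup <- config$ingroup %||% setdiff(species, outgroup)
  ks_source <- make_ks_source(data$ks_pairs, data$cds)

  # --- per-species paralog RBH, inter-chromosomal filter, Ks peak count ---
  mode_fits <- list()
  paralogs <- list()
  for (sp in species) {
    gsp <- genes[genes$species == sp, , drop = FALSE]
    hsp <- hits[hits$query %in% gsp$gene_id & hits$subject %in% gsp$gene_id, ,
                drop = FALSE]
    pr <- within_species_paralog_rbh(hsp, config$evalue_max)
    fp <- filter_interchromosomal(pr, gsp)
    if (nrow(fp) > 0L) fp$ks <- ks_source(fp)
    fp$species <- sp
    paralogs[[sp]] <- fp
    fit <- tryCatch(
      fit_ks_modes(fp$ks, k_max = config$k_max,
                   weight_floor = config$weight_floor,
                   ks_min = config$ks_min, ks_max = config$ks_max,
                   seed = substream_seed(config$seed, paste0("modes-", sp))),
      error = function(e) {
        notes <<- c(notes, sprintf("ks modes %s: %s", sp, conditionMessage(e)))
        NULL
      })
    mode_fits[[sp]] <- fit
    say("homology/ks %s: %d RBH pairs, %d inter-chromosomal, %s peak(s)",
        sp, nrow(pr), nrow(fp),
        if (is.null(fit)) "no" else fit$n_components)
  }

  # --- macrosynteny: AC labels, segments, reassembly, dot plots ---
  segments <- list()
  reorgs <- list()
  dots <- list()
  for (sp in ingroup) {
    gsp <- genes[genes$species == sp, , drop = FALSE]
    lab <- assign_ac_labels(gsp, data$alg_map, hits, config$evalue_max)
    seg <- call_segments_genome(lab, min_run = config$min_run,
                                max_gap = config$max_gap, species = sp)
    segments[[sp]] <- seg
    reorg <- reassemble_chromosomes(cluster_segments(seg), gsp,
                                    seed = substream_seed(
                                      config$seed, paste0("reassemble-", sp)))
    reorgs[[sp]] <- reorg
    dots[[sp]] <- dotplot_table(reorg, data$alg_map, hits, config$evalue_max)
    say("synteny %s: %d segments over %d ACs, %d genes reassembled",
        sp, nrow(seg), length(unique(seg$ac)), nrow(reorg))
  }
  segments <- dplyr::bind_rows(segments)

  # --- homolog selection, per-AC trees, verdict ---
  hsets <- select_homolog_sets(segments, genes, hits, data$alg_map,
                               evalue_max = config$evalue_max,
                               ingroup = ingroup)
  n_sets <- length(unique(hsets$ancestral_gene))
  say("selection: %d ancestral genes with two homologs in every species",
      n_sets)

  tree_ks <- NULL
  calls <- tibble::tibble(ac = character(0), label = character(0),
                          shared = integer(0), independent = integer(0),
                          ambiguous = integer(0), n_genes = integer(0))
  trees <- list()
  if (n_sets > 0L) {
    need <- needed_pairs(hsets)
    need$ks <- ks_source(need)
    tree_ks <- need
    dup <- duplication_calls(hsets, tree_ks,
                             min_sets_per_ac = config$min_sets_per_ac)
    calls <- dup$calls
    trees <- dup$trees
  }

  ingroup_fits <- mode_fits[ingroup]
  ingroup_fits <- ingroup_fits[!vapply(ingroup_fits, is.null, logical(1))]
  if (nrow(calls) > 0L && length(ingroup_fits) > 0L) {
    verdict <- aggregate_verdict(calls, ingroup_fits,
                                 shared_threshold = config$shared_threshold,
                                 min_modes = config$min_modes)
  } else {
    notes <- c(notes, if (nrow(calls) == 0L)
      "no per-AC duplication calls possible; verdict defaults to FALSE"
      else "no ingroup Ks mode fit; verdict defaults to FALSE")
    verdict <- list(n_calls = nrow(calls),
                    labels = c(shared = 0L, independent = 0L, ambiguous = 0L),
                    shared_fraction = NA_real_,
                    ks_modes = if (length(ingroup_fits))
                      min(vapply(ingroup_fits, function(f)
                        as.integer(f$n_components), integer(1)))
                      else NA_integer_,
                    verdict = FALSE,
                    thresholds = list(
                      shared_threshold = config$shared_threshold,
                      min_modes = config$min_modes))
  }
  say("verdict: %s (shared fraction %s, Ks modes %s)",
      verdict$verdict,
      format(verdict$shared_fraction, digits = 3), verdict$ks_modes)

  report <- list(
    schema_version = "1.0",
    generator = sprintf("paleoploid %s", as.character(packageVersion("paleoploid"))),
    seed = config$seed,
    params = unclass(config)[c("evalue_max", "min_run", "max_gap", "k_max",
                               "weight_floor", "ks_min", "ks_max",
                               "min_sets_per_ac", "shared_threshold",
                               "min_modes")],
    species = list(all = species, ingroup = ingroup, outgroup = outgroup),
    n_genes = as.list(table(genes$species)),
    paralog_pairs = lapply(paralogs, function(p)
      list(interchromosomal = nrow(p),
           ks_median = if (nrow(p)) stats::median(p$ks, na.rm = TRUE)
                       else NA_real_)),
    ks_modes = lapply(mode_fits, function(f) if (is.null(f)) NULL else
      list(n_components = f$n_components, means = f$means, sds = f$sds,
           weights = f$weights, n_used = f$n_used)),
    n_segments = if (nrow(segments)) as.list(table(segments$species))
                 else list(),
    n_homolog_sets = n_sets,
    calls = as.data.frame(calls),
    shared_fraction = verdict$shared_fraction,
    verdict = verdict,
    notes = notes
  )
  class(report) <- "wgd_report"

  if (!is.null(out_dir)) {
    write_run_dir(out_dir, config, data, paralogs, mode_fits, segments,
                  reorgs, dots, hsets, calls, trees, report)
    return(invisible(report))
  }
  report
}

# All unordered gene pairs inside each homolog set (distances the per-AC
# matrices will need).
needed_pairs <- function(hsets) {
  parts <- lapply(split(hsets$gene, hsets$ancestral_gene), function(g) {
    g <- unique(g)
    if (length(g) < 2L) return(NULL)
    cmb <- combn(sort(g), 2L)
    tibble::tibble(gene_a = cmb[1L, ], gene_b = cmb[2L, ])
  })
  out <- dplyr::bind_rows(parts)
  out[!duplicated(out), , drop = FALSE]
}

write_run_dir <- function(out_dir, config, data, paralogs, mode_fits,
                          segments, reorgs, dots, hsets, calls, trees,
                          report) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    dsdir <- file.path(out_dir, "dataset")
    # re-emit the simulated inputs so each stage can be re-run from files
    write_dataset(structure(list(genes = data$genes, hits = data$hits,
                                 ks_pairs = data$ks_pairs,
                                 alg_map = data$alg_map, cds = data$cds,
                                 truth = data$truth, config = sim_cfg),
                            class = "wgd_sim"), dsdir)
    add("dataset/")
  }
  pp <- dplyr::bind_rows(paralogs)
  write_tsv_plain(pp[, c("species", "gene_a", "gene_b", "ks",
                         "interchromosomal")],
                  file.path(out_dir, "paralog_pairs.tsv"))
  add("paralog_pairs.tsv")
  jsonlite::write_json(report$ks_modes, file.path(out_dir, "mode_fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  add("mode_fits.json")
  write_tsv_plain(segments, file.path(out_dir, "segments.tsv"))
  add("segments.tsv")
  for (sp in names(reorgs)) {
    write_tsv_plain(reorgs[[sp]],
                    file.path(out_dir, sprintf("reorganized_%s.tsv", sp)))
    write_tsv_plain(dots[[sp]],
                    file.path(out_dir, sprintf("dotplot_%s.tsv", sp)))
    add(sprintf("reorganized_%s.tsv", sp))
    add(sprintf("dotplot_%s.tsv", sp))
  }
  write_tsv_plain(as.data.frame(hsets), file.path(out_dir, "homolog_sets.tsv"))
  add("homolog_sets.tsv")
  if (length(trees)) {
    nwk <- vapply(trees, ape::write.tree, character(1))
    writeLines(paste(names(trees), nwk, sep = "\t"),
               file.path(out_dir, "ac_trees.tsv"))
    add("ac_trees.tsv")
  }
  write_tsv_plain(as.data.frame(calls), file.path(out_dir, "calls.tsv"))
  add("calls.tsv")
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", pretty = TRUE)
  add("report.json")
  log_lines <- c(
    sprintf("paleoploid %s", as.character(packageVersion("paleoploid"))),
    sprintf("seed\t%d", config$seed),
    sprintf("%s\t%s", names(report$params),
            vapply(report$params, function(v) paste(format(v), collapse = ","),
                   character(1))),
    sprintf("verdict\t%s", report$verdict$verdict))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  add("run.log")
  jsonlite::write_json(list(format = "paleoploid-run", schema_version = "1.0",
                            files = files),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' @export
print.wgd_report <- function(x, ...) {
  cat("<wgd_report>\n")
  cat(sprintf("  species: %s (outgroup %s)\n",
              paste(x$species$all, collapse = ", "), x$species$outgroup))
  for (sp in names(x$ks_modes)) {
    f <- x$ks_modes[[sp]]
    cat(sprintf("  Ks peaks %s: %s\n", sp,
                if (is.null(f)) "not fit"
                else sprintf("%d at Ks %s", f$n_components,
                             paste(sprintf("%.3g", exp(f$means)),
                                   collapse = ", "))))
  }
  cat(sprintf("  homolog sets: %d; calls: %d (%s)\n",
              x$n_homolog_sets, x$verdict$n_calls,
              paste(sprintf("%s=%d", names(x$verdict$labels),
                            x$verdict$labels), collapse = ", ")))
  cat(sprintf("  verdict: %s (shared fraction %s, Ks modes %s)\n",
              x$verdict$verdict, format(x$shared_fraction, digits = 3),
              x$verdict$ks_modes))
  invisible(x)
}
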