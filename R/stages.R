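# File-based pipeline stages. Each stage reads its predecessor's files from
# the run directory (or the configured input directory), writes its own
# outputs there, and derives its randomness from the global seed by stage
# name — so re-running a single stage reproduces the in-pipeline result.

stage_names <- function() {
  c("simulate", "homology", "ks", "synteny", "select", "trees", "verdict",
    "all")
}

stage_data <- function(config, run_dir) {
  ds <- file.path(run_dir, "dataset")
  if (dir.exists(ds)) return(read_dataset(ds))
  if (!is.null(config$input_dir)) return(read_dataset(config$input_dir))
  stop("no dataset found: run the simulate stage first or set input_dir",
       call. = FALSE)
}

need_file <- function(path, hint) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s (%s)", path, hint), call. = FALSE)
  path
}

#' Run one pipeline stage from files
#'
#' Stages: `simulate` (emit a dataset), `homology` (within-species paralog
#' RBH), `ks` (inter-chromosomal filter + Ks peak fits), `synteny` (AC
#' labels, segments, reassembly, dot plots), `select` (homolog sets),
#' `trees` (per-AC distance trees and calls), `verdict` (aggregate report),
#' `all` (the whole chain, equivalent to [run_pipeline()] with `out_dir`).
#'
#' @param stage One of the names above.
#' @param config A [pipeline_config()].
#' @param run_dir Run directory holding stage inputs/outputs.
#' @return Invisibly, the stage's main result.
#' @export
run_stage <- function(stage, config, run_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- match.arg(stage, stage_names())
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)

  if (stage == "all")
    return(invisible(run_pipeline(config, out_dir = run_dir, quiet = TRUE)))

  if (stage == "simulate") {
    if (is.null(config$sim))
      stop("simulate stage needs a sim block in the config", call. = FALSE)
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    sim <- simulate_dataset(sim_cfg)
    write_dataset(sim, file.path(run_dir, "dataset"))
    return(invisible(sim))
  }

  data <- stage_data(config, run_dir)
  genes <- data$genes
  species <- sort(unique(genes$species))
  ingroup <- config$ingroup %||% setdiff(species, config$outgroup)

  if (stage == "homology") {
    out <- lapply(species, function(sp) {
      gsp <- genes[genes$species == sp, , drop = FALSE]
      hsp <- data$hits[data$hits$query %in% gsp$gene_id &
                         data$hits$subject %in% gsp$gene_id, , drop = FALSE]
      pr <- within_species_paralog_rbh(hsp, config$evalue_max)
      pr$species <- sp
      pr[, c("species", "gene_a", "gene_b")]
    })
    out <- dplyr::bind_rows(out)
    write_tsv_plain(out, file.path(run_dir, "rbh_pairs.tsv"))
    return(invisible(out))
  }

  if (stage == "ks") {
    pf <- need_file(file.path(run_dir, "rbh_pairs.tsv"),
                    "run the homology stage first")
    pairs <- tibble::as_tibble(read.delim(pf, stringsAsFactors = FALSE))
    ks_source <- make_ks_source(data$ks_pairs, data$cds)
    used <- list()
    fits <- list()
    for (sp in species) {
      pr <- pairs[pairs$species == sp, , drop = FALSE]
      gsp <- genes[genes$species == sp, , drop = FALSE]
      fp <- filter_interchromosomal(pr, gsp)
      if (nrow(fp) > 0L) fp$ks <- ks_source(fp)
      used[[sp]] <- fp
      fits[[sp]] <- tryCatch({
        f <- fit_ks_modes(fp$ks, k_max = config$k_max,
                          weight_floor = config$weight_floor,
                          ks_min = config$ks_min, ks_max = config$ks_max,
                          seed = substream_seed(config$seed,
                                                paste0("modes-", sp)))
        list(n_components = f$n_components, means = f$means, sds = f$sds,
             weights = f$weights, n_used = f$n_used)
      }, error = function(e) NULL)
    }
    write_tsv_plain(dplyr::bind_rows(used), file.path(run_dir, "ks_used.tsv"))
    jsonlite::write_json(fits, file.path(run_dir, "mode_fits.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    return(invisible(fits))
  }

  if (stage == "synteny") {
    segs <- list()
    for (sp in ingroup) {
      gsp <- genes[genes$species == sp, , drop = FALSE]
      lab <- assign_ac_labels(gsp, data$alg_map, data$hits, config$evalue_max)
      seg <- call_segments_genome(lab, min_run = config$min_run,
                                  max_gap = config$max_gap, species = sp)
      segs[[sp]] <- seg
      reorg <- reassemble_chromosomes(
        cluster_segments(seg), gsp,
        seed = substream_seed(config$seed, paste0("reassemble-", sp)))
      write_tsv_plain(reorg,
                      file.path(run_dir, sprintf("reorganized_%s.tsv", sp)))
      write_tsv_plain(dotplot_table(reorg, data$alg_map, data$hits,
                                    config$evalue_max),
                      file.path(run_dir, sprintf("dotplot_%s.tsv", sp)))
    }
    segs <- dplyr::bind_rows(segs)
    write_tsv_plain(segs, file.path(run_dir, "segments.tsv"))
    return(invisible(segs))
  }

  if (stage == "select") {
    sf <- need_file(file.path(run_dir, "segments.tsv"),
                    "run the synteny stage first")
    segments <- tibble::as_tibble(read.delim(sf, stringsAsFactors = FALSE))
    hs <- select_homolog_sets(segments, genes, data$hits, data$alg_map,
                              evalue_max = config$evalue_max,
                              ingroup = ingroup)
    write_tsv_plain(as.data.frame(hs), file.path(run_dir, "homolog_sets.tsv"))
    return(invisible(hs))
  }

  if (stage == "trees") {
    hf <- need_file(file.path(run_dir, "homolog_sets.tsv"),
                    "run the select stage first")
    hs <- tibble::as_tibble(read.delim(hf, stringsAsFactors = FALSE))
    calls <- tibble::tibble(ac = character(0), label = character(0),
                            shared = integer(0), independent = integer(0),
                            ambiguous = integer(0), n_genes = integer(0))
    trees <- list()
    if (nrow(hs) > 0L) {
      ks_source <- make_ks_source(data$ks_pairs, data$cds)
      need <- needed_pairs(hs)
      need$ks <- ks_source(need)
      dup <- duplication_calls(hs, need,
                               min_sets_per_ac = config$min_sets_per_ac)
      calls <- dup$calls
      trees <- dup$trees
    }
    if (length(trees)) {
      nwk <- vapply(trees, ape::write.tree, character(1))
      writeLines(paste(names(trees), nwk, sep = "\t"),
                 file.path(run_dir, "ac_trees.tsv"))
    }
    write_tsv_plain(as.data.frame(calls), file.path(run_dir, "calls.tsv"))
    return(invisible(calls))
  }

  # stage == "verdict"
  cf <- need_file(file.path(run_dir, "calls.tsv"),
                  "run the trees stage first")
  calls <- tibble::as_tibble(read.delim(cf, stringsAsFactors = FALSE))
  mf <- need_file(file.path(run_dir, "mode_fits.json"),
                  "run the ks stage first")
  fits <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ingroup_fits <- fits[intersect(names(fits), ingroup)]
  ingroup_fits <- ingroup_fits[!vapply(ingroup_fits, is.null, logical(1))]
  verdict <- if (nrow(calls) > 0L && length(ingroup_fits) > 0L) {
    aggregate_verdict(calls, ingroup_fits,
                      shared_threshold = config$shared_threshold,
                      min_modes = config$min_modes)
  } else {
    list(n_calls = nrow(calls),
         labels = c(shared = 0L, independent = 0L, ambiguous = 0L),
         shared_fraction = NA_real_, ks_modes = NA_integer_, verdict = FALSE,
         thresholds = list(shared_threshold = config$shared_threshold,
                           min_modes = config$min_modes))
  }
  report <- list(schema_version = "1.0",
                 generator = sprintf("paleoploid %s",
                                     as.character(packageVersion("paleoploid"))),
                 seed = config$seed, calls = as.data.frame(calls),
                 ks_modes = fits, verdict = verdict)
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", pretty = TRUE)
  invisible(verdict)
}

#' Read a pipeline configuration from a JSON file
#'
#' The file may contain any [pipeline_config()] field; a `sim` object (any
#' [sim_config()] field) switches on simulate mode, `input_dir` switches on
#' file mode. Omitted fields take their documented defaults.
#'
#' @param path JSON file.
#' @param seed Optional override of the config's seed.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$sim)) {
    sim <- do.call(sim_config, raw$sim)
  } else if (is.null(raw$input_dir)) {
    sim <- sim_config()
  }
  args <- raw[setdiff(names(raw), "sim")]
  args$sim <- sim
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(pipeline_config, args)
}
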