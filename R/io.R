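# Readers and writers for the pipeline's plain-text interchange formats:
# per-species gene tables (TSV with header), BLAST outfmt-6-compatible hit
# tables (12 columns, headerless), pair-Ks tables, ancestral-linkage proxy
# maps, CDS FASTA, and a JSON truth/manifest. All numeric columns are written
# with fixed formatting so seeded runs are byte-identical.

write_tsv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

#' Write a simulated dataset to a directory
#'
#' Emits the same file set a real analysis would consume: one gene table per
#' species (`genes_<species>.tsv`: gene_id, chromosome, ordinal, strand
#' placeholder), directed hits as 12-column BLAST-tabular TSV (`hits.tsv`,
#' headerless: qseqid, sseqid, pident/length placeholders, six zero columns,
#' evalue, bitscore), the observed pair-Ks table (`ks_pairs.tsv`), the
#' ancestral-linkage proxy map (`alg_map.tsv`), optional `cds.fasta`, the
#' ground truth as `truth.json`, and a `manifest.json` echoing the config.
#'
#' @param sim A `wgd_sim` object from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @seealso [read_dataset()] for the lossless round-trip.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "wgd_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sp in sort(unique(sim$genes$species))) {
    g <- sim$genes[sim$genes$species == sp,
                   c("gene_id", "chromosome", "ordinal")]
    g$strand <- "+"
    f <- file.path(dir, sprintf("genes_%s.tsv", sp))
    write_tsv_plain(g, f)
    files <- c(files, basename(f))
  }
  if (nrow(sim$genes) == 0L) {
    f <- file.path(dir, "genes_empty.tsv")
    write_tsv_plain(tibble::tibble(gene_id = character(0),
                                   chromosome = character(0),
                                   ordinal = integer(0),
                                   strand = character(0)), f)
    files <- c(files, basename(f))
  }
  write_hits(sim$hits, file.path(dir, "hits.tsv"))
  write_tsv_plain(sim$ks_pairs[, c("gene_a", "gene_b", "ks")],
                  file.path(dir, "ks_pairs.tsv"))
  write_tsv_plain(sim$alg_map, file.path(dir, "alg_map.tsv"))
  files <- c(files, "hits.tsv", "ks_pairs.tsv", "alg_map.tsv")
  if (!is.null(sim$cds)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds),
                                file.path(dir, "cds.fasta"))
    files <- c(files, "cds.fasta")
  }
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", pretty = TRUE)
  files <- c(files, "truth.json")
  manifest <- list(format = "paleoploid-dataset", schema_version = "1.0",
                   files = files, config = unclass(sim$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(c(files, "manifest.json"))
}

#' Read a gene position table
#'
#' @param path TSV with header columns gene_id, chromosome, ordinal (strand
#'   and further columns are ignored).
#' @param species Species id to attach; defaults to the file name stem.
#' @return Tibble with columns gene_id, species, chromosome, ordinal.
#' @export
read_gene_table <- function(path, species = NULL) {
  if (!file.exists(path)) stop("gene table not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "ordinal")
  if (!all(need %in% names(df)))
    stop("gene table ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (is.null(species)) {
    species <- sub("^genes_", "", sub("\\.tsv$", "", basename(path)))
  }
  tibble::tibble(gene_id = as.character(df$gene_id),
                 species = species,
                 chromosome = as.character(df$chromosome),
                 ordinal = as.integer(df$ordinal))
}

write_hits <- function(hits, path) {
  n <- nrow(hits)
  df <- data.frame(q = hits$query, s = hits$subject,
                   pident = numeric(n), len = numeric(n), mm = numeric(n),
                   go = numeric(n), qs = numeric(n), qe = numeric(n),
                   ss = numeric(n), se = numeric(n),
                   evalue = sprintf("%.6e", hits$evalue),
                   bitscore = fmt_num(hits$score))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' @param path Headerless 12-column TSV; columns 1, 2, 11, 12 are used as
#'   query, subject, e-value and score.
#' @return Tibble with columns query, subject, score, evalue.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0)
    return(tibble::tibble(query = character(0), subject = character(0),
                          score = numeric(0), evalue = numeric(0)))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L)
    stop("hit table ", path, " is not 12-column BLAST tabular", call. = FALSE)
  tibble::tibble(query = as.character(df[[1]]), subject = as.character(df[[2]]),
                 score = as.numeric(df[[12]]), evalue = as.numeric(df[[11]]))
}

#' Read a precomputed pair-Ks table
#'
#' @param path TSV with header columns gene_a, gene_b, ks.
#' @return Tibble with those columns, pairs in canonical order.
#' @export
read_ks_table <- function(path) {
  if (!file.exists(path)) stop("Ks table not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "ks")
  if (!all(need %in% names(df)))
    stop("Ks table ", path, " lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  cp <- canonical_pairs(as.character(df$gene_a), as.character(df$gene_b))
  tibble::tibble(gene_a = cp$gene_a, gene_b = cp$gene_b,
                 ks = as.numeric(df$ks))
}

#' Read an ancestral-linkage proxy map
#'
#' @param path TSV with header columns proxy_gene and ac (alias ac_id);
#'   optional ac_ordinal.
#' @return Tibble with columns proxy_gene, ac and, if present, ac_ordinal.
#' @export
read_alg_map <- function(path) {
  if (!file.exists(path)) stop("ALG map not found: ", path, call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("ac_id" %in% names(df) && !"ac" %in% names(df)) df$ac <- df$ac_id
  if (!all(c("proxy_gene", "ac") %in% names(df)))
    stop("ALG map ", path, " needs columns proxy_gene and ac", call. = FALSE)
  out <- tibble::tibble(proxy_gene = as.character(df$proxy_gene),
                        ac = as.character(df$ac))
  if ("ac_ordinal" %in% names(df)) out$ac_ordinal <- as.integer(df$ac_ordinal)
  out
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Reconstructs the in-memory dataset, including truth columns (family,
#' subgenome) from `truth.json`, so write-then-read round-trips losslessly.
#'
#' @param dir Directory containing the dataset files.
#' @return A list with elements genes, hits, ks_pairs, alg_map, cds, truth.
#' @export
read_dataset <- function(dir) {
  gf <- sort(list.files(dir, pattern = "^genes_.*\\.tsv$", full.names = TRUE))
  if (!length(gf)) stop("no gene tables under ", dir, call. = FALSE)
  genes <- dplyr::bind_rows(lapply(gf, read_gene_table))
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    gt <- tibble::as_tibble(truth$genes_truth)
    if (nrow(genes) > 0 && !is.null(gt) && nrow(gt) > 0) {
      m <- match(genes$gene_id, gt$gene_id)
      genes$family <- gt$family[m]
      genes$subgenome <- gt$subgenome[m]
    }
  }
  ks_pairs <- NULL
  if (file.exists(file.path(dir, "ks_pairs.tsv")))
    ks_pairs <- read_ks_table(file.path(dir, "ks_pairs.tsv"))
  alg_map <- NULL
  if (file.exists(file.path(dir, "alg_map.tsv")))
    alg_map <- read_alg_map(file.path(dir, "alg_map.tsv"))
  cds <- NULL
  if (file.exists(file.path(dir, "cds.fasta"))) {
    x <- Biostrings::readDNAStringSet(file.path(dir, "cds.fasta"))
    cds <- setNames(as.character(x), names(x))
  }
  list(genes = genes,
       hits = read_hits(file.path(dir, "hits.tsv")),
       ks_pairs = ks_pairs, alg_map = alg_map, cds = cds, truth = truth)
}
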