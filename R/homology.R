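# Best-hit and reciprocal-best-hit (RBH) computation over similarity tables.
# Ties on score break by lower e-value, then lexicographically smallest
# subject id, so results are invariant to row order.

#' Best hit per query under an e-value threshold
#'
#' For every query, returns the subject with the maximal score among hits
#' passing `evalue_max`. Self-hits (query == subject) are dropped first.
#' Queries with no passing hit are absent from the result.
#'
#' @param hits Tibble/data frame with columns query, subject, score, evalue.
#' @param evalue_max Maximum e-value for a hit to count (default 1e-3).
#' @return Tibble with columns query, subject, score, evalue; one row per
#'   query.
#' @examples
#' h <- tibble::tibble(query = c("g1", "g1"), subject = c("h1", "h2"),
#'                     score = c(100, 90), evalue = c(1e-10, 1e-8))
#' best_hits(h)
#' @export
best_hits <- function(hits, evalue_max = 1e-3) {
  if (!is.numeric(evalue_max) || length(evalue_max) != 1L || evalue_max < 0)
    stop("evalue_max must be a single non-negative number", call. = FALSE)
  need <- c("query", "subject", "score", "evalue")
  if (!all(need %in% names(hits)))
    stop("hits need columns: ", paste(need, collapse = ", "), call. = FALSE)
  h <- hits[hits$evalue <= evalue_max & hits$query != hits$subject, ,
            drop = FALSE]
  if (nrow(h) == 0L) return(tibble::as_tibble(h[need]))
  h <- h[order(h$query, -h$score, h$evalue, h$subject), , drop = FALSE]
  tibble::as_tibble(h[!duplicated(h$query), need])
}

#' Reciprocal best hits between two gene sets
#'
#' A pair (a, b) is reported when b is a's best hit in `hits_ab` and a is
#' b's best hit in `hits_ba`, both under the e-value threshold. The result
#' (as a set of unordered pairs) is invariant to swapping the two inputs.
#'
#' @param hits_ab,hits_ba Hit tables for the two directions.
#' @inheritParams best_hits
#' @return Tibble with columns a_gene, b_gene (a from the query side of
#'   `hits_ab`).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, evalue_max = 1e-3) {
  ba <- best_hits(hits_ab, evalue_max)
  bb <- best_hits(hits_ba, evalue_max)
  m <- match(ba$subject, bb$query)
  ok <- !is.na(m) & bb$subject[m] == ba$query
  out <- tibble::tibble(a_gene = ba$query[ok], b_gene = ba$subject[ok])
  out[order(out$a_gene, out$b_gene), , drop = FALSE]
}

#' Within-species paralog pairs by reciprocal best hit
#'
#' Applies RBH to one species' self-comparison (after removing self-hits):
#' pairs of genes that are mutually each other's best hit, canonicalized to
#' lexicographic order. Ks is left unset for downstream estimation.
#'
#' @param hits_self Hit table of a species against itself.
#' @inheritParams best_hits
#' @return Tibble of paralog pairs: gene_a, gene_b (gene_a < gene_b), ks
#'   (NA), interchromosomal (NA until [filter_interchromosomal()]).
#' @export
within_species_paralog_rbh <- function(hits_self, evalue_max = 1e-3) {
  b <- best_hits(hits_self, evalue_max)
  m <- match(b$subject, b$query)
  ok <- !is.na(m) & b$subject[m] == b$query
  if (!any(ok))
    return(tibble::tibble(gene_a = character(0), gene_b = character(0),
                          ks = numeric(0), interchromosomal = logical(0)))
  cp <- canonical_pairs(b$query[ok], b$subject[ok])
  out <- tibble::tibble(gene_a = cp$gene_a, gene_b = cp$gene_b)
  out <- out[!duplicated(out), , drop = FALSE]
  out$ks <- NA_real_
  out$interchromosomal <- NA
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}
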